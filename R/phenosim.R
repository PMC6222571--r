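#' Anthocyanin compound catalogue
#'
#' The eight chromatogram peaks quantified at 520 nm and their acylation
#' status. Peak 3 is the co-elution bundle under peonidin 3-glucoside
#' (treated as a single non-acylated peak), peak 6 is the unidentified peak
#' eluting with the acylated compounds, and peak 7 is the peonidin
#' 3-(6''-malonyl) glucoside / cyanidin dimalonyl co-elution treated as one
#' acylated compound.
#'
#' @return A \code{data.frame} with \code{id}, \code{code} (column name used
#'   in peak tables) and \code{acylated}.
#' @export
anthocyanin_catalogue <- function() {
  data.frame(
    id = 1:8,
    code = c("C3G", "Pg3G", "Pn3G", "C3MG", "Pg3MG", "ID6",
             "Pn3MG_C3DMG", "Pg3DMG"),
    acylated = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# fixed within-class peak-area shares (acylated compounds and non-acylated
# compounds each sum to 1); malonylated cyanidin dominates the acylated
# fraction as in deeply pigmented dent backgrounds
acyl_shares <- c(C3MG = 0.50, Pg3MG = 0.12, ID6 = 0.08,
                 Pn3MG_C3DMG = 0.22, Pg3DMG = 0.08)
nonacyl_shares <- c(C3G = 0.60, Pg3G = 0.15, Pn3G = 0.25)

# scored-class indicator for one causal locus given mutant-allele dosage
scored_class <- function(dosage, mode) {
  switch(mode,
         recessive = dosage == 2L,
         dominant  = dosage >= 1L,
         het       = dosage == 1L,
         stop("unknown locus mode: ", mode, call. = FALSE))
}

#' Simulate HPLC phenotypes for an F2 population
#'
#' Builds per-sample traits from the causal genotypes and decomposes them
#' into replicate chromatogram peak areas so every derived statistic can be
#' recomputed from the raw layer:
#' \itemize{
#'   \item anthocyanin content (mg/kg) = baseline + the sum of per-locus
#'     shifts applied when each locus's scored-class condition holds, plus a
#'     mean-zero right-skewed (shifted log-normal) residual, floored at
#'     1 mg/kg;
#'   \item acylation percentage drawn from the mutant class distribution
#'     when the reduced-acylation locus is homozygous mutant, otherwise the
#'     wild-type class;
#'   \item peak areas: total area proportional to anthocyanin content via
#'     the external standard, split between acylated and non-acylated
#'     compounds by the acylation percentage and fixed within-class shares;
#'   \item two replicate injections per sample, each scaling the whole
#'     chromatogram by an independent factor calibrated so the expected
#'     two-replicate coefficient of variation equals
#'     \code{replicate_cv_pct};
#'   \item kernel scores from the causal genotypes: \code{r1_score} (0/1
#'     speckling), \code{c1_recessive}, the inert \code{p1_score}, and the
#'     reduced-acylation truth flag.
#' }
#'
#' @param pop An \code{\link{simulate_f2}} population.
#' @param config A \code{\link{population_config}}; defaults to the
#'   population's own.
#' @return An object of class \code{"phenotype_sim"}: list with
#'   \code{peaks} (one row per sample x replicate, wide compound columns),
#'   \code{truth} (per-sample generating values and 0/1 scored-class
#'   columns) and \code{config}.
#' @export
simulate_phenotypes <- function(pop, config = pop$config) {
  validate_population_config(config)
  if (config$acyl_mean_mutant < 0 || config$acyl_mean_wildtype < 0) {
    stop("invalid config: negative class means", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed + 3L)
  loci <- pop$loci
  geno <- pop$causal_geno
  n <- length(pop$samples)

  scored <- vapply(seq_len(nrow(loci)),
                   function(i) scored_class(geno[loci$name[i], ], loci$mode[i]),
                   logical(n))
  colnames(scored) <- loci$name

  acyl_idx <- which(loci$is_acylation_locus)
  is_reduced <- scored[, acyl_idx]

  # acylation percentage: bimodal by reduced-acylation class
  acyl_true <- ifelse(is_reduced,
                      stats::rnorm(n, config$acyl_mean_mutant, config$acyl_sd_mutant),
                      stats::rnorm(n, config$acyl_mean_wildtype, config$acyl_sd_wildtype))
  acyl_true <- pmin(100, pmax(0, acyl_true))

  # anthocyanin content: additive scored-class shifts + skewed residual
  ac_gen <- config$baseline_ac + as.numeric(scored %*% loci$ac_effect)
  if (config$ac_noise_sd > 0) {
    s <- config$ac_noise_sdlog
    scale <- config$ac_noise_sd / sqrt((exp(s^2) - 1) * exp(s^2))
    noise <- scale * stats::rlnorm(n, 0, s) - scale * exp(s^2 / 2)
  } else {
    noise <- 0
  }
  ac_true <- pmax(1, ac_gen + noise)

  # decompose into compound areas via the external standard
  cat8 <- anthocyanin_catalogue()
  total_area <- ac_true / config$standard_ac * config$standard_total_area
  areas <- matrix(0, n, nrow(cat8), dimnames = list(pop$samples, cat8$code))
  for (cc in names(acyl_shares)) {
    areas[, cc] <- total_area * acyl_true / 100 * acyl_shares[[cc]]
  }
  for (cc in names(nonacyl_shares)) {
    areas[, cc] <- total_area * (1 - acyl_true / 100) * nonacyl_shares[[cc]]
  }

  # two replicate injections; whole-chromatogram multiplier per injection,
  # sd calibrated so E[sample CV of 2 replicates] = replicate_cv_pct
  sd_rep <- (config$replicate_cv_pct / 100) / sqrt(2 / pi)
  reps <- lapply(1:2, function(r) {
    m <- if (sd_rep > 0) pmax(0.01, 1 + stats::rnorm(n, 0, sd_rep)) else rep(1, n)
    data.frame(sample = pop$samples, replicate = r,
               areas * m, stringsAsFactors = FALSE, row.names = NULL)
  })
  peaks <- do.call(rbind, reps)
  peaks <- peaks[order(peaks$sample, peaks$replicate), , drop = FALSE]
  rownames(peaks) <- NULL

  truth <- data.frame(sample = pop$samples,
                      ac_true = ac_true,
                      acyl_true = acyl_true,
                      reduced_acylation = as.integer(is_reduced),
                      stringsAsFactors = FALSE)
  for (nm in setdiff(loci$name, loci$name[acyl_idx])) {
    truth[[nm]] <- as.integer(scored[, nm])
  }
  truth$r1_score <- if ("r1" %in% loci$name) as.integer(scored[, "r1"]) else NA_integer_
  truth$c1_recessive <- if ("c1" %in% loci$name) scored[, "c1"] else NA
  dosg <- t(geno)
  colnames(dosg) <- paste0("dosage_", rownames(geno))
  truth <- cbind(truth, as.data.frame(dosg, row.names = NULL))

  structure(list(peaks = peaks, truth = truth, config = config),
            class = "phenotype_sim")
}
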