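#' Causal loci for the default trait architecture
#'
#' The default architecture places the reduced-acylation locus at
#' chr1:300,173,138 (the candidate acyltransferase's coordinate), an
#' anthocyanin-content intensifier on chromosome 7, and the two aleurone
#' transcription-factor loci on chromosomes 9 and 10. Effects are additive
#' shifts on anthocyanin content (mg/kg) applied when the locus's scored
#' class condition holds: \code{"recessive"} loci score the homozygous
#' mutant class, \code{"het"} loci score heterozygotes (the kernel-phenotype
#' scores for the speckling and colorless traits track the segregating
#' heterozygous ears). The pericarp-color locus is carried with a zero
#' effect and emitted only as an inert score column.
#'
#' @param reduced_acylation_pos bp position of the reduced-acylation locus
#'   on chromosome 1.
#' @return A \code{data.frame} with columns \code{name}, \code{chrom},
#'   \code{pos}, \code{mode} ("recessive" or "het"), \code{ac_effect}
#'   (mg/kg) and \code{is_acylation_locus} (exactly one \code{TRUE}).
#' @export
default_causal_loci <- function(reduced_acylation_pos = 300173138L) {
  data.frame(
    name  = c("aat1", "in1", "c1", "r1", "p1"),
    chrom = c(1L, 7L, 9L, 10L, 1L),
    pos   = c(as.integer(reduced_acylation_pos), 100000000L, 110000000L,
              95000000L, 48000000L),
    mode  = c("recessive", "recessive", "het", "het", "recessive"),
    ac_effect = c(-23.3, 105.4, -29.1, -24.2, 0),
    is_acylation_locus = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

validate_causal_loci <- function(loci, chrom_lengths) {
  stopifnot(is.data.frame(loci),
            all(c("name", "chrom", "pos", "mode", "ac_effect",
                  "is_acylation_locus") %in% names(loci)))
  if (sum(loci$is_acylation_locus) != 1L) {
    stop("exactly one locus must be flagged as the reduced-acylation locus",
         call. = FALSE)
  }
  if (!all(loci$mode %in% c("recessive", "dominant", "het"))) {
    stop("locus mode must be 'recessive', 'dominant' or 'het'", call. = FALSE)
  }
  bad <- loci$pos < 1 | loci$pos > chrom_lengths[loci$chrom]
  if (any(bad)) {
    stop("causal locus position outside its chromosome: ",
         paste(loci$name[bad], collapse = ", "), call. = FALSE)
  }
  invisible(loci)
}

# Simulate gamete haplotypes for one chromosome.
#
# Positions are bp; the genetic map is linear at cm_per_mb. Crossover counts
# per gamete are Poisson with mean equal to the map length in Morgans and
# crossover positions are uniform on the genetic map (no interference), so
# the recombination fraction between two positions d cM apart is the Haldane
# value (1 - exp(-2d/100)) / 2. Returns an n_gametes x n_pos integer matrix
# of founder origins (0 = founder A, 1 = founder B).
sim_gametes_chrom <- function(pos_bp, chrom_len, cm_per_mb, n_gametes) {
  g_cm <- pos_bp / 1e6 * cm_per_mb
  len_m <- chrom_len / 1e6 * cm_per_mb / 100
  out <- matrix(0L, nrow = n_gametes, ncol = length(pos_bp))
  k <- stats::rpois(n_gametes, len_m)
  init <- stats::rbinom(n_gametes, 1L, 0.5)
  for (g in seq_len(n_gametes)) {
    if (k[g] == 0L) {
      out[g, ] <- init[g]
    } else {
      xo <- sort(stats::runif(k[g], 0, len_m * 100))
      out[g, ] <- (init[g] + findInterval(g_cm, xo)) %% 2L
    }
  }
  out
}

#' Simulate an F2 mapping population
#'
#' Generates F2 genotypes from a cross between an inbred founder ("A") and a
#' near-inbred founder ("B") by simulating meioses under the Haldane map
#' function: crossover counts are Poisson with mean equal to the chromosome
#' map length in Morgans and crossover positions are uniform on the genetic
#' map. Each F2 individual receives two independent F1 gametes, so marker
#' genotype classes segregate 1:2:1. At a \code{residual_founder_het}
#' fraction of markers the B founder is still heterozygous and carries a
#' third allele, producing occasional tri-allelic sites as in a not-fully
#' inbred genetic stock. Causal loci ride the same simulated haplotypes (as
#' pseudo-markers on the B-founder mutant background) but are recorded
#' separately and never degraded.
#'
#' @param map A \code{\link{build_marker_map}} result.
#' @param loci Causal-locus table, see \code{\link{default_causal_loci}}.
#' @param config A \code{\link{population_config}}.
#' @return An object of class \code{"f2_population"}: a list with
#'   \code{map}, \code{samples}, \code{calls} (marker x sample two-letter
#'   calls), \code{codes}/\code{maf} (from \code{\link{code_numeric}}),
#'   \code{causal_geno} (locus x sample dosage of the B/mutant allele,
#'   0/1/2), \code{loci} and \code{config}.
#' @export
simulate_f2 <- function(map, loci = default_causal_loci(),
                        config = population_config()) {
  validate_population_config(config)
  if (is.null(map) || nrow(map) == 0L) {
    stop("invalid input: empty marker map", call. = FALSE)
  }
  lens <- attr(map, "chrom_lengths")
  if (is.null(lens)) lens <- config$chrom_lengths
  validate_causal_loci(loci, lens)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)

  n <- config$n_individuals
  samples <- sprintf("F2_%03d", seq_len(n))
  n_gam <- 2L * n

  # founder alleles per marker: A-founder homozygous a1, B-founder a2
  # (plus a third allele a3 at residual-het sites)
  m <- nrow(map)
  nucs <- c("A", "C", "G", "T")
  a1 <- sample(nucs, m, replace = TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(nucs, x), 1L), character(1))
  het_site <- stats::runif(m) < config$residual_founder_het
  a3 <- rep(NA_character_, m)
  if (any(het_site)) {
    a3[het_site] <- mapply(function(x, y) sample(setdiff(nucs, c(x, y)), 1L),
                           a1[het_site], a2[het_site])
  }

  # simulate founder-origin haplotypes over markers and causal loci jointly
  origin_mk <- matrix(0L, nrow = n_gam, ncol = m)
  origin_cl <- matrix(0L, nrow = n_gam, ncol = nrow(loci))
  for (ch in sort(unique(c(map$chrom, loci$chrom)))) {
    mk_idx <- which(map$chrom == ch)
    cl_idx <- which(loci$chrom == ch)
    pos <- c(map$pos[mk_idx], loci$pos[cl_idx])
    ord <- order(pos)
    len_ch <- if (is.null(names(lens))) lens[[ch]] else lens[[as.character(ch)]]
    hap <- sim_gametes_chrom(pos[ord], len_ch, config$cm_per_mb, n_gam)
    hap <- hap[, order(ord), drop = FALSE]   # back to input order
    if (length(mk_idx)) origin_mk[, mk_idx] <- hap[, seq_along(mk_idx), drop = FALSE]
    if (length(cl_idx)) origin_cl[, cl_idx] <- hap[, length(mk_idx) + seq_along(cl_idx), drop = FALSE]
  }

  g1 <- origin_mk[seq(1L, n_gam, by = 2L), , drop = FALSE]  # maternal gamete
  g2 <- origin_mk[seq(2L, n_gam, by = 2L), , drop = FALSE]  # paternal gamete

  # at residual-het sites, each F2's B-founder lineage carries a2 or a3
  # (its F1 parent drew one of the two alleles)
  b_allele <- matrix(rep(a2, each = n), nrow = n, byrow = FALSE)
  if (any(het_site)) {
    for (j in which(het_site)) {
      pick3 <- stats::runif(n) < 0.5
      b_allele[pick3, j] <- a3[j]
    }
  }

  # assemble two-letter calls, alleles sorted within a call
  call_allele <- function(origin) {
    out <- matrix(rep(a1, each = n), nrow = n)
    bsel <- origin == 1L
    out[bsel] <- b_allele[bsel]
    out
  }
  al1 <- call_allele(g1)
  al2 <- call_allele(g2)
  lo <- pmin(al1, al2); hi <- pmax(al1, al2)
  calls <- t(matrix(paste0(lo, hi), nrow = n))   # markers x samples
  dimnames(calls) <- list(map$marker, samples)

  causal_geno <- t(origin_cl[seq(1L, n_gam, by = 2L), , drop = FALSE] +
                   origin_cl[seq(2L, n_gam, by = 2L), , drop = FALSE])
  dimnames(causal_geno) <- list(loci$name, samples)

  pop <- structure(list(map = map, samples = samples, calls = calls,
                        codes = NULL, maf = NULL,
                        causal_geno = causal_geno, loci = loci,
                        config = config),
                   class = "f2_population")
  coded <- code_numeric(pop$calls, map)
  pop$codes <- coded$codes
  pop$maf <- coded$maf
  pop$map <- coded$map
  pop$calls <- coded$calls
  pop
}

#' Degrade genotype calls with missingness and heterozygote miscalls
#'
#' Emulates low-coverage genotyping noise: each marker call is masked as
#' missing with probability \code{missing_rate}, and each surviving
#' heterozygous call is replaced by one of its two homozygotes (equal
#' probability) with probability \code{het_miscall_rate}. Causal-locus truth
#' is never degraded. Numeric codes and minor-allele frequencies are
#' recomputed from the degraded calls.
#'
#' @param pop An \code{f2_population}.
#' @param config A \code{\link{population_config}} supplying the rates and
#'   seed; defaults to the population's own config.
#' @return The degraded \code{f2_population}.
#' @export
degrade_calls <- function(pop, config = pop$config) {
  validate_population_config(config)
  if (config$missing_rate == 0 && config$het_miscall_rate == 0) return(pop)
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  calls <- pop$calls
  nmk <- nrow(calls); ns <- ncol(calls)
  if (config$het_miscall_rate > 0) {
    a <- substr(calls, 1L, 1L); b <- substr(calls, 2L, 2L)
    het <- !is.na(calls) & a != b
    flip <- het & matrix(stats::runif(nmk * ns) < config$het_miscall_rate, nmk, ns)
    if (any(flip)) {
      pickb <- stats::runif(sum(flip)) < 0.5
      calls[flip] <- ifelse(pickb, paste0(b[flip], b[flip]),
                            paste0(a[flip], a[flip]))
    }
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(nmk * ns) < config$missing_rate, nmk, ns)
    calls[drop] <- NA_character_
  }
  coded <- code_numeric(calls, pop$map, drop_all_missing = FALSE)
  pop$calls <- coded$calls
  pop$codes <- coded$codes
  pop$maf <- coded$maf
  pop$map <- coded$map
  pop
}
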