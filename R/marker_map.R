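#' B73-like chromosome lengths (bp)
#'
#' Physical lengths of the ten maize chromosomes used as the default genome
#' for simulated marker maps, matching RefGen_v3-scale coordinates.
#' Chromosome 1 ends at 301,476,924 bp so that loci near its distal tip
#' (including the reduced-acylation candidate region) are representable.
#'
#' @return Named integer vector of length 10 (names "1".."10").
#' @export
maize_chrom_lengths <- function() {
  c(`1` = 301476924L, `2` = 237917468L, `3` = 232245527L,
    `4` = 242062272L, `5` = 217959525L, `6` = 169407836L,
    `7` = 176826311L, `8` = 175377492L, `9` = 157038028L,
    `10` = 149632204L)
}

#' Configuration for a synthetic F2 mapping population
#'
#' Collects every tunable of the population generator: genome/marker-map
#' geometry, meiosis rate, call-degradation rates, and the phenotype model
#' (anthocyanin content baseline and per-locus shifts in mg/kg, acylation
#' percentage class means, HPLC replicate repeatability).
#'
#' Defaults reproduce the study conditions the downstream analyses assume:
#' 128 genotyped individuals, 8062 markers over 10 chromosomes with denser
#' chromosome ends, wild-type/mutant acylation class means of 70.8 and 15.0
#' percent, a mean replicate coefficient of variation of 3.09 percent, and a
#' complete (post-imputation-like) genotype matrix; degradation rates default
#' to zero and are applied only via \code{\link{degrade_calls}}.
#'
#' @param n_individuals Number of F2 individuals.
#' @param n_markers Total marker count across the genome (>= 10).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param cm_per_mb Genetic-to-physical map rate (cM/Mb), applied uniformly.
#' @param end_fraction Fraction of each chromosome counted as a "terminal"
#'   region at each end for marker-density purposes.
#' @param end_density_boost Relative marker density of terminal regions vs
#'   the interior (1 = uniform).
#' @param residual_founder_het Fraction of markers at which the mutant-stock
#'   founder is still heterozygous (it was not fully inbred); such sites
#'   carry a third allele and behave as tri-allelic downstream.
#' @param missing_rate Per-entry missing-call probability for
#'   \code{\link{degrade_calls}}.
#' @param het_miscall_rate Probability that a heterozygous call is degraded
#'   to a random homozygote in \code{\link{degrade_calls}}.
#' @param seed Integer seed; every generator operation is deterministic
#'   given the seed.
#' @param baseline_ac Anthocyanin content (mg/kg) of an individual in the
#'   reference class at every scored locus, before locus shifts and noise.
#' @param ac_noise_sd Standard deviation (mg/kg) of the right-skewed
#'   (shifted log-normal) residual added to anthocyanin content.
#' @param ac_noise_sdlog Log-scale shape of the residual distribution.
#' @param acyl_mean_mutant,acyl_mean_wildtype Acylation-percentage class
#'   means for reduced-acylation mutants and wild types.
#' @param acyl_sd_mutant,acyl_sd_wildtype Within-class standard deviations
#'   of acylation percentage.
#' @param replicate_cv_pct Target mean coefficient of variation (percent)
#'   between the two HPLC replicate injections of a sample.
#' @param standard_total_area Integrated chromatogram area assigned to the
#'   external standard (arbitrary absorbance-area units).
#' @param standard_ac Anthocyanin content of the external standard (mg/kg).
#' @return An object of class \code{"population_config"} (a validated list).
#' @export
population_config <- function(n_individuals = 128L,
                              n_markers = 8062L,
                              chrom_lengths = maize_chrom_lengths(),
                              cm_per_mb = 0.7,
                              end_fraction = 0.2,
                              end_density_boost = 2,
                              residual_founder_het = 0.05,
                              missing_rate = 0,
                              het_miscall_rate = 0,
                              seed = 1L,
                              baseline_ac = 102.3,
                              ac_noise_sd = 25,
                              ac_noise_sdlog = 0.6,
                              acyl_mean_mutant = 15.0,
                              acyl_mean_wildtype = 70.8,
                              acyl_sd_mutant = 5,
                              acyl_sd_wildtype = 6,
                              replicate_cv_pct = 3.09,
                              standard_total_area = 1e6,
                              standard_ac = 1000) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_markers = as.integer(n_markers),
              chrom_lengths = chrom_lengths,
              cm_per_mb = cm_per_mb,
              end_fraction = end_fraction,
              end_density_boost = end_density_boost,
              residual_founder_het = residual_founder_het,
              missing_rate = missing_rate,
              het_miscall_rate = het_miscall_rate,
              seed = if (is.null(seed)) NULL else as.integer(seed),
              baseline_ac = baseline_ac,
              ac_noise_sd = ac_noise_sd,
              ac_noise_sdlog = ac_noise_sdlog,
              acyl_mean_mutant = acyl_mean_mutant,
              acyl_mean_wildtype = acyl_mean_wildtype,
              acyl_sd_mutant = acyl_sd_mutant,
              acyl_sd_wildtype = acyl_sd_wildtype,
              replicate_cv_pct = replicate_cv_pct,
              standard_total_area = standard_total_area,
              standard_ac = standard_ac)
  class(cfg) <- "population_config"
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  if (cfg$n_individuals < 1L) stop("n_individuals must be >= 1", call. = FALSE)
  if (cfg$n_markers < 1L) stop("n_markers must be >= 1", call. = FALSE)
  if (any(cfg$chrom_lengths <= 0)) {
    stop("invalid config: chromosome lengths must be positive", call. = FALSE)
  }
  rates <- c(cfg$residual_founder_het, cfg$missing_rate, cfg$het_miscall_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("invalid config: rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$end_fraction < 0 || cfg$end_fraction > 0.5) {
    stop("invalid config: end_fraction must lie in [0, 0.5]", call. = FALSE)
  }
  if (cfg$end_density_boost <= 0 || cfg$cm_per_mb <= 0) {
    stop("invalid config: densities and map rates must be positive", call. = FALSE)
  }
  if (cfg$acyl_mean_mutant < 0 || cfg$acyl_mean_wildtype < 0) {
    stop("invalid config: acylation class means must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

# Allocate n markers to chromosomes proportionally to physical length,
# guaranteeing at least one marker per chromosome (largest-remainder rule).
allocate_markers <- function(n, chrom_lengths) {
  k <- length(chrom_lengths)
  stopifnot(n >= k)
  share <- chrom_lengths / sum(chrom_lengths) * n
  alloc <- pmax(1L, floor(share))
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(share - floor(share), decreasing = TRUE)
    i <- 0L
    while (rem > 0) {
      j <- extra[(i %% k) + 1L]
      alloc[j] <- alloc[j] + 1L
      rem <- rem - 1L
      i <- i + 1L
    }
  } else if (rem < 0) {
    while (rem < 0) {
      j <- which.max(alloc)
      alloc[j] <- alloc[j] - 1L
      rem <- rem + 1L
    }
  }
  as.integer(alloc)
}

# Sample one chromosome's marker positions from a piecewise-uniform density
# with elevated weight in the terminal end_fraction at each end.
sample_positions <- function(n, len, end_fraction, boost) {
  if (n == 0L) return(integer(0))
  e <- end_fraction * len
  # segment weights: [0,e] boost, (e, len-e) 1, [len-e, len] boost
  w <- c(boost * e, len - 2 * e, boost * e)
  w <- w / sum(w)
  u <- stats::runif(n)
  seg <- findInterval(u, cumsum(w)[1:2]) + 1L
  v <- stats::runif(n)
  pos <- numeric(n)
  pos[seg == 1L] <- v[seg == 1L] * e
  pos[seg == 2L] <- e + v[seg == 2L] * (len - 2 * e)
  pos[seg == 3L] <- (len - e) + v[seg == 3L] * e
  pos <- sort(unique(pmax(1, round(pos))))
  # resolve duplicate integer positions by nudging until n distinct values
  while (length(pos) < n) {
    fill <- pmax(1, round(stats::runif(n - length(pos), 1, len)))
    pos <- sort(unique(c(pos, fill)))
  }
  as.integer(pos[seq_len(n)])
}

#' Build a GBS-style marker map
#'
#' Places markers on a 10-chromosome genome with configurably elevated
#' density in the terminal regions of each chromosome, emulating the
#' end-of-chromosome enrichment typical of reduced-representation SNP sets.
#' Positions are 1-based bp, strictly increasing within a chromosome.
#'
#' @param config A \code{\link{population_config}}.
#' @return A \code{data.frame} of class \code{"marker_map"} with columns
#'   \code{marker} (label \code{S<chrom>_<pos>}), \code{chrom} (integer) and
#'   \code{pos} (bp), plus attributes \code{chrom_lengths} and
#'   \code{cm_per_mb}.
#' @examples
#' map <- build_marker_map(population_config(n_markers = 500, seed = 7))
#' spacing_stats(map)
#' @export
build_marker_map <- function(config = population_config()) {
  validate_population_config(config)
  if (config$n_markers < 10L) stop("n_markers must be >= 10", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  lens <- config$chrom_lengths
  alloc <- allocate_markers(config$n_markers, lens)
  chrom <- rep(seq_along(lens), alloc)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    sample_positions(alloc[i], lens[i], config$end_fraction,
                     config$end_density_boost)
  }), use.names = FALSE)
  map <- data.frame(marker = sprintf("S%d_%d", chrom, pos),
                    chrom = as.integer(chrom), pos = as.integer(pos),
                    stringsAsFactors = FALSE)
  attr(map, "chrom_lengths") <- lens
  attr(map, "cm_per_mb") <- config$cm_per_mb
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Adjacent-marker spacing diagnostics
#'
#' Summarises within-chromosome gaps between adjacent markers: the mean gap,
#' the fraction of gaps under 1 Mb, and among those the fraction under 1 kb.
#' Gaps never span chromosome boundaries.
#'
#' @param map A \code{marker_map} (or any data.frame with \code{chrom} and
#'   \code{pos} columns).
#' @return A list with \code{n_gaps}, \code{mean_gap}, \code{frac_lt_1mb}
#'   and \code{frac_lt_1kb_of_lt_1mb} (all \code{NA}/0 when no chromosome
#'   holds two or more markers).
#' @export
spacing_stats <- function(map) {
  gaps <- unlist(lapply(split(map$pos, map$chrom), function(p) {
    if (length(p) < 2L) numeric(0) else diff(sort(p))
  }), use.names = FALSE)
  if (length(gaps) == 0L) {
    return(list(n_gaps = 0L, mean_gap = NA_real_, frac_lt_1mb = NA_real_,
                frac_lt_1kb_of_lt_1mb = NA_real_))
  }
  lt1mb <- gaps < 1e6
  list(n_gaps = length(gaps),
       mean_gap = mean(gaps),
       frac_lt_1mb = mean(lt1mb),
       frac_lt_1kb_of_lt_1mb = if (any(lt1mb)) mean(gaps[lt1mb] < 1e3) else NA_real_)
}
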