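#' Proportion of a subsample in the scored phenotype class
#'
#' @param idx Subsample indices (or labels) into the population.
#' @param flags Logical (or 0/1) vector over the whole population marking
#'   the scored (recessive/mutant) class.
#' @return Fraction of the subsample carrying the scored class.
#' @examples
#' proportion_recessive(1:20, rep(c(TRUE, FALSE), c(8, 12)))  # 0.4
#' @export
proportion_recessive <- function(idx, flags) {
  mean(as.logical(flags[idx]))
}

#' Subsampling power simulation for QTL detection
#'
#' For each subsample size, repeatedly draws genotypes at random without
#' replacement, runs a single-marker scan of the trait, and classifies the
#' most significant marker (ties broken by genomic coordinate) as:
#' \emph{detected} — below the Bonferroni per-test level
#' (\code{alpha / n_markers}, with n_markers the full marker count, constant
#' across replicates) \emph{and} within \code{window_bp} of the true locus;
#' \emph{false positive} — significant but outside the window; or
#' \emph{non-significant}. Distances are measured on the cumulative genome
#' coordinate (chromosomes laid end to end), which equals the within-
#' chromosome bp distance for same-chromosome pairs and guarantees that a
#' genome-length window can produce no false positives. A replicate whose
#' subsampled trait is constant is recorded as non-significant.
#'
#' Summaries per size follow the conventions of a QTL simulation table:
#' detection and false-positive percentages over all replicates; the
#' average and minimum subsample proportion of the scored phenotype class;
#' the average \eqn{-log10(p)} of the top marker over \emph{significant}
#' replicates; and the average distance (bp) from the true locus over
#' \emph{detected} replicates.
#'
#' @param pop An \code{f2_population}.
#' @param y Trait vector over the population's samples.
#' @param true_locus \code{c(chrom, pos)} of the known causal locus.
#' @param sizes Subsample sizes, each at most the population size.
#' @param reps Replicates per size (default 100).
#' @param window_bp Detection window around the true locus (default 10 Mb).
#' @param alpha Family-wise level for the Bonferroni rule (default 0.05).
#' @param seed Integer seed; fixed seed gives an identical report.
#' @param recessive Logical vector marking the scored phenotype class per
#'   sample; defaults to \code{y == max(y)...} only when \code{y} is binary
#'   0/1, otherwise must be supplied.
#' @return Data frame of class \code{"power_report"}, one row per size:
#'   \code{size}, \code{detection_pct}, \code{false_positive_pct},
#'   \code{avg_prop_recessive}, \code{min_prop_recessive},
#'   \code{avg_mlog10p}, \code{avg_distance_bp}; attributes \code{reps},
#'   \code{window_bp}, \code{alpha}, \code{per_test_p}, \code{n_markers}.
#' @export
run_power_simulation <- function(pop, y, true_locus,
                                 sizes = c(20, 40, 60, 80, 100),
                                 reps = 100L, window_bp = 1e7,
                                 alpha = 0.05, seed = 1L,
                                 recessive = NULL) {
  ns <- length(pop$samples)
  stopifnot(all(sizes <= ns), reps >= 1L, length(true_locus) == 2L)
  if (is.null(recessive)) {
    vals <- sort(unique(y[!is.na(y)]))
    if (length(vals) == 2L && all(vals %in% c(0, 1))) {
      recessive <- y == 1
    } else {
      stop("supply `recessive` flags for a non-binary trait", call. = FALSE)
    }
  }
  n_markers <- nrow(pop$codes)
  per_test_p <- alpha / n_markers
  # cumulative genome coordinates for distance computation
  lens <- attr(pop$map, "chrom_lengths")
  chroms <- sort(unique(c(pop$map$chrom, true_locus[1L])))
  if (is.null(lens)) {
    lens <- vapply(chroms, function(ch) {
      max(pop$map$pos[pop$map$chrom == ch], true_locus[2L][true_locus[1L] == ch])
    }, numeric(1))
    names(lens) <- chroms
  }
  offset <- stats::setNames(cumsum(c(0, as.numeric(lens[as.character(chroms)])[-length(chroms)])),
                            chroms)
  cum_mk <- pop$map$pos + offset[as.character(pop$map$chrom)]
  cum_true <- true_locus[2L] + offset[as.character(true_locus[1L])]
  set.seed(seed)

  rows <- lapply(sizes, function(sz) {
    det <- fp <- logical(reps)
    prop <- mlog <- dist <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      idx <- sample.int(ns, sz)
      prop[r] <- proportion_recessive(idx, recessive)
      ysub <- y[idx]
      if (length(unique(ysub[!is.na(ysub)])) < 2L) next  # constant trait
      sc <- scan_codes(pop$codes[, idx, drop = FALSE], pop$map, ysub)
      top <- order(-sc$mlog10p, pop$map$chrom, pop$map$pos)[1L]
      if (sc$p[top] < per_test_p) {
        mlog[r] <- sc$mlog10p[top]
        d_bp <- abs(cum_mk[top] - cum_true)
        hit <- d_bp <= window_bp
        det[r] <- hit
        fp[r] <- !hit
        if (hit) dist[r] <- d_bp
      }
    }
    data.frame(size = sz,
               detection_pct = 100 * mean(det),
               false_positive_pct = 100 * mean(fp),
               avg_prop_recessive = mean(prop),
               min_prop_recessive = min(prop),
               avg_mlog10p = if (any(!is.na(mlog))) mean(mlog, na.rm = TRUE)
                             else NA_real_,
               avg_distance_bp = if (any(!is.na(dist))) mean(dist, na.rm = TRUE)
                                 else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "reps") <- as.integer(reps)
  attr(out, "window_bp") <- window_bp
  attr(out, "alpha") <- alpha
  attr(out, "per_test_p") <- per_test_p
  attr(out, "n_markers") <- n_markers
  class(out) <- c("power_report", "data.frame")
  out
}
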