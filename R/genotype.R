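#' Convert raw genotype calls to numeric codes
#'
#' Applies the major/minor numeric coding used for GBS SNP matrices: at each
#' marker the major allele is the most frequent allele across the population
#' (ties broken lexicographically by allele symbol); a call is coded as its
#' dosage of the major allele, so major homozygote = 2, heterozygote = 1 and
#' any other homozygote — including third/fourth alleles at residually
#' heterozygous sites, which are collapsed with the minor alleles — = 0.
#' Markers with no non-missing calls are excluded with a warning.
#'
#' @param calls Character matrix (markers x samples) of two-letter calls
#'   such as \code{"AA"}, \code{"AG"}; \code{NA} for missing. Heterozygosity
#'   is symbol-based (two distinct letters, order-insensitive).
#' @param map Optional \code{marker_map} aligned with \code{calls}; filtered
#'   alongside the calls.
#' @param drop_all_missing Exclude markers with no non-missing call (with a
#'   warning); set \code{FALSE} to keep them with \code{NA} codes and maf,
#'   preserving matrix shape (used after call degradation).
#' @return List with \code{calls} (possibly reduced), \code{codes} (integer
#'   matrix, values 0/1/2/NA), \code{maf} (per-marker minor-allele frequency,
#'   the frequency of the rarer of major-vs-rest, in [0, 0.5]) and
#'   \code{map}.
#' @examples
#' m <- matrix(c("AA", "AG", "GG", "AA"), nrow = 1,
#'             dimnames = list("S1_1", paste0("s", 1:4)))
#' code_numeric(m)$codes
#' @export
code_numeric <- function(calls, map = NULL, drop_all_missing = TRUE) {
  stopifnot(is.matrix(calls))
  a <- substr(calls, 1L, 1L)
  b <- substr(calls, 2L, 2L)
  # order alleles within call so coding is orientation-free
  lo <- pmin(a, b); hi <- pmax(a, b)
  n_non_missing <- rowSums(!is.na(calls))
  dead <- n_non_missing == 0L
  if (any(dead) && drop_all_missing) {
    warning(sum(dead), " marker(s) with all calls missing excluded: ",
            paste(utils::head(rownames(calls)[dead], 5L), collapse = ", "),
            call. = FALSE)
    keep <- !dead
    calls <- calls[keep, , drop = FALSE]
    lo <- lo[keep, , drop = FALSE]; hi <- hi[keep, , drop = FALSE]
    if (!is.null(map)) map <- map[keep, , drop = FALSE]
  }
  nmk <- nrow(calls)
  codes <- matrix(NA_integer_, nmk, ncol(calls), dimnames = dimnames(calls))
  maf <- rep(NA_real_, nmk)
  for (i in seq_len(nmk)) {
    obs <- !is.na(calls[i, ])
    if (!any(obs)) next
    tab <- table(c(lo[i, obs], hi[i, obs]))
    major <- names(tab)[which.max(tab)]   # which.max takes first on ties;
    # table() names are sorted, so ties resolve lexicographically
    codes[i, obs] <- (lo[i, obs] == major) + (hi[i, obs] == major)
    fmaj <- as.numeric(tab[major]) / sum(tab)
    maf[i] <- min(fmaj, 1 - fmaj)
  }
  list(calls = calls, codes = codes, maf = maf, map = map)
}

#' Filter markers by minor-allele frequency
#'
#' Removes markers whose minor-allele frequency falls below the threshold;
#' markers exactly at the threshold are retained. Marker order is preserved.
#'
#' @param pop An \code{f2_population} (or any list with \code{codes},
#'   \code{maf}, \code{calls}, \code{map}).
#' @param threshold MAF cutoff in [0, 0.5]; default 0.05.
#' @return The filtered population object.
#' @export
filter_maf <- function(pop, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  keep <- pop$maf >= threshold
  subset_markers(pop, keep)
}

#' Filter samples by missing-data fraction
#'
#' Removes samples whose fraction of missing marker calls strictly exceeds
#' \code{max_missing} (a sample at exactly the threshold is retained), then
#' recomputes numeric codes and minor-allele frequencies from the surviving
#' samples, matching the pipeline order of sample filtering before the MAF
#' filter.
#'
#' @param pop An \code{f2_population}.
#' @param max_missing Maximum tolerated missing fraction; default 0.80.
#' @return The filtered population object.
#' @export
filter_samples_by_missing <- function(pop, max_missing = 0.80) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- colMeans(is.na(pop$codes))
  keep <- miss <= max_missing
  if (!any(keep)) stop("all samples exceed the missing-data threshold",
                       call. = FALSE)
  pop$calls <- pop$calls[, keep, drop = FALSE]
  pop$codes <- pop$codes[, keep, drop = FALSE]
  pop$samples <- pop$samples[keep]
  if (!is.null(pop$causal_geno)) {
    pop$causal_geno <- pop$causal_geno[, keep, drop = FALSE]
  }
  coded <- code_numeric(pop$calls, pop$map)
  pop$calls <- coded$calls
  pop$codes <- coded$codes
  pop$maf <- coded$maf
  pop$map <- coded$map
  pop
}

subset_markers <- function(pop, keep) {
  pop$calls <- pop$calls[keep, , drop = FALSE]
  pop$codes <- pop$codes[keep, , drop = FALSE]
  pop$maf <- pop$maf[keep]
  pop$map <- pop$map[keep, , drop = FALSE]
  pop
}
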