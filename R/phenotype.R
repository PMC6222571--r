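#' Acylation percentage of one sample
#'
#' 100 times the summed peak area of acylated compounds divided by the total
#' integrated chromatogram area. Scale-invariant: multiplying all areas by a
#' positive constant leaves the result unchanged.
#'
#' @param areas Named numeric vector of peak areas for one sample
#'   (replicate-averaged).
#' @param acylated Logical vector marking which entries of \code{areas} are
#'   acylated compounds; defaults to matching names against
#'   \code{\link{anthocyanin_catalogue}} (unknown compounds count in the
#'   denominator only).
#' @return Percentage in [0, 100], or \code{NA} when the total area is zero
#'   (undefined trait; such samples are excluded from acylation analyses).
#' @examples
#' acylation_percentage(c(C3G = 30, C3MG = 70))  # 70
#' @export
acylation_percentage <- function(areas, acylated = NULL) {
  if (is.null(acylated)) {
    cat8 <- anthocyanin_catalogue()
    acylated <- names(areas) %in% cat8$code[cat8$acylated]
  }
  stopifnot(all(areas >= 0, na.rm = TRUE))
  tot <- sum(areas, na.rm = TRUE)
  if (tot <= 0) return(NA_real_)
  100 * sum(areas[acylated], na.rm = TRUE) / tot
}

#' Anthocyanin content by the external-standard method
#'
#' Content in mg/kg is proportional to total chromatogram area relative to
#' an external standard of known content run under the same method:
#' \code{standard_ac * (total_area / standard_total_area) *
#' mass_volume_scale}.
#'
#' @param total_area Total integrated area of the sample chromatogram (or a
#'   vector of areas, which is summed).
#' @param standard_total_area Total area of the external standard; must be
#'   positive.
#' @param standard_ac Content of the standard, default 1000 mg/kg.
#' @param mass_volume_scale Correction when sample and standard extraction
#'   geometry differ; default 1 (identical mass/volume).
#' @return Content in mg/kg.
#' @export
anthocyanin_content <- function(total_area, standard_total_area,
                                standard_ac = 1000, mass_volume_scale = 1) {
  if (!is.finite(standard_total_area) || standard_total_area <= 0) {
    stop("invalid standard: standard_total_area must be positive",
         call. = FALSE)
  }
  if (length(total_area) > 1L) total_area <- sum(total_area, na.rm = TRUE)
  standard_ac * (total_area / standard_total_area) * mass_volume_scale
}

#' Replicate coefficient of variation
#'
#' 100 times the sample standard deviation of replicate measurements
#' divided by their mean, the repeatability statistic for duplicate HPLC
#' injections.
#'
#' @param values Numeric vector of at least two replicate measurements.
#' @return CV in percent, or \code{NA} when the mean is zero (undefined).
#' @examples
#' replicate_cv(c(90, 110))  # 14.14
#' @export
replicate_cv <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Classify a sample as a reduced-acylation mutant
#'
#' The mutant class is defined by the valley of the bimodal acylation
#' histogram: strictly less than 50 percent acylation.
#'
#' @param acylation_pct Acylation percentage(s) in [0, 100].
#' @return Logical: \code{TRUE} for mutants.
#' @export
classify_reduced_acylation <- function(acylation_pct) {
  stopifnot(all(acylation_pct >= 0 & acylation_pct <= 100, na.rm = TRUE))
  acylation_pct < 50
}

#' Score kernel marker-gene phenotypes
#'
#' Converts per-ear kernel observations to the 0/1 marker-gene scores used
#' as regression factors: \code{r1_score} is 1 when speckled kernels are
#' present; \code{c1_recessive} is \code{TRUE} when the ear has yellow
#' kernels without speckling, or when the colorless-kernel fraction lies in
#' a configurable band around one half (the "approximately 50 percent
#' colorless" rule).
#'
#' @param obs Data frame with logical \code{speckled} and
#'   \code{yellow_no_speckle} columns and numeric \code{colorless_fraction}.
#' @param colorless_band Two-element numeric interval treated as
#'   "approximately 50 percent"; default \code{c(0.4, 0.6)}.
#' @return Data frame with \code{r1_score} (integer 0/1) and
#'   \code{c1_recessive} (logical).
#' @export
score_marker_genes <- function(obs, colorless_band = c(0.4, 0.6)) {
  stopifnot(all(c("speckled", "yellow_no_speckle", "colorless_fraction")
                %in% names(obs)),
            length(colorless_band) == 2L)
  data.frame(
    r1_score = as.integer(obs$speckled),
    c1_recessive = obs$yellow_no_speckle |
      (obs$colorless_fraction >= colorless_band[1] &
       obs$colorless_fraction <= colorless_band[2]))
}

#' Derive per-sample traits from a replicate peak table
#'
#' Averages replicate injections per sample, then computes acylation
#' percentage from the averaged areas, anthocyanin content from the averaged
#' total area via the external standard, the replicate coefficient of
#' variation from per-replicate contents, and the reduced-acylation
#' classification. Compound columns not in the catalogue are retained and
#' counted in the total-area denominator (as non-acylated).
#'
#' @param peaks Data frame with \code{sample}, \code{replicate} and one
#'   numeric column per compound (see \code{\link{simulate_phenotypes}}).
#' @param standard_total_area,standard_ac,mass_volume_scale External
#'   standard parameters, see \code{\link{anthocyanin_content}}.
#' @return Data frame (one row per sample) with \code{AC},
#'   \code{acylation_pct}, \code{cv_pct}, \code{is_reduced_acylation} and
#'   replicate-averaged compound areas.
#' @export
derive_phenotypes <- function(peaks, standard_total_area,
                              standard_ac = 1000, mass_volume_scale = 1) {
  stopifnot(all(c("sample", "replicate") %in% names(peaks)))
  comp_cols <- setdiff(names(peaks), c("sample", "replicate"))
  cat8 <- anthocyanin_catalogue()
  acylated <- comp_cols %in% cat8$code[cat8$acylated]

  out <- lapply(split(peaks, peaks$sample), function(d) {
    m <- as.matrix(d[, comp_cols, drop = FALSE])
    avg <- colMeans(m)
    rep_ac <- apply(m, 1L, function(r) {
      anthocyanin_content(sum(r), standard_total_area, standard_ac,
                          mass_volume_scale)
    })
    acyl <- acylation_percentage(avg, acylated)
    res <- data.frame(sample = d$sample[1L],
                      AC = anthocyanin_content(sum(avg), standard_total_area,
                                               standard_ac, mass_volume_scale),
                      acylation_pct = acyl,
                      cv_pct = if (length(rep_ac) >= 2L) replicate_cv(rep_ac)
                               else NA_real_,
                      is_reduced_acylation =
                        if (is.na(acyl)) NA else classify_reduced_acylation(acyl),
                      stringsAsFactors = FALSE)
    cbind(res, as.data.frame(as.list(avg)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
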