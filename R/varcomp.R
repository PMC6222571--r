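#' Type-3 variance-component decomposition across segregating loci
#'
#' Treats each locus score as a random factor in a main-effects crossed
#' model and partitions the phenotypic variance by the Type-3
#' method of moments: for every factor, compute the Type-III sum of squares
#' (the reduction from dropping that factor from the full main-effects
#' model), equate each observed sum of squares — including the residual — to
#' its expectation under the all-random model
#' \eqn{E[y'Ay] = \sum_j \sigma_j^2 tr(A Z_j Z_j') + \sigma_e^2 tr(A)},
#' and solve the resulting linear system for the variance components.
#' Negative solutions are truncated to zero (optionally reported raw) and
#' proportions renormalised to sum to 100.
#'
#' Factors observed at a single level are dropped with a warning. If the
#' expected-mean-square system is singular the function falls back to a
#' sequential (Type-I) decomposition with a warning.
#'
#' @param y Numeric trait vector.
#' @param factors Data frame of per-sample locus scores (0/1 or factors),
#'   one column per locus.
#' @param truncate Truncate negative components at zero (default TRUE).
#' @return An object of class \code{"variance_decomposition"}: a data frame
#'   with \code{factor}, \code{variance} and \code{proportion} (percent)
#'   rows including \code{Residual}; attributes \code{raw} (untruncated
#'   solutions) and \code{method} ("type3" or "type1").
#' @export
decompose_variance <- function(y, factors, truncate = TRUE) {
  stopifnot(is.data.frame(factors), nrow(factors) == length(y))
  keep <- vapply(factors, function(f) length(unique(f[!is.na(f)])) >= 2L,
                 logical(1))
  if (!all(keep)) {
    warning("dropping single-level factor(s): ",
            paste(names(factors)[!keep], collapse = ", "), call. = FALSE)
    factors <- factors[, keep, drop = FALSE]
  }
  if (ncol(factors) == 0L) stop("no usable factors", call. = FALSE)
  ok <- stats::complete.cases(factors) & !is.na(y)
  y <- y[ok]; factors <- factors[ok, , drop = FALSE]
  n <- length(y)
  fnames <- names(factors)
  Z <- lapply(factors, function(f) {
    stats::model.matrix(~ 0 + factor(f))
  })
  Zall <- do.call(cbind, Z)
  Xfull <- cbind(1, Zall)
  qr_full <- qr(Xfull)
  rss_full <- sum(qr.resid(qr_full, y)^2)
  # residual sums of squares of each Z column under a design's projection
  zres <- function(qrx) {
    vapply(Z, function(Zi) sum(qr.resid(qrx, Zi)^2), numeric(1))
  }
  zres_full <- zres(qr_full)

  k <- length(fnames)
  SS <- numeric(k + 1L)
  C <- matrix(0, k + 1L, k + 1L,
              dimnames = list(c(fnames, "Residual"), c(fnames, "Residual")))
  for (i in seq_len(k)) {
    Xi <- cbind(rep(1, n),
                if (length(Z[-i])) do.call(cbind, Z[-i]))
    qri <- qr(Xi)
    SS[i] <- sum(qr.resid(qri, y)^2) - rss_full
    C[i, seq_len(k)] <- zres(qri) - zres_full
    C[i, k + 1L] <- qr_full$rank - qri$rank
  }
  SS[k + 1L] <- rss_full
  C[k + 1L, seq_len(k)] <- zres_full
  C[k + 1L, k + 1L] <- n - qr_full$rank

  method <- "type3"
  est <- tryCatch(solve(C, SS), error = function(e) NULL)
  if (is.null(est) || rcond_safe(C) < 1e-12) {
    warning("singular expected-mean-square system; ",
            "falling back to sequential (Type-I) decomposition",
            call. = FALSE)
    method <- "type1"
    SS <- numeric(k + 1L)
    C <- matrix(0, k + 1L, k + 1L)
    prev_qr <- qr(matrix(1, n, 1))
    prev_rss <- sum(qr.resid(prev_qr, y)^2)
    prev_zres <- zres(prev_qr)
    for (i in seq_len(k)) {
      qri <- qr(cbind(1, do.call(cbind, Z[seq_len(i)])))
      rss_i <- sum(qr.resid(qri, y)^2)
      zres_i <- zres(qri)
      SS[i] <- prev_rss - rss_i
      C[i, seq_len(k)] <- prev_zres - zres_i
      C[i, k + 1L] <- qri$rank - prev_qr$rank
      prev_qr <- qri; prev_rss <- rss_i; prev_zres <- zres_i
    }
    SS[k + 1L] <- prev_rss
    C[k + 1L, seq_len(k)] <- prev_zres
    C[k + 1L, k + 1L] <- n - prev_qr$rank
    est <- solve(C, SS)
  }
  raw <- stats::setNames(est, c(fnames, "Residual"))
  comp <- if (truncate) pmax(raw, 0) else raw
  prop <- 100 * comp / sum(pmax(comp, 0))
  out <- data.frame(factor = c(fnames, "Residual"),
                    variance = as.numeric(comp),
                    proportion = as.numeric(prop),
                    stringsAsFactors = FALSE)
  attr(out, "raw") <- raw
  attr(out, "method") <- method
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

rcond_safe <- function(M) {
  tryCatch(rcond(M), error = function(e) 0)
}

#' Fixed-effects summary of locus scores
#'
#' Multiple regression of the trait on all locus scores jointly: the
#' coefficient of each 0/1 score estimates the trait shift attributable to
#' that locus's scored class, with a two-sided t-test per coefficient.
#' Aliased (perfectly confounded) factors are reported explicitly rather
#' than silently dropped.
#'
#' @param y Numeric trait vector.
#' @param factors Data frame of per-sample 0/1 locus scores.
#' @return Data frame of class \code{"fixed_effects_summary"} with
#'   \code{term}, \code{estimate}, \code{se}, \code{t}, \code{p} and
#'   significance category \code{sig} ("***" p<0.0001, "**" p<0.001,
#'   "*" p<0.05); attribute \code{aliased} lists confounded terms (their
#'   rows carry NA estimates).
#' @export
fixed_effects_summary <- function(y, factors) {
  stopifnot(is.data.frame(factors), nrow(factors) == length(y))
  dat <- data.frame(.y = y, factors)
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  sm <- summary(fit)$coefficients
  terms <- names(cf)
  out <- data.frame(term = terms,
                    estimate = as.numeric(cf),
                    se = NA_real_, t = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  m <- match(rownames(sm), terms)
  out$se[m] <- sm[, "Std. Error"]
  out$t[m] <- sm[, "t value"]
  out$p[m] <- sm[, "Pr(>|t|)"]
  out$sig <- ifelse(is.na(out$p), "",
                    ifelse(out$p < 1e-4, "***",
                           ifelse(out$p < 1e-3, "**",
                                  ifelse(out$p < 0.05, "*", ""))))
  attr(out, "aliased") <- aliased
  attr(out, "fit") <- fit
  class(out) <- c("fixed_effects_summary", "data.frame")
  out
}
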