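#' Bonferroni genome-wide significance threshold
#'
#' Family-wise error control for a genome scan: the per-test level is
#' \code{alpha / n_tests} where \code{n_tests} is the number of SNPs
#' scanned.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_tests Number of tests (markers), >= 1.
#' @return An object of class \code{"qtl_threshold"} with \code{alpha},
#'   \code{n_tests}, \code{per_test_p} and \code{minus_log10}.
#' @examples
#' bonferroni(0.05, 8062)$minus_log10  # 5.2074...
#' @export
bonferroni <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  per <- alpha / n_tests
  structure(list(alpha = alpha, n_tests = as.integer(n_tests),
                 per_test_p = per, minus_log10 = -log10(per)),
            class = "qtl_threshold")
}

#' Fixed (relaxed, exploratory) significance threshold
#'
#' An alternative threshold constructor for exploratory scans where the
#' conservative genome-wide correction hides modest-effect loci; the usual
#' relaxed choice is \code{1e-4}.
#'
#' @param per_test_p Per-test p-value cutoff in (0, 1).
#' @return A \code{"qtl_threshold"}.
#' @export
fixed_threshold <- function(per_test_p = 1e-4) {
  stopifnot(per_test_p > 0, per_test_p < 1)
  structure(list(alpha = NA_real_, n_tests = NA_integer_,
                 per_test_p = per_test_p, minus_log10 = -log10(per_test_p)),
            class = "qtl_threshold")
}

# Core per-marker OLS scan on a codes matrix (markers x samples).
#
# Fits y = b0 + b1 * code + covariates per marker and returns the two-sided
# t-test of b1 = 0 with df = n_used - rank. Complete data uses a vectorised
# residualisation (Frisch-Waugh): residualise y and every marker on
# [1, covariates], then simple regression on the residuals, which is
# algebraically identical to the full fit. Markers with (near-)zero residual
# variance are flagged monomorphic/collinear with p = 1. Missing entries
# fall back to a per-marker complete-case fit.
scan_codes <- function(codes, map, y, qmat = NULL) {
  ns <- ncol(codes)
  stopifnot(length(y) == ns)
  use_y <- !is.na(y)
  if (!is.null(qmat)) use_y <- use_y & stats::complete.cases(qmat)
  if (stats::var(y[use_y]) == 0) {
    stop("degenerate trait: phenotype is constant across samples",
         call. = FALSE)
  }
  nmk <- nrow(codes)
  beta <- rep(NA_real_, nmk); pval <- rep(1, nmk)
  mlog10 <- rep(0, nmk); nuse <- integer(nmk)
  flag <- rep("ok", nmk)

  complete <- !anyNA(codes[, use_y, drop = FALSE])
  if (complete) {
    yy <- y[use_y]
    M <- codes[, use_y, drop = FALSE]
    X0 <- cbind(rep(1, sum(use_y)),
                if (!is.null(qmat)) qmat[use_y, , drop = FALSE])
    qr0 <- qr(X0)
    r0 <- qr0$rank
    df <- sum(use_y) - r0 - 1L
    if (df < 1L) {
      flag[] <- "insufficient"
      nuse[] <- sum(use_y)
    } else {
      ey <- qr.resid(qr0, yy)
      E <- qr.resid(qr0, t(M))           # samples x markers
      exx <- colSums(E^2)
      exy <- as.numeric(crossprod(E, ey))
      sxx <- rowSums((M - rowMeans(M))^2)
      bad <- exx < 1e-10 * pmax(1, sxx) | exx < 1e-12
      b <- exy / exx
      rss <- sum(ey^2) - b^2 * exx
      rss[rss < 0] <- 0
      tstat <- b / sqrt(rss / df / exx)
      logp <- log(2) + stats::pt(-abs(tstat), df, log.p = TRUE)
      logp[logp > 0] <- 0
      beta <- b; pval <- pmax(exp(logp), .Machine$double.xmin)
      mlog10 <- -logp / log(10)
      nuse[] <- sum(use_y)
      beta[bad] <- NA_real_; pval[bad] <- 1; mlog10[bad] <- 0
      flag[bad] <- ifelse(sxx[bad] < 1e-12, "monomorphic", "collinear")
    }
  } else {
    for (j in seq_len(nmk)) {
      ok <- use_y & !is.na(codes[j, ])
      n <- sum(ok)
      nuse[j] <- n
      if (n < 3L) { flag[j] <- "insufficient"; next }
      x <- codes[j, ok]
      if (stats::var(x) == 0) { flag[j] <- "monomorphic"; next }
      X <- cbind(1, if (!is.null(qmat)) qmat[ok, , drop = FALSE], x)
      fit <- stats::lm.fit(X, y[ok])
      bx <- fit$coefficients[ncol(X)]
      if (is.na(bx)) { flag[j] <- "collinear"; next }
      df <- n - fit$rank
      if (df < 1L) { flag[j] <- "insufficient"; next }
      rss <- sum(fit$residuals^2)
      R <- qr.R(fit$qr)
      xpos <- which(fit$qr$pivot == ncol(X))   # column pivoting in dqrdc2
      xtx_inv_x <- sum(backsolve(R, diag(ncol(X)))[xpos, ]^2)
      se <- sqrt(rss / df * xtx_inv_x)
      if (se < 1e-300) { flag[j] <- "collinear"; next }
      tstat <- bx / se
      logp <- min(0, log(2) + stats::pt(-abs(tstat), df, log.p = TRUE))
      beta[j] <- bx; pval[j] <- max(exp(logp), .Machine$double.xmin)
      mlog10[j] <- -logp / log(10)
    }
  }
  list(beta = beta, p = pval, mlog10p = mlog10, n_used = nuse, flag = flag)
}

# resolve a covariate specification (marker names/indices or numeric matrix)
# into a samples x q matrix of codes
covariate_matrix <- function(pop, covariates) {
  if (is.null(covariates) || (length(covariates) == 0L)) return(NULL)
  if (is.matrix(covariates)) return(covariates)
  if (is.character(covariates)) {
    idx <- match(covariates, pop$map$marker)
    if (anyNA(idx)) stop("unknown covariate marker(s): ",
                         paste(covariates[is.na(idx)], collapse = ", "),
                         call. = FALSE)
  } else idx <- as.integer(covariates)
  t(pop$codes[idx, , drop = FALSE])
}

#' Single-marker regression scan
#'
#' For every marker, fits an ordinary least-squares regression of the
#' phenotype on the marker's numeric genotype code plus any covariate
#' markers, and reports the slope and the two-sided t-test of the slope
#' being zero (df = samples used minus model rank). Samples with missing
#' genotype or phenotype are dropped pairwise per marker. Markers that are
#' monomorphic among the used samples, or collinear with the covariate set,
#' are assigned p = 1 and flagged.
#'
#' @param pop An \code{f2_population} (or list with \code{codes} markers x
#'   samples and \code{map}).
#' @param y Numeric phenotype vector aligned with the population's samples.
#' @param covariates Covariate markers: marker names, row indices, or a
#'   samples x q numeric matrix of codes.
#' @param trait Optional trait label stored on the result.
#' @return A \code{data.frame} of class \code{"scan_result"} in map order:
#'   \code{marker}, \code{chrom}, \code{pos}, \code{beta}, \code{p},
#'   \code{mlog10p}, \code{n_used}, \code{flag}; attributes \code{trait} and
#'   \code{covariates}.
#' @export
scan_single_marker <- function(pop, y, covariates = NULL, trait = NULL) {
  qmat <- covariate_matrix(pop, covariates)
  sc <- scan_codes(pop$codes, pop$map, y, qmat)
  res <- data.frame(marker = pop$map$marker, chrom = pop$map$chrom,
                    pos = pop$map$pos, beta = sc$beta, p = sc$p,
                    mlog10p = sc$mlog10p, n_used = sc$n_used,
                    flag = sc$flag, stringsAsFactors = FALSE)
  attr(res, "trait") <- trait
  attr(res, "covariates") <-
    if (is.character(covariates)) covariates else NULL
  class(res) <- c("scan_result", "data.frame")
  res
}

# index of the most significant marker; ordered on the -log10 scale (immune
# to double underflow of extreme p-values), ties broken by genomic coordinate
top_marker <- function(res) {
  order(-res$mlog10p, res$chrom, res$pos)[1L]
}

#' Stepwise covariate QTL selection
#'
#' Round 1 scans with no covariates; while the most significant marker is
#' below the per-test threshold (and fewer than \code{max_qtl} markers have
#' been selected), that marker joins the covariate set and the scan is
#' repeated, so each round tests for additional QTL conditional on those
#' already found. Ties on p-value break by smaller genomic coordinate.
#'
#' @param pop An \code{f2_population}.
#' @param y Phenotype vector.
#' @param threshold A \code{\link{bonferroni}} or \code{\link{fixed_threshold}}.
#' @param max_qtl Cap on selected markers (runaway guard), default 10.
#' @param trait Optional trait label.
#' @return List of class \code{"stepwise_scan"}: \code{rounds} (one
#'   \code{scan_result} per round) and \code{selected} (marker names in
#'   selection order; possibly empty).
#' @export
stepwise_scan <- function(pop, y, threshold, max_qtl = 10L, trait = NULL) {
  stopifnot(inherits(threshold, "qtl_threshold"), max_qtl >= 1L)
  selected <- character(0)
  rounds <- list()
  repeat {
    res <- scan_single_marker(pop, y, covariates = selected, trait = trait)
    rounds[[length(rounds) + 1L]] <- res
    top <- top_marker(res)
    if (res$p[top] < threshold$per_test_p && length(selected) < max_qtl) {
      selected <- c(selected, res$marker[top])
    } else break
  }
  structure(list(rounds = rounds, selected = selected,
                 threshold = threshold, trait = trait),
            class = "stepwise_scan")
}

#' Span of significant markers on a chromosome
#'
#' Returns the minimum and maximum position of markers whose p-value is
#' below the per-test threshold on the given chromosome — the significant
#' interval reported for a mapped locus. A single significant marker yields
#' a zero-width interval.
#'
#' @param result A \code{scan_result}.
#' @param threshold A \code{qtl_threshold}.
#' @param chromosome Chromosome to summarise.
#' @return Named numeric \code{c(start, end)} in bp, or \code{NULL} when no
#'   marker is significant there.
#' @export
significant_interval <- function(result, threshold, chromosome) {
  sig <- result$chrom == chromosome & result$p < threshold$per_test_p
  if (!any(sig)) return(NULL)
  c(start = min(result$pos[sig]), end = max(result$pos[sig]))
}

#' Manhattan table for a scan
#'
#' Adds a cumulative genome coordinate (chromosomes laid end to end) and a
#' significance flag to a scan result, ready for plotting or TSV export.
#' The threshold line value is carried in the \code{threshold_mlog10}
#' attribute.
#'
#' @param result A \code{scan_result}.
#' @param threshold A \code{qtl_threshold}.
#' @param chrom_lengths Optional named chromosome lengths for offsets;
#'   defaults to the per-chromosome maximum marker position.
#' @return Data frame with \code{marker}, \code{chrom}, \code{pos},
#'   \code{cum_pos}, \code{mlog10p}, \code{significant}.
#' @export
manhattan_export <- function(result, threshold, chrom_lengths = NULL) {
  chroms <- sort(unique(result$chrom))
  if (is.null(chrom_lengths)) {
    lens <- vapply(chroms, function(ch) max(result$pos[result$chrom == ch]),
                   numeric(1))
  } else {
    lens <- as.numeric(chrom_lengths[as.character(chroms)])
  }
  offset <- stats::setNames(cumsum(c(0, lens[-length(lens)])), chroms)
  out <- data.frame(marker = result$marker, chrom = result$chrom,
                    pos = result$pos,
                    cum_pos = result$pos + offset[as.character(result$chrom)],
                    mlog10p = result$mlog10p,
                    significant = result$p < threshold$per_test_p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold_mlog10") <- threshold$minus_log10
  out
}

#' Plot a Manhattan table
#'
#' Base-graphics Manhattan plot with alternating chromosome shading and the
#' genome-wide threshold line.
#'
#' @param mh A \code{\link{manhattan_export}} table.
#' @param main Plot title.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{mh}.
#' @export
plot_manhattan <- function(mh, main = "", ...) {
  col <- ifelse(mh$chrom %% 2 == 0, "grey40", "steelblue4")
  graphics::plot(mh$cum_pos / 1e6, mh$mlog10p, pch = 20, cex = 0.5,
                 col = col, xlab = "Genome position (Mb)",
                 ylab = expression(-log[10](italic(p))), main = main, ...)
  graphics::abline(h = attr(mh, "threshold_mlog10"), lty = 2, col = "red3")
  invisible(mh)
}
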