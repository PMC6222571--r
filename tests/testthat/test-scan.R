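toy_pop <- function(codes, chrom = NULL, pos = NULL) {
  nm <- nrow(codes)
  if (is.null(chrom)) chrom <- rep(1L, nm)
  if (is.null(pos)) pos <- seq_len(nm) * 1000L
  map <- data.frame(marker = sprintf("S%d_%d", chrom, pos),
                    chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  rownames(codes) <- map$marker
  list(codes = codes, map = map,
       samples = sprintf("s%d", seq_len(ncol(codes))))
}

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(bonferroni(0.05, 1)$per_test_p, 0.05)
  expect_equal(bonferroni(0.05, 100)$per_test_p, 5e-4)
  expect_equal(fixed_threshold(1e-4)$minus_log10, 4)
})

test_that("scan slope and p-value match a brute-force OLS oracle", {
  # four-point example: slope exactly 1
  pop <- toy_pop(matrix(c(0, 0, 2, 2), nrow = 1))
  y <- c(1, 2, 3, 4)
  res <- scan_single_marker(pop, y)
  orc <- brute_ols_p(y, c(0, 0, 2, 2))
  expect_equal(res$beta, 1.0)
  expect_equal(res$p, orc$p, tolerance = 1e-12)

  # random toy matrices, with and without a covariate
  set.seed(42)
  for (rep in 1:5) {
    codes <- matrix(sample(0:2, 20 * 12, replace = TRUE), nrow = 20)
    pop <- toy_pop(codes)
    y <- rnorm(12) + 0.5 * codes[3, ]
    res <- scan_single_marker(pop, y)
    for (j in c(1, 3, 7, 20)) {
      orc <- brute_ols_p(y, codes[j, ])
      expect_equal(res$beta[j], orc$beta, tolerance = 1e-10)
      expect_equal(res$p[j], orc$p, tolerance = 1e-10)
    }
    resq <- scan_single_marker(pop, y, covariates = pop$map$marker[3])
    for (j in c(1, 7, 20)) {
      orc <- brute_ols_p(y, codes[j, ], Q = codes[3, ])
      expect_equal(resq$beta[j], orc$beta, tolerance = 1e-10)
      expect_equal(resq$p[j], orc$p, tolerance = 1e-10)
    }
  }
})

test_that("missing genotypes drop pairwise and match complete-case OLS", {
  set.seed(9)
  codes <- matrix(sample(0:2, 15 * 30, replace = TRUE), nrow = 15)
  codes[sample(length(codes), 60)] <- NA
  pop <- toy_pop(codes)
  y <- rnorm(30)
  res <- scan_single_marker(pop, y)
  for (j in c(2, 8, 14)) {
    ok <- !is.na(codes[j, ])
    orc <- brute_ols_p(y[ok], codes[j, ok])
    expect_equal(res$p[j], orc$p, tolerance = 1e-10)
    expect_equal(res$n_used[j], sum(ok))
  }
})

test_that("degenerate markers and traits are handled explicitly", {
  codes <- rbind(rep(1, 8), c(0, 0, 1, 1, 2, 2, 0, 1))
  pop <- toy_pop(codes)
  y <- rnorm(8)
  res <- scan_single_marker(pop, y)
  expect_equal(res$p[1], 1)
  expect_equal(res$flag[1], "monomorphic")
  expect_true(is.na(res$beta[1]))

  # marker duplicated in the covariate set is collinear
  dup <- toy_pop(rbind(codes[2, ], codes[2, ]))
  resd <- scan_single_marker(dup, y, covariates = dup$map$marker[2])
  expect_equal(resd$p[1], 1)
  expect_equal(resd$flag[1], "collinear")

  # constant trait aborts the whole scan
  expect_error(scan_single_marker(pop, rep(3, 8)), "degenerate")
})

test_that("p-values stay in (0, 1] and -log10 stays finite for huge effects", {
  set.seed(4)
  x <- rep(0:2, each = 40)
  y <- x + rnorm(120, sd = 1e-4)
  pop <- toy_pop(matrix(x, nrow = 1))
  res <- scan_single_marker(pop, y)
  expect_gt(res$p, 0)
  expect_true(is.finite(res$mlog10p))
  expect_gt(res$mlog10p, 50)
})

test_that("stepwise selection recovers a monogenic trait near its locus", {
  d <- small_pop()
  thr <- bonferroni(0.05, nrow(d$pop$codes))
  y <- as.numeric(d$sim$truth$reduced_acylation)
  sw <- stepwise_scan(d$pop, y, thr)
  expect_equal(length(sw$selected), 1L)
  hit <- d$pop$map[d$pop$map$marker == sw$selected[1], ]
  expect_equal(hit$chrom, 1L)
  expect_lt(abs(hit$pos - 300173138), 1e7)
})

test_that("stepwise selection finds nothing in pure noise", {
  d <- small_pop()
  thr <- bonferroni(0.05, nrow(d$pop$codes))
  set.seed(55)
  zero_sel <- vapply(1:20, function(i) {
    length(stepwise_scan(d$pop, rnorm(128), thr)$selected) == 0L
  }, logical(1))
  expect_gte(mean(zero_sel), 0.95)
})

test_that("two additive loci are recovered in two stepwise rounds", {
  d <- small_pop()
  thr <- bonferroni(0.05, nrow(d$pop$codes))
  # trait driven by two markers on different chromosomes
  m1 <- which(d$pop$map$chrom == 3)[10]
  m2 <- which(d$pop$map$chrom == 8)[10]
  set.seed(77)
  y <- 5 * d$pop$codes[m1, ] + 4 * d$pop$codes[m2, ] + rnorm(128)
  sw <- stepwise_scan(d$pop, y, thr)
  expect_equal(length(sw$selected), 2L)
  expect_equal(length(sw$rounds), 3L)   # final round finds nothing more
  sel <- d$pop$map[match(sw$selected, d$pop$map$marker), ]
  truth <- d$pop$map[c(m1, m2), ]
  hit <- function(row) {
    any(row$chrom == truth$chrom & abs(row$pos - truth$pos) < 1e7)
  }
  expect_true(hit(sel[1, ]) && hit(sel[2, ]))
  expect_false(sel$chrom[1] == sel$chrom[2])
})

test_that("significant intervals span the sub-threshold markers", {
  res <- data.frame(marker = c("a", "b", "c", "d"),
                    chrom = c(1, 1, 1, 2),
                    pos = c(279.2e6, 290e6, 301.5e6, 5e6),
                    p = c(1e-8, 0.5, 1e-7, 1e-9))
  thr <- fixed_threshold(1e-6)
  expect_equal(significant_interval(res, thr, 1),
               c(start = 279.2e6, end = 301.5e6))
  expect_null(significant_interval(res, fixed_threshold(1e-12), 1))
  expect_equal(unname(diff(significant_interval(res, thr, 2))), 0)
})

test_that("Manhattan export is complete and flags the causal peak", {
  d <- small_pop()
  thr <- bonferroni(0.05, nrow(d$pop$codes))
  res <- scan_single_marker(d$pop, d$derived$acylation_pct)
  mh <- manhattan_export(res, thr)
  expect_equal(nrow(mh), nrow(d$pop$map))
  expect_equal(mh$chrom[which.max(mh$mlog10p)], 1L)
  expect_equal(attr(mh, "threshold_mlog10"), thr$minus_log10)
  expect_true(all(diff(mh$cum_pos[mh$chrom == 5]) > 0))

  flat <- res; flat$p <- rep(1, nrow(flat)); flat$mlog10p <- rep(0, nrow(flat))
  mh0 <- manhattan_export(flat, thr)
  expect_true(all(mh0$mlog10p == 0) && !any(mh0$significant))
})

test_that("permuting the phenotype destroys significance", {
  d <- small_pop()
  thr <- bonferroni(0.05, nrow(d$pop$codes))
  y <- d$derived$acylation_pct
  set.seed(66)
  exceed <- vapply(1:40, function(i) {
    res <- scan_single_marker(d$pop, sample(y))
    max(res$mlog10p) > thr$minus_log10
  }, logical(1))
  expect_lte(mean(exceed), 0.05)
})

test_that("an orthogonal covariate leaves balanced-design slopes unchanged", {
  x <- rep(c(0, 2), each = 8)
  q <- rep(c(0, 1), times = 8)          # orthogonal to x by balance
  set.seed(8)
  y <- 1.5 * x + rnorm(16)
  pop <- toy_pop(matrix(x, nrow = 1))
  b0 <- scan_single_marker(pop, y)$beta
  b1 <- scan_single_marker(pop, y, covariates = matrix(q))$beta
  expect_equal(b0, b1, tolerance = 1e-10)
})
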