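# Shared synthetic populations, built lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

# small population: fast, used by most module tests
small_pop <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- population_config(n_individuals = 128L, n_markers = 600L,
                             seed = 11L)
    map <- build_marker_map(cfg)
    pop <- simulate_f2(map, config = cfg)
    sim <- simulate_phenotypes(pop)
    der <- derive_phenotypes(sim$peaks, cfg$standard_total_area)
    der <- der[match(pop$samples, der$sample), ]
    .fixtures$small <- list(cfg = cfg, pop = pop, sim = sim, derived = der)
  }
  .fixtures$small
}

# study-scale population (full marker density) for detection-power and
# end-to-end checks
dense_pop <- function() {
  if (is.null(.fixtures$dense)) {
    cfg <- population_config(seed = 21L)   # 128 individuals, 8062 markers
    map <- build_marker_map(cfg)
    pop <- simulate_f2(map, config = cfg)
    sim <- simulate_phenotypes(pop)
    .fixtures$dense <- list(cfg = cfg, pop = pop, sim = sim)
  }
  .fixtures$dense
}

# brute-force OLS oracle: normal-equations solve + t survival function,
# independent of the scan implementation
brute_ols_p <- function(y, x, Q = NULL) {
  X <- cbind(1, Q, x)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[ncol(X), ncol(X)])
  tt <- b[ncol(X)] / se
  list(beta = b[ncol(X)], p = 2 * stats::pt(-abs(tt), df), t = tt, df = df)
}
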