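test_that("F2 marker genotypes segregate 1:2:1", {
  cfg <- population_config(n_individuals = 3000, n_markers = 30, seed = 17,
                           residual_founder_het = 0)
  map <- build_marker_map(cfg)
  pop <- simulate_f2(map, config = cfg)
  n <- cfg$n_individuals
  se_het <- sqrt(0.5 * 0.5 / n)
  for (j in seq_len(nrow(pop$codes))) {
    counts <- tabulate(pop$codes[j, ] + 1L, nbins = 3L)
    # heterozygote frequency close to 1/2
    expect_lt(abs(counts[2] / n - 0.5), 3 * se_het)
    # chi-square goodness of fit to 1:2:1
    gof <- chi_square_segregation(counts, c(0.25, 0.5, 0.25))
    expect_gt(gof$p_value, 0.001)
  }
})

test_that("recombination follows the Haldane map function", {
  set.seed(31)
  for (d_cm in c(5, 20, 50)) {
    pos <- c(1e6, (1 + d_cm / 0.7) * 1e6)
    g <- anthomap:::sim_gametes_chrom(pos, 3e8, 0.7, 20000)
    r_obs <- mean(g[, 1] != g[, 2])
    r_exp <- (1 - exp(-2 * d_cm / 100)) / 2
    se <- sqrt(r_exp * (1 - r_exp) / 20000)
    expect_lt(abs(r_obs - r_exp), 3 * se)
  }
  # coincident markers: complete linkage, no recombinants
  set.seed(32)
  g0 <- anthomap:::sim_gametes_chrom(c(5e6, 5e6), 3e8, 0.7, 5000)
  expect_identical(g0[, 1], g0[, 2])
})

test_that("simulation is reproducible and records causal truth", {
  cfg <- population_config(n_individuals = 40, n_markers = 80, seed = 7)
  map <- build_marker_map(cfg)
  p1 <- simulate_f2(map, config = cfg)
  p2 <- simulate_f2(map, config = cfg)
  expect_identical(p1$calls, p2$calls)
  expect_identical(p1$causal_geno, p2$causal_geno)
  expect_equal(dim(p1$causal_geno), c(5L, 40L))
  expect_true(all(p1$causal_geno %in% 0:2))
  # empty map rejected
  expect_error(simulate_f2(map[0, ], config = cfg), "empty")
})

test_that("residual founder heterozygosity yields tri-allelic-like sites", {
  cfg <- population_config(n_individuals = 100, n_markers = 400, seed = 13,
                           residual_founder_het = 0.2)
  pop <- simulate_f2(build_marker_map(cfg), config = cfg)
  n_alleles <- apply(pop$calls, 1L, function(x) {
    length(unique(unlist(strsplit(x[!is.na(x)], ""))))
  })
  expect_gt(sum(n_alleles >= 3), 0)
})

test_that("call degradation masks and miscalls at the configured rates", {
  d <- small_pop()
  # identity when rates are zero
  expect_identical(degrade_calls(d$pop, d$cfg)$calls, d$pop$calls)

  cfg <- d$cfg
  cfg$missing_rate <- 0.2
  deg <- degrade_calls(d$pop, cfg)
  frac <- mean(is.na(deg$calls))
  se <- sqrt(0.2 * 0.8 / length(deg$calls))
  expect_lt(abs(frac - 0.2), 3 * se)
  # causal truth untouched
  expect_identical(deg$causal_geno, d$pop$causal_geno)

  # saturation: everything missing, matrix shape preserved
  cfg$missing_rate <- 1
  sat <- degrade_calls(d$pop, cfg)
  expect_true(all(is.na(sat$calls)))
  expect_equal(dim(sat$calls), dim(d$pop$calls))

  # heterozygote miscalls remove het calls entirely at rate 1
  cfg$missing_rate <- 0
  cfg$het_miscall_rate <- 1
  hm <- degrade_calls(d$pop, cfg)
  a <- substr(hm$calls, 1, 1); b <- substr(hm$calls, 2, 2)
  expect_true(all(a == b, na.rm = TRUE))
})

test_that("phenotype generator reproduces the expected trait structure", {
  d <- small_pop()
  tr <- d$sim$truth
  # recessive reduced-acylation count near n/4 = 32
  expect_lt(abs(sum(tr$reduced_acylation) - 32),
            3 * sqrt(128 * 0.25 * 0.75))
  # class means of acylation percentage
  mut <- tr$acyl_true[tr$reduced_acylation == 1]
  wt <- tr$acyl_true[tr$reduced_acylation == 0]
  expect_lt(abs(mean(mut) - 15.0), 3 * 5 / sqrt(length(mut)))
  expect_lt(abs(mean(wt) - 70.8), 3 * 6 / sqrt(length(wt)))
  # bimodality: classes separated by the 50% cutoff
  expect_true(all(mut < 50) && all(wt > 50))
})

test_that("null phenotype model returns the baseline exactly", {
  cfg <- population_config(n_individuals = 30, n_markers = 20, seed = 2,
                           ac_noise_sd = 0, replicate_cv_pct = 0)
  pop <- simulate_f2(build_marker_map(cfg), config = cfg)
  loci0 <- default_causal_loci()
  loci0$ac_effect <- 0
  pop$loci <- loci0
  sim <- simulate_phenotypes(pop, cfg)
  expect_equal(sim$truth$ac_true, rep(cfg$baseline_ac, 30))
})

test_that("derived traits round-trip the generator truth when noise is off", {
  cfg <- population_config(n_individuals = 40, n_markers = 30, seed = 5,
                           replicate_cv_pct = 0)
  pop <- simulate_f2(build_marker_map(cfg), config = cfg)
  sim <- simulate_phenotypes(pop, cfg)
  der <- derive_phenotypes(sim$peaks, cfg$standard_total_area)
  der <- der[match(sim$truth$sample, der$sample), ]
  expect_equal(der$AC, sim$truth$ac_true, tolerance = 1e-10)
  expect_equal(der$acylation_pct, sim$truth$acyl_true, tolerance = 1e-10)
  expect_equal(der$cv_pct, rep(0, 40), tolerance = 1e-10)
})
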