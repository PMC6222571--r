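test_that("motif patterns match their definitions", {
  rec <- scan_motifs("NYFGNC")
  expect_true(rec$passes_filter)
  expect_equal(rec$hits$motif3$offsets, 0L)

  expect_true(scan_motifs("AYLGNC")$passes_filter)    # leucine variant
  expect_false(scan_motifs("AYWGNC")$passes_filter)   # W not in {F, L}
  expect_true(scan_motifs("XYFGNC")$passes_filter)    # wildcard position
  expect_false(scan_motifs("NYFGNX")$passes_filter)   # X never matches fixed C

  m1 <- scan_motifs("AHQRSDVA")$hits$motif1
  expect_true(m1$present)
  expect_equal(m1$offsets, 1L)
  expect_true(scan_motifs("ADFGWGA")$hits$motif2$present)
  expect_false(scan_motifs("ADFGXGA")$hits$motif2$present)

  empty <- scan_motifs("")
  expect_false(empty$passes_filter)
  expect_equal(empty$hits$motif1$offsets, integer(0))

  # overlapping matches are all reported
  over <- scan_motifs("HAAHDAAD")$hits$motif1   # HAAHD and HDAAD
  expect_equal(over$offsets, c(0L, 3L))
})

test_that("offsets are position-consistent under prefix concatenation", {
  set.seed(14)
  base <- "MKNYFGNCTTDFGWGAAHQRSDV"
  for (k in c(1, 7, 19)) {
    prefix <- paste(sample(c("P", "Q", "R", "S", "T"), k, replace = TRUE),
                    collapse = "")
    r0 <- scan_motifs(base)
    r1 <- scan_motifs(paste0(prefix, base))
    for (m in names(r0$hits)) {
      expect_true(all((r0$hits[[m]]$offsets + k) %in% r1$hits[[m]]$offsets))
    }
  }
})

test_that("synthetic candidate FASTA filters on Motif 3 only", {
  fa <- system.file("extdata", "synthetic_candidates.fasta",
                    package = "anthomap")
  out <- filter_candidates(fa)
  expect_equal(out$passes[out$id == "syn_aat_full"], TRUE)
  expect_equal(out$passes[out$id == "syn_aat_leu"], TRUE)
  expect_equal(out$passes[out$id == "syn_trp_variant"], FALSE)
  expect_equal(out$passes[out$id == "syn_no_motifs"], FALSE)
  expect_equal(out$passes[out$id == "syn_unknown_x"], FALSE)
  # the tryptophan variant still carries the generic BAHD motifs
  expect_true(out$motif1[out$id == "syn_trp_variant"])
  expect_true(out$motif2[out$id == "syn_trp_variant"])
  # reports are 1-based
  expect_equal(out$motif3_pos1[out$id == "syn_aat_full"],
               scan_motifs("NYFGNC")$hits$motif3$offsets[1] +
                 regexpr("NYFGNC", paste0(readLines(fa)[2]))[1])
})

test_that("candidate coordinate table fixture is intact", {
  tsv <- system.file("extdata", "candidate_aats_table.tsv",
                     package = "anthomap")
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 8L)
  hit <- tab[tab$gene_id == "GRMZM2G387394", ]
  expect_equal(hit$chrom, 1L)
  expect_equal(hit$start, 300173138L)
})

test_that("segregation chi-square matches worked examples", {
  ko <- chi_square_segregation(c(14, 11), c(0.5, 0.5))
  expect_equal(ko$statistic, 0.36, tolerance = 1e-12)
  expect_equal(ko$df, 1L)
  expect_equal(round(ko$p_value, 4), 0.5485)

  perfect <- chi_square_segregation(c(25, 25), c(0.5, 0.5))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  f2 <- chi_square_segregation(c(32, 97), c(0.25, 0.75))
  expect_equal(f2$statistic, sum((c(32, 97) - c(32.25, 96.75))^2 /
                                   c(32.25, 96.75)), tolerance = 1e-12)
  expect_equal(f2$p_value, 0.959, tolerance = 1e-3)

  expect_error(chi_square_segregation(c(10, 10), c(0.5, 0.4)), "sum to 1")
  expect_error(chi_square_segregation(c(10, 10), c(1, 0)), "zero")
})

test_that("chi-square approximation tracks the exact binomial tail", {
  # exact multinomial enumeration oracle at N = 12, 1:1 expectation;
  # the continuous approximation is documented as approximate, so only a
  # loose agreement band is asserted
  n <- 12
  probs <- dbinom(0:n, n, 0.5)
  stat_of <- function(k) sum((c(k, n - k) - n / 2)^2 / (n / 2))
  stats_all <- vapply(0:n, stat_of, numeric(1))
  for (k in c(2, 4, 6)) {
    obs <- chi_square_segregation(c(k, n - k), c(0.5, 0.5))
    exact <- sum(probs[stats_all >= obs$statistic - 1e-12])
    expect_lt(abs(obs$p_value - exact), 0.15)
  }
})
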