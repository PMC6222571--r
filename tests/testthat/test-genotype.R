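toy_calls <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("S1_%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

test_that("numeric coding follows the major-allele dosage rule", {
  m <- toy_calls(c("AA", "AG", "GG", "AA"))
  out <- code_numeric(m)
  expect_equal(as.integer(out$codes), c(2L, 1L, 0L, 2L))
  expect_equal(out$maf, 0.375)  # A at 5/8

  # monomorphic site: all major homozygote, maf 0
  mono <- code_numeric(toy_calls(c("AA", "AA", "AA")))
  expect_equal(as.integer(mono$codes), rep(2L, 3))
  expect_equal(mono$maf, 0)

  # tri-allelic site: third-allele homozygote collapses with the minors
  tri <- code_numeric(toy_calls(c("AA", "AC", "TT")))
  expect_equal(as.integer(tri$codes), c(2L, 1L, 0L))

  # call orientation does not matter
  expect_equal(as.integer(code_numeric(toy_calls(c("GA", "AG")))$codes),
               as.integer(code_numeric(toy_calls(c("AG", "GA")))$codes))
})

test_that("all-missing markers are excluded with a warning", {
  m <- toy_calls(c("AA", "AG"), c(NA, NA), c("CC", "CT"))
  expect_warning(out <- code_numeric(m), "missing")
  expect_equal(nrow(out$codes), 2L)
})

test_that("coding is idempotent and invariant to sample order", {
  d <- small_pop()
  calls <- d$pop$calls[1:50, ]
  c1 <- code_numeric(calls)
  c2 <- code_numeric(c1$calls)
  expect_identical(c1$codes, c2$codes)
  perm <- sample(ncol(calls))
  c3 <- code_numeric(calls[, perm])
  expect_identical(c3$codes, c1$codes[, perm])
})

test_that("MAF filter removes below-threshold markers, keeps boundary", {
  # 4/50 het samples -> maf 0.04; 5/50 -> exactly 0.05
  mk_low <- c(rep("AG", 4), rep("AA", 46))
  mk_edge <- c(rep("AG", 5), rep("AA", 45))
  mk_hi <- c(rep("GG", 20), rep("AA", 30))
  m <- toy_calls(mk_low, mk_edge, mk_hi)
  coded <- code_numeric(m)
  pop <- list(calls = coded$calls, codes = coded$codes, maf = coded$maf,
              map = data.frame(marker = rownames(m), chrom = 1,
                               pos = seq_len(3)))
  expect_equal(pop$maf, c(0.04, 0.05, 0.40))
  filt <- filter_maf(pop, 0.05)
  expect_equal(rownames(filt$codes), c("S1_2", "S1_3"))
})

test_that("sample filter drops strictly-above-threshold missingness", {
  d <- small_pop()
  pop <- d$pop
  nm <- nrow(pop$codes)  # 600 markers
  # craft three samples: 81%, 80%, 0% missing
  pop$calls[seq_len(ceiling(0.81 * nm)), 1] <- NA
  pop$calls[seq_len(0.80 * nm), 2] <- NA
  coded <- code_numeric(pop$calls, pop$map)
  pop$codes <- coded$codes; pop$maf <- coded$maf
  filt <- filter_samples_by_missing(pop, 0.80)
  expect_false(pop$samples[1] %in% filt$samples)   # 81% excluded
  expect_true(pop$samples[2] %in% filt$samples)    # exactly 80% retained
  expect_true(pop$samples[3] %in% filt$samples)
  # maf recomputed from surviving samples
  expect_equal(length(filt$maf), nrow(filt$codes))

  # removing every sample is an error, not an empty result
  m <- toy_calls(c(NA, NA), c("AA", NA))
  coded <- code_numeric(m, drop_all_missing = FALSE)
  tiny <- list(calls = coded$calls, codes = coded$codes, maf = coded$maf,
               map = data.frame(marker = rownames(m), chrom = 1, pos = 1:2),
               samples = colnames(m))
  expect_error(filter_samples_by_missing(tiny, 0.2), "threshold")
})

test_that("genotype TSV round-trips codes exactly", {
  d <- small_pop()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(d$pop, tmp)
  back <- read_genotype_tsv(tmp)
  expect_equal(unname(back$codes), unname(d$pop$codes))
  expect_equal(back$map$pos, d$pop$map$pos)
})

test_that("HapMap-like TSV is read and coded", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rs\tchrom\tpos\ts1\ts2\ts3",
               "m1\t1\t100\tAA\tAG\tGG",
               "m2\t2\t200\tCC\tNA\tCT"), tmp)
  hm <- read_hapmap_tsv(tmp)
  expect_equal(as.integer(hm$codes[1, ]), c(2L, 1L, 0L))
  expect_equal(as.integer(hm$codes[2, ]), c(2L, NA, 1L))
})
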