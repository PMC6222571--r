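write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a genotype TSV
#'
#' One row per marker: \code{chrom}, \code{pos} (1-based bp), then one
#' column per sample with calls coded \code{A} (major homozygote),
#' \code{H} (heterozygote), \code{B} (any minor homozygote) or \code{NA}.
#' The A/B orientation is fixed to the major allele at write time so that
#' re-reading the file reproduces the numeric codes exactly.
#'
#' @param pop An \code{f2_population} (needs \code{map}, \code{codes},
#'   \code{samples}).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_genotype_tsv <- function(pop, path) {
  sym <- matrix(c("B", "H", "A")[pop$codes + 1L],
                nrow = nrow(pop$codes),
                dimnames = dimnames(pop$codes))
  df <- data.frame(chrom = pop$map$chrom, pos = pop$map$pos,
                   sym, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("chrom", "pos", pop$samples)
  write_tsv(df, path)
}

#' Read a genotype TSV
#'
#' Reads the dialect written by \code{\link{write_genotype_tsv}}. The format
#' fixes the A symbol to the major allele, so codes decode directly
#' (A = 2, H = 1, B = 0) without re-inferring the major allele — at
#' collapsed multi-allelic sites the true major allele can be rarer than
#' the pooled minors, and recomputing would flip the coding.
#'
#' @param path Input file.
#' @return A population-shaped list with \code{map}, \code{samples},
#'   \code{calls} (symbolic AA/AB/BB), \code{codes}, \code{maf}.
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  samples <- colnames(df)[-(1:2)]
  sym <- as.matrix(df[, -(1:2), drop = FALSE])
  map <- data.frame(marker = sprintf("S%d_%d", df$chrom, df$pos),
                    chrom = df$chrom, pos = df$pos, stringsAsFactors = FALSE)
  codes <- matrix(NA_integer_, nrow(sym), ncol(sym),
                  dimnames = list(map$marker, samples))
  codes[sym == "A"] <- 2L
  codes[sym == "H"] <- 1L
  codes[sym == "B"] <- 0L
  calls <- matrix(c("BB", "AB", "AA")[codes + 1L], nrow(codes), ncol(codes),
                  dimnames = dimnames(codes))
  n_obs <- rowSums(!is.na(codes))
  dead <- n_obs == 0L
  if (any(dead)) {
    warning(sum(dead), " marker(s) with all calls missing excluded",
            call. = FALSE)
    codes <- codes[!dead, , drop = FALSE]
    calls <- calls[!dead, , drop = FALSE]
    map <- map[!dead, , drop = FALSE]
    n_obs <- n_obs[!dead]
  }
  f_a <- rowSums(codes, na.rm = TRUE) / (2 * n_obs)
  list(map = map, samples = samples, calls = calls, codes = codes,
       maf = pmin(f_a, 1 - f_a))
}

#' Read a simplified HapMap-like genotype TSV
#'
#' Columns \code{rs}, \code{chrom}, \code{pos}, then one two-letter call
#' column per sample (e.g. \code{AA}, \code{AG}; \code{NA} missing).
#'
#' @param path Input file.
#' @return A population-shaped list as in \code{\link{read_genotype_tsv}}.
#' @export
read_hapmap_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "NN"))
  samples <- colnames(df)[-(1:3)]
  calls <- as.matrix(df[, -(1:3), drop = FALSE])
  map <- data.frame(marker = df$rs, chrom = df$chrom, pos = df$pos,
                    stringsAsFactors = FALSE)
  dimnames(calls) <- list(map$marker, samples)
  coded <- code_numeric(calls, map)
  list(map = coded$map, samples = samples, calls = coded$calls,
       codes = coded$codes, maf = coded$maf)
}

#' Write a phenotype peak-table TSV
#'
#' One row per sample x replicate with wide compound-area columns, the raw
#' layer from which all derived traits recompute.
#'
#' @param sim A \code{\link{simulate_phenotypes}} result (or a bare peaks
#'   data frame).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_phenotype_tsv <- function(sim, path) {
  peaks <- if (inherits(sim, "phenotype_sim")) sim$peaks else sim
  write_tsv(peaks, path)
}

#' Read a phenotype peak-table TSV
#' @param path Input file.
#' @return Data frame with \code{sample}, \code{replicate} and compound
#'   columns.
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
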