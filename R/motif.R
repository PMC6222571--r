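#' BAHD acyltransferase motif specifications
#'
#' The three diagnostic motifs of BAHD-superfamily acyltransferases:
#' Motif 1 \code{HXXXD} (catalytic histidine/aspartate, three arbitrary
#' residues between), Motif 2 \code{DFGWG} (exact), and the
#' anthocyanin-acyltransferase-specific Motif 3 \code{XY[F/L]GNC} (any
#' single residue, then Y, then F or L, then GNC). Wildcard positions match
#' any residue including the unknown letter X; fixed positions match only
#' their exact residue, so X in a sequence never satisfies a fixed position.
#'
#' @return Named list of motif specs (\code{name}, \code{regex}).
#' @export
default_motifs <- function() {
  list(
    motif1 = list(name = "motif1", regex = "H...D"),
    motif2 = list(name = "motif2", regex = "DFGWG"),
    motif3 = list(name = "motif3", regex = ".Y[FL]GNC"))
}

#' Scan a protein sequence for BAHD motifs
#'
#' Reports every (possibly overlapping) match position of each motif,
#' scanning left to right, and flags whether the sequence passes the
#' candidate filter — presence of the anthocyanin-acyltransferase Motif 3.
#'
#' @param sequence Amino-acid string (standard letters; X allowed as
#'   unknown).
#' @param specs Motif specs as from \code{\link{default_motifs}}.
#' @param id Optional sequence identifier carried on the record.
#' @return List of class \code{"candidate_record"}: \code{id},
#'   \code{hits} (per motif: \code{present} and 0-based \code{offsets})
#'   and \code{passes_filter}. An empty sequence yields no hits and
#'   \code{passes_filter = FALSE}.
#' @examples
#' scan_motifs("NYFGNC")$passes_filter  # TRUE, match at offset 0
#' @export
scan_motifs <- function(sequence, specs = default_motifs(), id = NULL) {
  sequence <- toupper(as.character(sequence))
  hits <- lapply(specs, function(sp) {
    if (nchar(sequence) == 0L) {
      return(list(present = FALSE, offsets = integer(0)))
    }
    m <- gregexpr(paste0("(?=", sp$regex, ")"), sequence, perl = TRUE)[[1L]]
    if (m[1L] == -1L) {
      list(present = FALSE, offsets = integer(0))
    } else {
      list(present = TRUE, offsets = as.integer(m) - 1L)  # 0-based
    }
  })
  names(hits) <- vapply(specs, `[[`, character(1), "name")
  passes <- isTRUE(hits[["motif3"]]$present)
  structure(list(id = id, hits = hits, passes_filter = passes),
            class = "candidate_record")
}

#' Filter candidate proteins by the Motif-3 criterion
#'
#' Reads protein sequences (FASTA path or \code{Biostrings::AAStringSet}),
#' scans each for the BAHD motifs and returns one row per sequence with
#' motif presence, the first Motif-3 offset (1-based in this human-readable
#' report), and the pass flag.
#'
#' @param sequences FASTA file path or an \code{AAStringSet}.
#' @param specs Motif specs, see \code{\link{default_motifs}}.
#' @return Data frame with \code{id}, \code{motif1}, \code{motif2},
#'   \code{motif3} (logical), \code{motif3_pos1} (1-based first offset or
#'   NA) and \code{passes}.
#' @export
filter_candidates <- function(sequences, specs = default_motifs()) {
  if (is.character(sequences) && length(sequences) == 1L) {
    sequences <- Biostrings::readAAStringSet(sequences)
  }
  seqs <- as.character(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  ids <- sub("\\s.*$", "", ids)
  rows <- lapply(seq_along(seqs), function(i) {
    rec <- scan_motifs(seqs[[i]], specs, id = ids[i])
    off3 <- rec$hits[["motif3"]]$offsets
    data.frame(id = ids[i],
               motif1 = rec$hits[["motif1"]]$present,
               motif2 = rec$hits[["motif2"]]$present,
               motif3 = rec$hits[["motif3"]]$present,
               motif3_pos1 = if (length(off3)) off3[1L] + 1L else NA_integer_,
               passes = rec$passes_filter,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square goodness-of-fit for a segregation ratio
#'
#' Tests observed category counts against an expected segregation ratio
#' (e.g. 1:1 for a testcross of a heterozygous insertion, 1:3 for an F2
#' recessive class): \eqn{\chi^2 = \sum (O_i - E_i)^2 / E_i} with
#' \eqn{E_i = N p_i}, df = categories - 1, upper-tail p-value.
#'
#' @param observed Non-negative integer counts, summing to >= 1.
#' @param expected_ratio Expected proportions, summing to 1.
#' @return List with \code{statistic}, \code{df} and \code{p_value}.
#' @examples
#' chi_square_segregation(c(14, 11), c(0.5, 0.5))$p_value  # 0.5485
#' @export
chi_square_segregation <- function(observed, expected_ratio) {
  stopifnot(length(observed) == length(expected_ratio),
            all(observed >= 0), sum(observed) >= 1)
  if (abs(sum(expected_ratio) - 1) > 1e-8) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  expected <- sum(observed) * expected_ratio
  if (any(expected == 0)) {
    stop("invalid expectation: expected count of zero", call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Expected homozygous-recessive count in an F2 population
#'
#' @param n Population size.
#' @param proportion Expected recessive-class proportion (default 1/4 for a
#'   single recessive locus).
#' @return Rounded expected count.
#' @examples
#' expected_recessive_count(129)  # 32
#' @export
expected_recessive_count <- function(n, proportion = 0.25) {
  round(n * proportion)
}
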