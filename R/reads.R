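# Read ingestion, primer trimming and length filtering. Reads live in a
# plain data.frame (read_id, sequence, quality) so every stage is easy to
# construct in tests; FASTQ I/O goes through Biostrings.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (plain or gzip).
#' @return `data.frame` with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  data.frame(read_id = names(x), sequence = as.character(x),
             quality = as.character(q), row.names = NULL)
}

#' Write a read table to FASTQ
#'
#' @param reads Read table (`read_id`, `sequence`, optional `quality`).
#' @param path Output path (`.gz` for compressed).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- if (!is.null(reads$quality)) Biostrings::BStringSet(reads$quality)
       else Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Which primer (if any) matches the given end windows within budget;
# fewer mismatches wins, forward on a tie.
.pick_primer <- function(mm_f, mm_r, budget) {
  ok_f <- !is.na(mm_f) & mm_f <= budget
  ok_r <- !is.na(mm_r) & mm_r <= budget
  out <- rep("none", length(mm_f))
  out[ok_f] <- "fwd"
  out[ok_r & !ok_f] <- "rev"
  both <- ok_f & ok_r
  out[both & mm_r < mm_f] <- "rev"
  out
}

.end_mismatches <- function(primer, windows, long_enough) {
  mm <- rep(NA_integer_, length(windows))
  if (any(long_enough))
    mm[long_enough] <- .hamming_iupac(primer, windows[long_enough])
  mm
}

#' Trim primer sequences from read ends
#'
#' Amplicon reads start from either primer (the protocol is unstranded), so
#' each read end is checked against both primers: the 5' end against the
#' forward and reverse primers as written, the 3' end against their reverse
#' complements. A primer is trimmed when it matches within `budget`
#' IUPAC-aware mismatches; when both primers match an end, the one with
#' fewer mismatches wins (forward on a tie). Reads may be trimmed at 0, 1,
#' or 2 ends.
#'
#' @param reads Read table.
#' @param primers A [primer_pair()].
#' @param budget Mismatches tolerated when locating a primer at a read end.
#' @return The read table with updated `sequence`/`quality` plus report
#'   columns `trimmed_5p` and `trimmed_3p` (`"none"`, `"fwd"` or `"rev"`).
#' @export
trim_primers <- function(reads, primers, budget = 1L) {
  stopifnot(inherits(primers, "primer_pair"))
  seqs <- toupper(reads$sequence)
  lens <- nchar(seqs)
  qual <- reads$quality
  lf <- nchar(primers$forward)
  lr <- nchar(primers$reverse)

  # 5' end: primers as written
  mm_f <- .end_mismatches(primers$forward, substr(seqs, 1L, lf), lens >= lf)
  mm_r <- .end_mismatches(primers$reverse, substr(seqs, 1L, lr), lens >= lr)
  t5 <- .pick_primer(mm_f, mm_r, budget)
  cut5 <- ifelse(t5 == "fwd", lf, ifelse(t5 == "rev", lr, 0L))
  seqs <- substr(seqs, cut5 + 1L, lens)
  if (!is.null(qual)) qual <- substr(qual, cut5 + 1L, lens)
  lens <- nchar(seqs)

  # 3' end: reverse complements
  mm_f <- .end_mismatches(.revcomp_chr(primers$forward),
                          substr(seqs, pmax(lens - lf + 1L, 1L), lens),
                          lens >= lf)
  mm_r <- .end_mismatches(.revcomp_chr(primers$reverse),
                          substr(seqs, pmax(lens - lr + 1L, 1L), lens),
                          lens >= lr)
  t3 <- .pick_primer(mm_f, mm_r, budget)
  cut3 <- ifelse(t3 == "fwd", lf, ifelse(t3 == "rev", lr, 0L))
  seqs <- substr(seqs, 1L, lens - cut3)
  if (!is.null(qual)) qual <- substr(qual, 1L, lens - cut3)

  out <- reads
  out$sequence <- seqs
  if (!is.null(qual)) out$quality <- qual
  out$trimmed_5p <- t5
  out$trimmed_3p <- t3
  out
}

#' Filter reads by post-trim length
#'
#' Keeps reads whose (post-trim) length is strictly greater than
#' `min_len_exclusive` (default 135, i.e. "reads > 135 bp").
#'
#' @param reads Read table.
#' @param min_len_exclusive Exclusive length floor in bp.
#' @return List with `kept` (read table) and `dropped` (count).
#' @export
length_filter <- function(reads, min_len_exclusive = 135L) {
  stopifnot(min_len_exclusive >= 0L)
  keep <- nchar(reads$sequence) > min_len_exclusive
  list(kept = reads[keep, , drop = FALSE], dropped = sum(!keep))
}
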