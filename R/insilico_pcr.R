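# In-silico PCR: enumerate genomic segments delimited by a degenerate primer
# pair. Candidate primer sites come from Biostrings::matchPattern (pattern
# ambiguities treated as wildcards, subject literal); the 3'-protection rule,
# site orientation, pairing and locus labelling are applied on top.

#' Parameters for the in-silico PCR scan
#'
#' @param min_amplicon_len,max_amplicon_len Amplicon length window in bp
#'   (primer-inclusive).
#' @param both_strands Also report amplicons whose forward primer binds the
#'   minus strand.
#' @return An object of class `pcr_scan_params`.
#' @export
pcr_scan_params <- function(min_amplicon_len = 100L, max_amplicon_len = 2000L,
                            both_strands = TRUE) {
  min_amplicon_len <- as.integer(min_amplicon_len)
  max_amplicon_len <- as.integer(max_amplicon_len)
  if (!(min_amplicon_len > 0L && min_amplicon_len <= max_amplicon_len))
    stop("need 0 < min_amplicon_len <= max_amplicon_len")
  structure(list(min_amplicon_len = min_amplicon_len,
                 max_amplicon_len = max_amplicon_len,
                 both_strands = isTRUE(both_strands)),
            class = "pcr_scan_params")
}

.as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    x <- Biostrings::DNAStringSet(genome)
    if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
    return(x)
  }
  stop("genome must be a DNAStringSet, a FASTA path, or named sequences")
}

# All sites on the plus-strand text where `primer` binds in the given
# orientation. orient = "forward": the window itself reads along the primer.
# orient = "revcomp": the window is the reverse complement of the primer
# footprint (primer binds the other strand here).
.primer_sites <- function(primer, subject, max_mm, protect, orient) {
  pat <- Biostrings::DNAString(primer)
  if (orient == "revcomp") pat <- Biostrings::reverseComplement(pat)
  m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm,
                                fixed = c(pattern = FALSE, subject = TRUE))
  if (length(m) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  st <- Biostrings::start(m); en <- Biostrings::end(m)
  keep <- st >= 1L & en <= length(subject)
  st <- st[keep]; en <- en[keep]
  win <- as.character(Biostrings::extractAt(
    subject, IRanges::IRanges(start = st, end = en)))
  if (orient == "revcomp") win <- .revcomp_chr(win)
  mm <- vapply(win, function(w)
    match_primer(primer, w, max_mm, protect), integer(1), USE.NAMES = FALSE)
  ok <- !is.na(mm)
  # 0-based half-open coordinates
  data.frame(start = st[ok] - 1L, end = en[ok], mismatches = mm[ok])
}

#' Enumerate candidate amplicon loci by in-silico PCR
#'
#' Scans every sequence of `genome` for sites of the forward and reverse
#' primers (either may carry up to `primers$max_mismatches` mismatches, none
#' within the protected 3' bases) and reports every correctly oriented pair
#' whose implied amplicon length falls within the scan window. Overlapping
#' and nested amplicons are all reported. Coordinates are 0-based half-open;
#' the amplicon sequence is reported on the strand the forward primer binds
#' and includes both primer footprints. Locus identifiers are assigned
#' per-chromosome in coordinate order as `<chrom>-<k>`.
#'
#' @param genome A `DNAStringSet`, FASTA path, or named character vector.
#' @param primers A [primer_pair()].
#' @param params A [pcr_scan_params()].
#' @return A `data.frame` with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `sequence`, `fwd_mismatches`, `rev_mismatches`.
#' @export
find_amplicons <- function(genome, primers, params = pcr_scan_params()) {
  stopifnot(inherits(primers, "primer_pair"),
            inherits(params, "pcr_scan_params"))
  genome <- .as_dnastringset(genome)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("genome is empty")
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))

  mm <- primers$max_mismatches
  pr <- primers$three_prime_protected
  out <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    s <- genome[[ci]]
    fwd_p <- .primer_sites(primers$forward, s, mm, pr, "forward")
    rcr_p <- .primer_sites(primers$reverse, s, mm, pr, "revcomp")
    # plus-strand amplicons: forward site ... revcomp(reverse) site
    if (nrow(fwd_p) > 0L && nrow(rcr_p) > 0L) {
      g <- expand.grid(f = seq_len(nrow(fwd_p)), r = seq_len(nrow(rcr_p)))
      len <- rcr_p$end[g$r] - fwd_p$start[g$f]
      ok <- len >= params$min_amplicon_len & len <= params$max_amplicon_len &
        rcr_p$start[g$r] >= fwd_p$end[g$f]
      if (any(ok)) {
        f <- g$f[ok]; r <- g$r[ok]
        seqs <- as.character(Biostrings::extractAt(
          s, IRanges::IRanges(start = fwd_p$start[f] + 1L, end = rcr_p$end[r])))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = fwd_p$start[f], end = rcr_p$end[r],
          strand = "+", sequence = seqs,
          fwd_mismatches = fwd_p$mismatches[f],
          rev_mismatches = rcr_p$mismatches[r])
      }
    }
    if (params$both_strands) {
      rev_f <- .primer_sites(primers$reverse, s, mm, pr, "forward")
      rcf <- .primer_sites(primers$forward, s, mm, pr, "revcomp")
      # minus-strand amplicons: reverse site ... revcomp(forward) site;
      # the product's top strand is the genome minus strand
      if (nrow(rev_f) > 0L && nrow(rcf) > 0L) {
        g <- expand.grid(a = seq_len(nrow(rev_f)), b = seq_len(nrow(rcf)))
        len <- rcf$end[g$b] - rev_f$start[g$a]
        ok <- len >= params$min_amplicon_len & len <= params$max_amplicon_len &
          rcf$start[g$b] >= rev_f$end[g$a]
        if (any(ok)) {
          a <- g$a[ok]; b <- g$b[ok]
          seqs <- .revcomp_chr(as.character(Biostrings::extractAt(
            s, IRanges::IRanges(start = rev_f$start[a] + 1L,
                                end = rcf$end[b]))))
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = rev_f$start[a], end = rcf$end[b],
            strand = "-", sequence = seqs,
            fwd_mismatches = rcf$mismatches[b],
            rev_mismatches = rev_f$mismatches[a])
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0)))
  }
  amp <- do.call(rbind, out)
  chrom_order <- match(amp$chrom, names(genome))
  amp <- amp[order(chrom_order, amp$start, amp$end, amp$strand), , drop = FALSE]
  ord <- stats::ave(seq_len(nrow(amp)), amp$chrom, FUN = seq_along)
  amp <- cbind(locus_id = sprintf("%s-%d", amp$chrom, ord), amp)
  rownames(amp) <- NULL
  amp
}

#' Write amplicon loci as BED6
#'
#' Score column carries the total primer mismatch count.
#'
#' @param amplicons Output of [find_amplicons()].
#' @param path Output file.
#' @export
write_amplicon_bed <- function(amplicons, path) {
  bed <- data.frame(amplicons$chrom, amplicons$start, amplicons$end,
                    amplicons$locus_id,
                    amplicons$fwd_mismatches + amplicons$rev_mismatches,
                    amplicons$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write amplicon sequences as FASTA
#'
#' @param amplicons Output of [find_amplicons()].
#' @param path Output file.
#' @export
write_amplicon_fasta <- function(amplicons, path) {
  x <- Biostrings::DNAStringSet(amplicons$sequence)
  names(x) <- amplicons$locus_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
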