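# Per-locus counting and relative frequencies.

#' Count mapped reads per amplicon locus
#'
#' A mapped hit counts toward a locus iff its reference span overlaps the
#' locus interval by at least `min_overlap` of the read's aligned span
#' (strand is ignored: cDNA amplicons read from either strand). Hits
#' overlapping no locus — including hits on chromosomes without loci —
#' increment the per-sample off-target tally. When a hit passes the
#' threshold for several (overlapping) loci, the largest overlap wins, with
#' locus order breaking exact ties.
#'
#' @param hits Output of [map_reads()] with an added `sample` column
#'   (unmapped rows are tallied as `unmapped`).
#' @param loci Locus table ([find_amplicons()] output or the generator's
#'   truth loci): `locus_id`, `chrom`, `start`, `end`.
#' @param sample_levels Optional sample ordering.
#' @param min_overlap Minimum overlapping fraction of the aligned span.
#' @return An object of class `locus_counts`: list with `counts` (integer
#'   matrix, loci x samples), `loci`, and `samples` (per-sample `mapped`,
#'   `on_target`, `off_target`, `unmapped` tallies).
#' @export
assign_to_loci <- function(hits, loci, sample_levels = NULL,
                           min_overlap = 0.9) {
  stopifnot(!is.null(hits$sample))
  if (is.null(sample_levels)) sample_levels <- unique(hits$sample)
  m <- hits[hits$mapped %in% TRUE, , drop = FALSE]

  locus_of <- rep(NA_character_, nrow(m))
  if (nrow(m) > 0L && nrow(loci) > 0L) {
    hg <- GenomicRanges::GRanges(m$chrom,
                                 IRanges::IRanges(m$start + 1L, m$end))
    lg <- GenomicRanges::GRanges(loci$chrom,
                                 IRanges::IRanges(loci$start + 1L, loci$end))
    ov <- GenomicRanges::findOverlaps(hg, lg, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(IRanges::ranges(hg)[qh],
                                              IRanges::ranges(lg)[sh]))
      frac <- w / IRanges::width(IRanges::ranges(hg)[qh])
      keep <- frac >= min_overlap
      qh <- qh[keep]; sh <- sh[keep]; w <- w[keep]
      if (length(qh) > 0L) {
        # best overlap per hit; earlier locus wins exact ties
        o <- order(qh, -w, sh)
        qh <- qh[o]; sh <- sh[o]
        firsts <- !duplicated(qh)
        locus_of[qh[firsts]] <- loci$locus_id[sh[firsts]]
      }
    }
  }

  sample_f <- factor(m$sample, levels = sample_levels)
  locus_f <- factor(locus_of, levels = loci$locus_id)
  counts <- table(locus_f, sample_f, useNA = "no")
  counts <- matrix(as.integer(counts), nrow = nrow(loci),
                   dimnames = list(loci$locus_id, sample_levels))

  all_f <- factor(hits$sample, levels = sample_levels)
  mapped <- as.integer(table(all_f[hits$mapped %in% TRUE]))
  total <- as.integer(table(all_f))
  on_target <- colSums(counts)
  samples <- data.frame(sample = sample_levels, n_reads = total,
                        mapped = mapped, on_target = as.integer(on_target),
                        off_target = mapped - as.integer(on_target),
                        unmapped = total - mapped, row.names = NULL)
  structure(list(counts = counts, loci = loci, samples = samples),
            class = "locus_counts")
}

#' @export
print.locus_counts <- function(x, ...) {
  cat(sprintf("locus_counts: %d loci x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  mapped %d | on-target %d | off-target %d | unmapped %d\n",
              sum(x$samples$mapped), sum(x$samples$on_target),
              sum(x$samples$off_target), sum(x$samples$unmapped)))
  invisible(x)
}

#' Convert locus counts to per-sample relative frequencies (%)
#'
#' `denominator = "on_target"` divides by the sum of counted locus reads
#' (columns then sum to exactly 100); `"all_mapped"` divides by all mapped
#' reads including off-target hits.
#'
#' @param lc A `locus_counts` object.
#' @param denominator `"on_target"` or `"all_mapped"`.
#' @return Numeric matrix of percentages (attribute `denominator` records
#'   the choice). Samples with a zero denominator get `NA` frequencies with
#'   a warning.
#' @export
to_frequencies <- function(lc, denominator = c("on_target", "all_mapped")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(lc, "locus_counts"))
  den <- if (denominator == "on_target") lc$samples$on_target
         else lc$samples$mapped
  if (any(den == 0L)) {
    warning("zero ", denominator, " total for sample(s): ",
            paste(lc$samples$sample[den == 0L], collapse = ", "),
            "; frequencies set to NA")
  }
  den2 <- ifelse(den == 0L, NA_real_, as.numeric(den))
  fr <- sweep(lc$counts, 2L, den2, "/") * 100
  attr(fr, "denominator") <- denominator
  fr
}

#' Exclude loci with too many low-count samples
#'
#' A locus is excluded iff the number of samples with a raw count below
#' `min_count` is strictly greater than `sample_fraction` of the samples
#' ("less than 1 raw count in more than 50% of samples" at the defaults).
#'
#' @param counts A `locus_counts` object or a counts matrix (loci x samples).
#' @param min_count Raw-count floor.
#' @param sample_fraction Fraction of samples allowed below the floor.
#' @return List with `retained` and `excluded` locus id vectors.
#' @export
low_count_filter <- function(counts, min_count = 1L, sample_fraction = 0.5) {
  m <- if (inherits(counts, "locus_counts")) counts$counts else counts
  low <- rowSums(m < min_count)
  excl <- low > sample_fraction * ncol(m)
  list(retained = rownames(m)[!excl], excluded = rownames(m)[excl])
}
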