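# End-to-end ("no soft clipping") read alignment. The DP core lives in
# src/align.cpp; this file defines scoring, acceptance, tie policy and the
# genome-scale mapper wrapper.

#' Alignment scoring scheme
#'
#' Match +1, mismatch -10, gap -10 per gap base (linear; no separate
#' gap-open term). `min_accept_score = NULL` selects the default acceptance
#' rule `read_length - 33`, i.e. at most three penalized events (each
#' substitution or gap base forfeits a +1 match and incurs -10).
#'
#' @param match,mismatch,gap Per-base scores.
#' @param min_accept_score Integer threshold for calling a read mapped, or
#'   `NULL` for the read-length-dependent default.
#' @return An object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -10L, gap = -10L,
                              min_accept_score = NULL) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap <- as.integer(gap)
  if (!(match > 0L && mismatch < 0L && gap < 0L))
    stop("need match > 0, mismatch < 0, gap < 0")
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 min_accept_score = min_accept_score),
            class = "alignment_scoring")
}

.accept_threshold <- function(scoring, read_len) {
  if (is.null(scoring$min_accept_score)) read_len - 33L
  else scoring$min_accept_score
}

#' Decide whether an alignment score qualifies as mapped
#'
#' @param score Alignment score(s).
#' @param read_len Read length(s) (post-trim).
#' @param scoring An [alignment_scoring()].
#' @return Logical vector: `TRUE` = mapped.
#' @export
accept_hit <- function(score, read_len, scoring = alignment_scoring()) {
  score >= .accept_threshold(scoring, read_len)
}

#' Glocal alignment of one read against one reference sequence
#'
#' Dynamic programming in which the full read must align (global in the
#' read) starting at any reference position (local in the reference); every
#' read base is scored, so there is no soft clipping. Returns all positions
#' achieving the maximum score, on both strands unless `both_strands =
#' FALSE`. Coordinates are 0-based half-open on the given reference.
#'
#' @param read,reference Nucleotide strings.
#' @param scoring An [alignment_scoring()].
#' @param both_strands Also align the reverse complement of the read.
#' @return `data.frame` with columns `start`, `end`, `strand`, `score`,
#'   `mismatches`, `gap_bases`, `aligned_ref_span`; zero rows if nothing
#'   aligns (e.g. read much longer than the reference).
#' @export
align_read_glocal <- function(read, reference,
                              scoring = alignment_scoring(),
                              both_strands = TRUE) {
  read <- toupper(read); reference <- toupper(reference)
  hit_p <- glocal_align_cpp(read, reference, scoring$match,
                            scoring$mismatch, scoring$gap)
  hit_p$strand <- rep("+", nrow(hit_p))
  hits <- hit_p
  if (both_strands) {
    hit_m <- glocal_align_cpp(.revcomp_chr(read), reference, scoring$match,
                              scoring$mismatch, scoring$gap)
    hit_m$strand <- rep("-", nrow(hit_m))
    hits <- rbind(hits, hit_m)
  }
  if (nrow(hits) == 0L) return(.empty_hits())
  best <- max(hits$score)
  hits <- hits[hits$score == best, , drop = FALSE]
  hits$aligned_ref_span <- hits$end - hits$start
  rownames(hits) <- NULL
  hits[, c("start", "end", "strand", "score", "mismatches", "gap_bases",
           "aligned_ref_span")]
}

.empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             score = integer(0), mismatches = integer(0),
             gap_bases = integer(0), aligned_ref_span = integer(0))
}

#' Resolve equal-best alignment hits by a seeded per-read draw
#'
#' Implements the "random among best hits" policy: a uniform choice driven
#' by a hash of `(seed, read_id)`, so the choice is reproducible read by
#' read and independent of input order.
#'
#' @param hits `data.frame` of equal-score hits (one read).
#' @param seed Integer seed.
#' @param read_id Read identifier keying the draw.
#' @return A single-row `data.frame`.
#' @export
resolve_ties <- function(hits, seed, read_id) {
  n <- nrow(hits)
  if (is.null(n) || n == 0L) stop("resolve_ties requires a non-empty hit set")
  if (length(unique(hits$score)) > 1L)
    stop("resolve_ties requires equal-score hits")
  if (n == 1L) return(hits)
  u <- tie_hash_cpp(as.character(read_id), as.integer(seed))
  idx <- 1L + as.integer(floor(u * n))
  if (idx > n) idx <- n
  hits[idx, , drop = FALSE]
}

#' Map reads to a genome
#'
#' Seeded glocal mapping of every read (both orientations) against all
#' genome sequences. Seeding splits each read into `n_chunks` disjoint
#' chunks and anchors candidate windows at exact k-mer matches; by the
#' pigeonhole principle every placement with at most `n_chunks - 1`
#' penalized events is found, which covers all placements at or above the
#' default acceptance threshold. Equal best hits are resolved by
#' [resolve_ties()] keyed on `(seed, read_id)`.
#'
#' @param reads Read table (`read_id`, `sequence`).
#' @param genome `DNAStringSet`, FASTA path, or named character vector.
#' @param scoring An [alignment_scoring()].
#' @param seed Integer seed for the tie draw.
#' @param n_chunks Seeding chunks per read (event budget + 1).
#' @param k Seed k-mer length (<= 31).
#' @param band Diagonal slack for candidate windows, in bp.
#' @return `data.frame` with one row per read: `read_id`, `chrom`, `start`,
#'   `end`, `strand`, `score`, `mismatches`, `gap_bases`, `n_best`,
#'   `mapped`. Reads with no alignment or a best score below the acceptance
#'   threshold have `mapped = FALSE` (coordinates `NA` when nothing aligned).
#' @export
map_reads <- function(reads, genome, scoring = alignment_scoring(),
                      seed = 1L, n_chunks = 4L, k = 31L, band = 8L) {
  genome <- .as_dnastringset(genome)
  seqs <- toupper(reads$sequence)
  raw <- map_reads_cpp(seqs, as.character(genome),
                       scoring$match, scoring$mismatch, scoring$gap,
                       as.integer(n_chunks), as.integer(k), as.integer(band))
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)

  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id,
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    score = NA_integer_, mismatches = NA_integer_,
                    gap_bases = NA_integer_, n_best = 0L, mapped = FALSE,
                    row.names = NULL)
  if (nrow(raw) > 0L) {
    # rows are grouped by read; pick one hit per read via the tie hash
    first <- which(!duplicated(raw$read))
    ridx <- raw$read[first]
    nbest <- raw$n_best[first]
    u <- tie_hash_cpp(as.character(reads$read_id[ridx]), as.integer(seed))
    off <- as.integer(floor(u * nbest))
    off[off >= nbest] <- nbest - 1L
    pick <- first + ifelse(nbest > 1L, off, 0L)
    sel <- raw[pick, , drop = FALSE]
    out$chrom[ridx] <- names(genome)[sel$chrom]
    out$start[ridx] <- sel$start
    out$end[ridx] <- sel$end
    out$strand[ridx] <- sel$strand
    out$score[ridx] <- sel$score
    out$mismatches[ridx] <- sel$mismatches
    out$gap_bases[ridx] <- sel$gap_bases
    out$n_best[ridx] <- nbest
  }
  out$mapped <- !is.na(out$score) &
    accept_hit(out$score, nchar(seqs), scoring)
  out
}

#' Per-sample alignment quality summary
#'
#' Accumulated mismatch percentage over mapped reads (total mismatching
#' bases / total aligned read bases), plus mapped and gapped-read tallies.
#' Reported as a QC metric, not applied as a filter.
#'
#' @param hits Output of [map_reads()] (optionally with a `sample` column).
#' @param read_len Read lengths matching `hits` rows.
#' @return One-row `data.frame` (or one row per sample).
#' @export
alignment_qc <- function(hits, read_len) {
  grp <- if (!is.null(hits$sample)) hits$sample else rep("all", nrow(hits))
  m <- hits$mapped
  agg <- function(g) {
    i <- m & grp == g
    data.frame(sample = g, n_reads = sum(grp == g), n_mapped = sum(i),
               mismatch_pct = if (any(i))
                 100 * sum(hits$mismatches[i]) / sum(read_len[i]) else NA_real_,
               gapped_reads = sum(hits$gap_bases[i] > 0, na.rm = TRUE))
  }
  do.call(rbind, lapply(unique(grp), agg))
}
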