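# Independent oracles used to cross-check the implementation.

oracle_revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(strsplit(x, NULL), function(ch)
           paste(rev(ch), collapse = ""), character(1)))
}

# Naive all-positions in-silico PCR scan: every window of the genome is
# tested against both primers in both orientations with match_primer, and
# all correctly oriented pairs within the length window are reported.
oracle_primer_sites <- function(primer, s, mm, protect, orient) {
  L <- nchar(primer)
  n <- nchar(s)
  res <- list()
  if (n >= L) {
    for (i in seq_len(n - L + 1L)) {
      w <- substr(s, i, i + L - 1L)
      if (orient == "revcomp") w <- oracle_revcomp(w)
      m <- match_primer(primer, w, mm, protect)
      if (!is.na(m))
        res[[length(res) + 1L]] <- c(start = i - 1L, end = i + L - 1L,
                                     mismatches = m)
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  as.data.frame(do.call(rbind, res))
}

oracle_find_amplicons <- function(genome, primers, params) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else seqs <- genome
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  mm <- primers$max_mismatches
  pr <- primers$three_prime_protected
  out <- list()
  for (chrom in names(seqs)) {
    s <- seqs[[chrom]]
    fwd <- oracle_primer_sites(primers$forward, s, mm, pr, "forward")
    rcr <- oracle_primer_sites(primers$reverse, s, mm, pr, "revcomp")
    for (f in seq_len(nrow(fwd))) for (r in seq_len(nrow(rcr))) {
      len <- rcr$end[r] - fwd$start[f]
      if (len >= params$min_amplicon_len && len <= params$max_amplicon_len &&
          rcr$start[r] >= fwd$end[f])
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = fwd$start[f], end = rcr$end[r], strand = "+")
    }
    if (params$both_strands) {
      rev <- oracle_primer_sites(primers$reverse, s, mm, pr, "forward")
      rcf <- oracle_primer_sites(primers$forward, s, mm, pr, "revcomp")
      for (a in seq_len(nrow(rev))) for (b in seq_len(nrow(rcf))) {
        len <- rcf$end[b] - rev$start[a]
        if (len >= params$min_amplicon_len &&
            len <= params$max_amplicon_len && rcf$start[b] >= rev$end[a])
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = rev$start[a], end = rcf$end[b],
            strand = "-")
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  res <- do.call(rbind, out)
  res[order(match(res$chrom, names(seqs)), res$start, res$end, res$strand), ,
      drop = FALSE]
}

# Brute-force glocal score: best over all ungapped placements plus all
# placements with a single gap run (insertion or deletion, up to max_gap
# bases), via cumulative mismatch arrays. Read fully inside the reference.
oracle_glocal_score <- function(read, ref, match = 1, mismatch = -10,
                                gap = -10, max_gap = 3) {
  r <- utf8ToInt(read)
  g <- utf8ToInt(ref)
  L <- length(r)
  G <- length(g)
  if (L > G) stop("oracle requires read <= ref")
  offs <- 0:(G - L)
  M <- t(vapply(offs, function(o)
    c(0L, cumsum(r != g[(o + 1):(o + L)])), integer(L + 1)))
  sc <- function(nalign, mm, gapb)
    (nalign - mm) * match + mm * mismatch + gapb * gap
  best <- max(sc(L, M[, L + 1], 0))
  for (gd in seq_len(max_gap)) {
    # deletion run: ref consumes L + gd bases
    o_ok <- which(offs + L + gd <= G)
    if (length(o_ok)) {
      for (k in 0:L) {
        mm <- M[o_ok, k + 1] + (M[o_ok + gd, L + 1] - M[o_ok + gd, k + 1])
        best <- max(best, sc(L, mm, gd))
      }
    }
    # insertion run: gd read bases unaligned
    if (gd < L) {
      o_ok <- which(offs - gd >= 0)
      for (k in 0:(L - gd)) {
        mm <- M[o_ok, k + 1] +
          (M[o_ok - gd, L + 1] - M[o_ok - gd, k + gd + 1])
        best <- max(best, sc(L - gd, mm, gd))
      }
    }
  }
  best
}

# Exhaustive edit-path enumeration for tiny cases: depth-first recursion
# over all monotone alignments with at most `max_gap` gap bases, free
# reference prefix (start offset loop) and suffix (stop when the read is
# consumed). Independent of any DP recurrence cache.
oracle_glocal_exhaustive <- function(read, ref, match = 1, mismatch = -10,
                                     gap = -10, max_gap = 3) {
  r <- utf8ToInt(read)
  g <- utf8ToInt(ref)
  L <- length(r)
  G <- length(g)
  rec <- function(i, j, left) {
    if (i > L) return(0)
    best <- -Inf
    if (j <= G) {
      s <- if (r[i] == g[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, left))
    }
    if (left > 0L) {
      best <- max(best, gap + rec(i + 1L, j, left - 1L))      # read base gapped
      if (j <= G)
        best <- max(best, gap + rec(i, j + 1L, left - 1L))    # ref base gapped
    }
    best
  }
  best <- -Inf
  for (s in 0:G) best <- max(best, rec(1L, s + 1L, max_gap))
  best
}

# Brute-force Benjamini-Hochberg: p_adj for the i-th smallest p is
# min over j >= i of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# NB counts fixture for the DE calibration experiments: log-normal
# baseline means, common dispersion, optional per-locus fold on group 2.
make_nb_counts <- function(n_loci, n_per_group, mu_log = log(100),
                           mu_sd = 1, dispersion = 0.05, fold = NULL) {
  mu <- exp(rnorm(n_loci, mu_log, mu_sd))
  f <- if (is.null(fold)) rep(1, n_loci) else fold
  c1 <- matrix(rnbinom(n_loci * n_per_group, mu = rep(mu, n_per_group),
                       size = 1 / dispersion), n_loci, n_per_group)
  c2 <- matrix(rnbinom(n_loci * n_per_group, mu = rep(mu * f, n_per_group),
                       size = 1 / dispersion), n_loci, n_per_group)
  m <- cbind(c1, c2)
  rownames(m) <- paste0("locus", seq_len(n_loci))
  colnames(m) <- c(paste0("ctrl", seq_len(n_per_group)),
                   paste0("case", seq_len(n_per_group)))
  m
}
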