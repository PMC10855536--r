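# Fixture builders (all data generated in code, seeded).

FIX_FWD <- "GACCTGAGCGTTAAGCTTGC"
FIX_REV <- "TTGACGCGTTAGGCTCATCC"

fix_primers <- function(...) primer_pair(FIX_FWD, FIX_REV, ...)

rand_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# A single chromosome with exact primer-site pairs planted at the given
# start positions, each spanning an insert of `insert_len` background bases.
plant_genome <- function(total_len, starts, insert_len = 160,
                         primers = fix_primers()) {
  bg <- rand_dna(total_len)
  lf <- nchar(primers$forward)
  lr <- nchar(primers$reverse)
  amp_len <- lf + insert_len + lr
  rcr <- oracle_revcomp(primers$reverse)
  loci <- data.frame(start = integer(0), end = integer(0))
  for (s in starts) {
    amp <- paste0(primers$forward, rand_dna(insert_len), rcr)
    substr(bg, s + 1, s + amp_len) <- amp
    loci <- rbind(loci, data.frame(start = s, end = s + amp_len))
  }
  list(genome = c(chr1 = bg), loci = loci, amp_len = amp_len)
}

# A planted read: substring of the reference with optional substitutions
# and one indel run, for aligner oracle checks.
planted_read <- function(ref, len, n_sub = 0, indel = 0) {
  G <- nchar(ref)
  s <- sample(G - len - abs(indel), 1)
  r <- substr(ref, s + 1, s + len)
  if (n_sub > 0) {
    pos <- sample(len, n_sub)
    for (i in pos) {
      old <- substr(r, i, i)
      substr(r, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  if (indel > 0) { # deletion from the read (reference keeps the bases)
    k <- sample(len - indel - 2, 1) + 1
    r <- paste0(substr(r, 1, k), substr(r, k + indel + 1, len))
  } else if (indel < 0) { # insertion into the read
    k <- sample(nchar(r) - 2, 1) + 1
    r <- paste0(substr(r, 1, k), rand_dna(-indel), substr(r, k + 1, nchar(r)))
  }
  r
}
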