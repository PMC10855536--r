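test_that("exact and near-exact reads score by the stated scheme", {
  set.seed(31)
  ref <- rand_dna(400)
  read <- substr(ref, 101, 240) # 140 nt
  h <- align_read_glocal(read, ref)
  expect_equal(nrow(h), 1L)
  expect_equal(h$score, 140L)
  expect_equal(h$start, 100L)
  expect_equal(h$strand, "+")
  # one substitution: 139 matches - 10 = 129
  r2 <- read
  substr(r2, 70, 70) <- setdiff(c("A", "C", "G", "T"), substr(r2, 70, 70))[1]
  h2 <- align_read_glocal(r2, ref)
  expect_equal(h2$score, 129L)
  expect_equal(h2$mismatches, 1L)
})

test_that("a read present at two reference positions yields two equal hits", {
  set.seed(32)
  core <- rand_dna(60)
  ref <- paste0(rand_dna(50), core, rand_dna(80), core, rand_dna(50))
  h <- align_read_glocal(core, ref)
  expect_equal(nrow(h), 2L)
  expect_equal(unique(h$score), 60L)
  expect_equal(h$start, c(50L, 190L))
})

test_that("DP dominates the placement oracle, with equality for gapless optima", {
  set.seed(33)
  for (i in 1:120) {
    G <- sample(150:300, 1)
    ref <- rand_dna(G)
    read <- if (i %% 3 == 0) rand_dna(sample(20:60, 1))
            else planted_read(ref, sample(30:60, 1),
                              n_sub = sample(0:2, 1),
                              indel = sample(c(0, 0, 1, 2, -1, -2), 1))
    hit <- align_read_glocal(read, ref, both_strands = FALSE)
    enum <- oracle_glocal_score(read, ref)
    expect_gte(hit$score[1], enum)
    if (hit$gap_bases[1] <= 1)
      expect_equal(hit$score[1], enum, info = paste("case", i))
  }
})

test_that("DP equals exhaustive edit-path enumeration on tiny cases", {
  set.seed(39)
  for (i in 1:30) {
    read <- rand_dna(sample(4:8, 1))
    ref <- rand_dna(sample(8:16, 1))
    hit <- align_read_glocal(read, ref, both_strands = FALSE)
    ex <- oracle_glocal_exhaustive(read, ref, max_gap = 3)
    expect_gte(hit$score[1], ex)
    if (hit$gap_bases[1] <= 3)
      expect_equal(hit$score[1], ex, info = paste("tiny", i))
  }
})

test_that("DP score agrees with an independent glocal implementation", {
  set.seed(34)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -10)
  for (i in 1:60) {
    ref <- rand_dna(sample(120:250, 1))
    read <- planted_read(ref, sample(25:50, 1), n_sub = sample(0:3, 1),
                         indel = sample(-2:2, 1))
    got <- align_read_glocal(read, ref, both_strands = FALSE)$score[1]
    pa <- Biostrings::pairwiseAlignment(
      read, ref, type = "global-local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 10)
    expect_equal(got, Biostrings::score(pa), info = paste("case", i))
  }
})

test_that("aligning the reverse complement flips strand but preserves score", {
  set.seed(35)
  ref <- rand_dna(300)
  read <- planted_read(ref, 50, n_sub = 1)
  h_f <- align_read_glocal(read, ref)
  h_r <- align_read_glocal(oracle_revcomp(read), ref)
  expect_equal(h_r$score, h_f$score)
  expect_equal(sort(h_r$start), sort(h_f$start))
  expect_setequal(h_r$strand, setdiff(c("+", "-"), h_f$strand))
})

test_that("score never exceeds read length; equality iff exact substring", {
  set.seed(36)
  ref <- rand_dna(300)
  for (i in 1:40) {
    read <- if (i %% 2) rand_dna(30) else planted_read(ref, 30, n_sub = i %% 3)
    h <- align_read_glocal(read, ref, both_strands = FALSE)
    expect_lte(h$score[1], nchar(read))
    is_sub <- grepl(read, ref, fixed = TRUE)
    expect_equal(h$score[1] == nchar(read), is_sub)
  }
})

test_that("acceptance threshold defaults to read_len - 33", {
  sc <- alignment_scoring()
  expect_true(accept_hit(140, 140, sc))
  expect_true(accept_hit(140 - 33, 140, sc))   # 3 events, boundary
  expect_false(accept_hit(140 - 44, 140, sc))  # 4 events
  loose <- alignment_scoring(min_accept_score = -1e9)
  expect_true(accept_hit(-500, 140, loose))
})

test_that("tie resolution is deterministic per (seed, read_id) and uniform", {
  hits <- data.frame(start = c(10L, 200L), end = c(60L, 250L),
                     strand = c("+", "+"), score = c(50L, 50L))
  a <- resolve_ties(hits, seed = 5, read_id = "readA")
  b <- resolve_ties(hits, seed = 5, read_id = "readA")
  expect_identical(a, b)
  expect_equal(nrow(resolve_ties(hits[1, ], 5, "x")), 1L)
  expect_error(resolve_ties(hits[0, ], 5, "x"), "non-empty")
  expect_error(resolve_ties(data.frame(score = c(1L, 2L)), 5, "x"),
               "equal-score")
  picks <- vapply(1:2000, function(i)
    resolve_ties(hits, seed = 5, read_id = paste0("read", i))$start,
    integer(1))
  frac <- mean(picks == 10L)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("seeded genome mapper agrees with the exhaustive aligner", {
  set.seed(37)
  genome <- c(chr1 = rand_dna(4000), chr2 = rand_dna(3000))
  reads <- character(40)
  for (i in seq_along(reads)) {
    src <- sample(1:2, 1)
    reads[i] <- planted_read(genome[[src]], 140, n_sub = sample(0:3, 1),
                             indel = sample(c(0, 0, 1, -1), 1))
  }
  rd <- data.frame(read_id = paste0("r", seq_along(reads)), sequence = reads)
  mapped <- map_reads(rd, genome, seed = 9)
  for (i in seq_along(reads)) {
    ex <- lapply(genome, function(s)
      align_read_glocal(reads[i], s, both_strands = TRUE))
    best <- max(vapply(ex, function(h) max(h$score), integer(1)))
    expect_equal(mapped$score[i], best, info = paste("read", i))
  }
  expect_true(all(mapped$mapped[nchar(reads) - mapped$score <= 33]))
})

test_that("mapper reports unmapped reads and multi-mapper tallies", {
  set.seed(38)
  core <- rand_dna(150)
  genome <- c(chr1 = paste0(rand_dna(500), core, rand_dna(500), core,
                            rand_dna(500)))
  rd <- data.frame(read_id = c("dup", "junk"),
                   sequence = c(core, rand_dna(150)))
  h <- map_reads(rd, genome, seed = 1)
  expect_equal(h$n_best[1], 2L)
  expect_true(h$mapped[1])
  expect_false(h$mapped[2])
  # same seed, different input order: same placement for the same read
  h2 <- map_reads(rd[2:1, ], genome, seed = 1)
  expect_equal(h2$start[h2$read_id == "dup"], h$start[h$read_id == "dup"])
})
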