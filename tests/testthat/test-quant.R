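mk_hits <- function(sample, chrom, start, end, mapped = TRUE) {
  n <- length(start)
  data.frame(read_id = paste0("r", seq_len(n)), sample = sample,
             chrom = chrom, start = start, end = end,
             strand = "+", score = ifelse(mapped, end - start, NA),
             mismatches = 0L, gap_bases = 0L, n_best = 1L, mapped = mapped)
}

toy_loci <- data.frame(locus_id = c("chr1-1", "chr1-2"),
                       chrom = "chr1",
                       start = c(1000L, 5000L), end = c(1180L, 5180L))

test_that("hits are assigned by fractional overlap with the locus", {
  hits <- mk_hits("s1", "chr1",
                  start = c(1010L, 1100L, 3000L, 5020L),
                  end = c(1160L, 1250L, 3150L, 5170L))
  # read 2 overlaps locus 1 by 80/150 < 0.9 -> off-target
  lc <- assign_to_loci(hits, toy_loci, min_overlap = 0.9)
  expect_equal(unname(lc$counts[, "s1"]), c(1L, 1L))
  expect_equal(lc$samples$off_target, 2L)
  # relaxed overlap captures the boundary-spanning read
  lc2 <- assign_to_loci(hits, toy_loci, min_overlap = 0.5)
  expect_equal(unname(lc2$counts[, "s1"]), c(2L, 1L))
})

test_that("hits on chromosomes without loci count as off-target", {
  hits <- mk_hits("s1", c("chr1", "chrX"), start = c(1010L, 100L),
                  end = c(1160L, 250L))
  lc <- assign_to_loci(hits, toy_loci)
  expect_equal(sum(lc$counts), 1L)
  expect_equal(lc$samples$off_target, 1L)
})

test_that("count conservation holds per sample", {
  set.seed(41)
  n <- 200
  st <- sample(c(1010L, 5010L, 8000L), n, replace = TRUE)
  hits <- mk_hits(sample(c("a", "b"), n, replace = TRUE), "chr1",
                  start = st, end = st + 150L,
                  mapped = runif(n) > 0.1)
  lc <- assign_to_loci(hits, toy_loci, sample_levels = c("a", "b"))
  expect_equal(lc$samples$on_target + lc$samples$off_target,
               lc$samples$mapped)
  expect_equal(lc$samples$mapped + lc$samples$unmapped, lc$samples$n_reads)
  expect_equal(unname(colSums(lc$counts)), lc$samples$on_target)
})

test_that("frequencies are percentages with the chosen denominator", {
  hits <- mk_hits("s1", "chr1", start = rep(c(1010L, 5010L, 8000L),
                                            c(50L, 30L, 20L)),
                  end = rep(c(1160L, 5160L, 8150L), c(50L, 30L, 20L)))
  lc <- assign_to_loci(hits, toy_loci)
  f_on <- to_frequencies(lc, "on_target")
  expect_equal(unname(f_on[, 1]), c(62.5, 37.5))
  expect_equal(sum(f_on), 100)
  f_all <- to_frequencies(lc, "all_mapped")
  expect_equal(unname(f_all[, 1]), c(50, 30))
  expect_equal(attr(f_all, "denominator"), "all_mapped")
})

test_that("zero denominators yield NA frequencies with a warning", {
  hits <- mk_hits("s1", "chr1", 8000L, 8150L) # off-target only
  lc <- assign_to_loci(hits, toy_loci)
  expect_warning(f <- to_frequencies(lc, "on_target"), "zero")
  expect_true(all(is.na(f)))
})

test_that("low-count rule excludes strictly above the sample fraction", {
  m <- rbind(zeros3of4 = c(0L, 0L, 0L, 5L),
             zeros2of4 = c(0L, 0L, 3L, 5L),
             full = c(2L, 3L, 4L, 5L))
  out <- low_count_filter(m, min_count = 1, sample_fraction = 0.5)
  expect_equal(out$excluded, "zeros3of4")
  expect_setequal(out$retained, c("zeros2of4", "full"))
  none <- low_count_filter(m[3, , drop = FALSE])
  expect_equal(none$excluded, character(0))
})

test_that("counts recover generator truth within the multinomial envelope", {
  cfg <- sim_config(seed = 42, n_loci = 12, n_mid = 4,
                    background_len = 40000, primer_site_mismatches = 0,
                    reads_per_sample = 5000, sub_rate = 0, indel_rate = 0,
                    group_sizes = c(control = 1, case = 1))
  sim <- build_genome(cfg)
  rd <- simulate_reads(sim)
  tr <- trim_primers(rd$reads, cfg$primers)
  fl <- length_filter(tr)
  h <- map_reads(fl$kept, sim$genome, seed = 42)
  h$sample <- fl$kept$sample
  lc <- assign_to_loci(h, sim$loci, sample_levels = rd$samples$sample)
  # every kept read maps: error-free reads are exact amplicon substrings
  expect_equal(sum(!h$mapped), 0L)
  # audit: reads are assigned to their source locus
  src <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", fl$kept$read_id)
  n <- sum(lc$samples$on_target)
  agree <- 0
  for (s in unique(fl$kept$sample)) agree <- agree +
    sum(pmin(table(factor(src[fl$kept$sample == s],
                          levels = sim$loci$locus_id)),
             lc$counts[, s]))
  expect_gte(agree / n, 0.995)
  # per-locus binomial envelope around the kept-read truth proportions
  for (s in colnames(lc$counts)) {
    ns <- sum(lc$counts[, s])
    p_true <- as.numeric(table(factor(src[fl$kept$sample == s],
                                      levels = sim$loci$locus_id))) /
      sum(fl$kept$sample == s)
    lo <- qbinom(5e-4, ns, p_true)
    hi <- qbinom(1 - 5e-4, ns, p_true)
    expect_true(all(lc$counts[, s] >= lo & lc$counts[, s] <= hi))
  }
})
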