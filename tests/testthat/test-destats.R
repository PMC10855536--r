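test_that("fold change is the ratio of group medians with zero conventions", {
  expect_equal(fold_change(c(1.8, 2.0, 2.2), c(0.9, 1.0, 1.1)), 2)
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fold_change(c(0, 0, 0), c(0.5, 0.6)), 0)
  expect_equal(fold_change(c(1, 2), c(0, 0)), Inf)
  expect_equal(fold_change(c(0, 0), c(0, 0)), 0)
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("relative fold change is the symmetric deviation from 1", {
  expect_equal(relative_fold_change(2), 1)
  expect_equal(relative_fold_change(0.5), 1)
  expect_equal(relative_fold_change(1), 0)
  expect_equal(relative_fold_change(0), 0)
  expect_error(relative_fold_change(-1), ">= 0")
  # inversion symmetry over random fold changes
  set.seed(51)
  x <- exp(runif(200, -4, 4))
  expect_equal(relative_fold_change(x), relative_fold_change(1 / x))
})

test_that("swapping case and control inverts x and preserves rfc", {
  set.seed(52)
  for (i in 1:20) {
    a <- runif(5, 0.1, 5)
    b <- runif(5, 0.1, 5)
    x <- fold_change(a, b)
    expect_equal(fold_change(b, a), 1 / x)
    expect_equal(relative_fold_change(x), relative_fold_change(1 / x))
  }
})

test_that("rfc summaries respect the unchanged window and signs", {
  x <- c(2, 0.5, 1, 1.1, 0.9, 3, Inf)
  all_s <- summarize_rfc(x, "all")
  expect_equal(all_s$n, 6L)
  expect_equal(all_s$n_excluded_infinite, 1L)
  ch <- summarize_rfc(x, "changed_only")
  expect_equal(ch$n, 3L) # drops 1, 1.1, 0.9
  expect_equal(ch$n_excluded_window, 3L)
  expect_equal(ch$median_abs, 1)
  # x = {2, 0.5}: equal magnitude, opposite signs
  two <- summarize_rfc(c(2, 0.5))
  expect_equal(two$median_signed, 0)
  expect_equal(two$mean_abs, 1)
  flat <- summarize_rfc(rep(1, 5))
  expect_equal(flat$median_signed, 0)
  expect_equal(flat$mean_abs, 0)
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("size factors recover planted depth ratios from NB counts", {
  set.seed(53)
  depth <- c(1, 0.5, 2, 1.5)
  mu <- exp(rnorm(300, log(200), 1))
  m <- sapply(depth, function(d) rnbinom(300, mu = mu * d, size = 20))
  sf <- size_factors(m)
  truth <- depth / exp(mean(log(depth)))
  expect_true(all(abs(sf / truth - 1) < 0.05))
})

test_that("size factors fall back to library size when no locus is complete", {
  m <- rbind(c(0L, 5L), c(6L, 0L))
  expect_message(sf <- size_factors(m), "library-size")
  expect_equal(unname(sf), c(6, 5) / sqrt(30))
  expect_error(size_factors(m, fallback = FALSE), "nonzero")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(54)
  for (i in 1:60) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("Wald test is exactly null for group-symmetric counts", {
  m <- cbind(a1 = c(10L, 50L), a2 = c(20L, 40L),
             b1 = c(10L, 50L), b2 = c(20L, 40L))
  r <- nb_wald_test(m, c("ctrl", "ctrl", "case", "case"), "case", "ctrl")
  expect_equal(r$log2_fc, c(0, 0))
  expect_equal(r$stat, c(0, 0))
  expect_equal(r$p, c(1, 1))
  expect_true(all(r$p_adj >= r$p))
})

test_that("planted log2 effects are recovered with small bias", {
  set.seed(55)
  bias <- replicate(40, {
    fold <- rep(1, 30); fold[7] <- 4
    m <- make_nb_counts(30, 4, dispersion = 0.05, fold = fold)
    r <- nb_wald_test(m, rep(c("ctrl", "case"), each = 4), "case", "ctrl")
    r$log2_fc[7] - 2
  })
  expect_lt(abs(mean(bias)), 0.25)
})

test_that("compare_groups merges fold change, rfc and the NB test", {
  set.seed(56)
  cfg <- sim_config(seed = 8, n_loci = 6, n_mid = 2, background_len = 30000,
                    reads_per_sample = 400,
                    group_sizes = c(control = 3, case = 3))
  sim <- build_genome(cfg)
  rd <- simulate_reads(sim)
  tr <- trim_primers(rd$reads, cfg$primers)
  fl <- length_filter(tr)
  h <- map_reads(fl$kept, sim$genome, seed = 8)
  h$sample <- fl$kept$sample
  lc <- assign_to_loci(h, sim$loci, sample_levels = rd$samples$sample)
  cmp <- compare_groups(lc, rd$samples$group, "case", "control")
  expect_equal(nrow(cmp), 6L)
  expect_true(all(cmp$fold_change >= 0))
  expect_true(all(cmp$relative_fold_change[is.finite(cmp$fold_change)] >= 0))
  ok <- !is.na(cmp$p)
  expect_true(all(cmp$p_adj[ok] >= cmp$p[ok]))
  expect_true(all(is.na(cmp$p[cmp$excluded])))
})
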