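# Group-comparison statistics: median-based fold change, the symmetric
# relative-fold-change transform, median-of-ratios size factors, and a
# simplified negative-binomial Wald test with BH-FDR.

#' Fold change of group median frequencies
#'
#' `x = median(case) / median(control)`. A zero control median with a
#' positive case median yields `Inf`; when both medians are zero, `x = 0`
#' by convention (which feeds the `rfc(0) = 0` rule).
#'
#' @param case_freqs,control_freqs Per-sample relative frequencies (%).
#' @return Non-negative fold change (possibly `Inf`).
#' @export
fold_change <- function(case_freqs, control_freqs) {
  if (length(case_freqs) == 0L || length(control_freqs) == 0L)
    stop("both groups must be non-empty")
  mc <- median(case_freqs)
  m0 <- median(control_freqs)
  if (m0 == 0) {
    if (mc == 0) return(0)
    return(Inf)
  }
  mc / m0
}

#' Relative fold change: symmetric deviation from a 1-fold change
#'
#' Piecewise transform of a fold change `x`: `x - 1` for `x > 1`,
#' `1/x - 1` for `0 < x < 1`, and 0 at `x = 1` and at `x = 0`. Symmetric
#' under inversion: `rfc(x) == rfc(1/x)` for every `x > 0`.
#'
#' @param x Non-negative fold change(s).
#' @return Non-negative relative fold change(s).
#' @export
relative_fold_change <- function(x) {
  if (any(is.na(x)) || any(x < 0)) stop("fold change must be >= 0")
  ifelse(x == 0, 0, ifelse(x > 1, x - 1, ifelse(x < 1, 1 / x - 1, 0)))
}

#' Summarize relative fold changes across loci
#'
#' Signed relative change per locus takes its sign from the direction of
#' the fold change (`+` for `x > 1`, `-` for `x < 1`). Infinite fold
#' changes are excluded and counted. With `subset = "changed_only"`, loci
#' with `0.8 < x < 1.2` are dropped first (the "unchanged" window).
#'
#' @param x Vector of fold changes (one per locus).
#' @param subset `"all"` or `"changed_only"`.
#' @param window Unchanged-window bounds used by `"changed_only"`.
#' @return One-row `data.frame` with counts and center/spread of both the
#'   signed and the absolute relative fold changes.
#' @export
summarize_rfc <- function(x, subset = c("all", "changed_only"),
                          window = c(0.8, 1.2)) {
  subset <- match.arg(subset)
  n_inf <- sum(!is.finite(x))
  x <- x[is.finite(x)]
  n_window <- 0L
  if (subset == "changed_only") {
    inside <- x > window[1] & x < window[2]
    n_window <- sum(inside)
    x <- x[!inside]
  }
  rfc <- relative_fold_change(x)
  signed <- ifelse(x >= 1, rfc, -rfc)
  data.frame(n = length(x), n_excluded_window = n_window,
             n_excluded_infinite = n_inf,
             median_signed = if (length(x)) median(signed) else NA_real_,
             mean_signed = if (length(x)) mean(signed) else NA_real_,
             sd_signed = if (length(x) > 1L) sd(signed) else NA_real_,
             median_abs = if (length(x)) median(rfc) else NA_real_,
             mean_abs = if (length(x)) mean(rfc) else NA_real_,
             sd_abs = if (length(x) > 1L) sd(rfc) else NA_real_)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-sample-nonzero loci of the ratio of
#' its count to the locus geometric mean; factors are normalized to
#' geometric mean 1. If no locus is nonzero in every sample, falls back to
#' library-size totals (with a message) unless `fallback = FALSE`.
#'
#' @param counts Counts matrix (loci x samples) or `locus_counts`.
#' @param fallback Allow the library-size fallback.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts, fallback = TRUE) {
  m <- if (inherits(counts, "locus_counts")) counts$counts else counts
  lg <- log(m)
  loggeo <- rowMeans(lg)
  use <- is.finite(loggeo)
  if (!any(use)) {
    if (!fallback)
      stop("no locus has nonzero counts in every sample")
    message("size_factors: no all-nonzero locus; using library-size totals")
    tot <- colSums(m)
    sf <- tot / exp(mean(log(tot)))
    return(setNames(sf, colnames(m)))
  }
  lr <- lg[use, , drop = FALSE] - loggeo[use]
  sf <- exp(apply(lr, 2L, median))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Simplified negative-binomial Wald test for differential expression
#'
#' Per locus, group means are fit on size-factor-normalized counts and the
#' NB dispersion is estimated by method-of-moments within groups (pooled
#' across the two groups, floored at `dispersion_floor`); no
#' empirical-Bayes shrinkage and no outlier handling. The Wald statistic
#' `log2FC / se(log2FC)` is referred to a t distribution with
#' `n1 + n2 - 2` degrees of freedom — the small-sample calibration of the
#' large-sample normal reference (they coincide as n grows). When a group
#' mean is zero, a +0.5 pseudocount is added to both group means for the
#' fold change and its standard error.
#'
#' Run [low_count_filter()] first; loci with zero counts in every sample of
#' both groups return `NA` statistics.
#'
#' @param counts Counts matrix (loci x samples) or `locus_counts`.
#' @param groups Group label per column of `counts`.
#' @param case,control Labels of the two groups to compare (log2FC is
#'   case over control).
#' @param sf Size factors; computed by [size_factors()] when `NULL`.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @return `data.frame` with `locus_id`, `base_mean`, `log2_fc`, `se`,
#'   `stat`, `p`, `p_adj` (BH over the tested loci).
#' @export
nb_wald_test <- function(counts, groups, case, control, sf = NULL,
                         dispersion_floor = 1e-8) {
  m <- if (inherits(counts, "locus_counts")) counts$counts else counts
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  i1 <- which(groups == control)
  i2 <- which(groups == case)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs at least two samples")
  if (is.null(sf)) sf <- size_factors(m)
  if (is.null(names(sf))) names(sf) <- colnames(m)
  q <- sweep(m, 2L, sf, "/")

  n1 <- length(i1); n2 <- length(i2)
  q1 <- q[, i1, drop = FALSE]; q2 <- q[, i2, drop = FALSE]
  m1 <- rowMeans(q1); m2 <- rowMeans(q2)
  v1 <- apply(q1, 1L, var); v2 <- apply(q2, 1L, var)
  a1 <- mean(1 / sf[i1]); a2 <- mean(1 / sf[i2])

  # method-of-moments dispersion, pooled over groups with df weights
  al1 <- (v1 - m1 * a1) / m1^2
  al2 <- (v2 - m2 * a2) / m2^2
  al1[!is.finite(al1)] <- 0
  al2[!is.finite(al2)] <- 0
  alpha <- pmax((al1 * (n1 - 1L) + al2 * (n2 - 1L)) / (n1 + n2 - 2L),
                dispersion_floor)

  use_pc <- (m1 == 0) | (m2 == 0)
  m1p <- ifelse(use_pc, m1 + 0.5, m1)
  m2p <- ifelse(use_pc, m2 + 0.5, m2)
  V1 <- m1p * a1 / n1 + alpha * m1p^2 / n1
  V2 <- m2p * a2 / n2 + alpha * m2p^2 / n2
  log2_fc <- log2(m2p / m1p)
  se <- sqrt(V1 / m1p^2 + V2 / m2p^2) / log(2)
  stat <- ifelse(log2_fc == 0, 0, log2_fc / se)
  dfree <- n1 + n2 - 2L
  p <- 2 * pt(-abs(stat), df = dfree)

  dead <- (m1 == 0) & (m2 == 0)
  p[dead] <- NA_real_; stat[dead] <- NA_real_
  log2_fc[dead] <- NA_real_; se[dead] <- NA_real_

  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) p_adj[ok] <- bh_adjust(p[ok])

  ids <- if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
         else rownames(m)
  data.frame(locus_id = ids, base_mean = rowMeans(q),
             log2_fc = log2_fc, se = se, stat = stat, p = p, p_adj = p_adj,
             row.names = NULL)
}

#' Full two-group locus comparison table
#'
#' Combines the frequency-scale fold change and relative fold change with
#' the count-scale NB Wald test. The low-count rule is applied first; all
#' loci are reported, with `excluded = TRUE` and `NA` test statistics for
#' filtered loci.
#'
#' @param lc A `locus_counts` object.
#' @param groups Group label per sample (aligned with `lc$samples$sample`).
#' @param case,control Group labels (fold change is case over control).
#' @param denominator Frequency denominator, see [to_frequencies()].
#' @param min_count,sample_fraction Low-count rule, see [low_count_filter()].
#' @return `data.frame` with `locus_id`, `fold_change`,
#'   `relative_fold_change`, `log2_fc`, `se`, `stat`, `p`, `p_adj`,
#'   `excluded`.
#' @export
compare_groups <- function(lc, groups, case, control,
                           denominator = "on_target",
                           min_count = 1L, sample_fraction = 0.5) {
  stopifnot(inherits(lc, "locus_counts"))
  groups <- as.character(groups)
  fr <- to_frequencies(lc, denominator)
  flt <- low_count_filter(lc, min_count, sample_fraction)
  keep <- rownames(lc$counts) %in% flt$retained

  x <- vapply(seq_len(nrow(fr)), function(i)
    fold_change(fr[i, groups == case], fr[i, groups == control]),
    numeric(1))
  rfc <- relative_fold_change(x)

  res <- data.frame(locus_id = rownames(lc$counts), fold_change = x,
                    relative_fold_change = rfc, log2_fc = NA_real_,
                    se = NA_real_, stat = NA_real_, p = NA_real_,
                    p_adj = NA_real_, excluded = !keep, row.names = NULL)
  if (sum(keep) > 0L) {
    nb <- nb_wald_test(lc$counts[keep, , drop = FALSE], groups,
                       case = case, control = control)
    j <- match(nb$locus_id, res$locus_id)
    res$log2_fc[j] <- nb$log2_fc
    res$se[j] <- nb$se
    res$stat[j] <- nb$stat
    res$p[j] <- nb$p
    res$p_adj[j] <- nb$p_adj
  }
  res
}
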