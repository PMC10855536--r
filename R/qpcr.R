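# qPCR relative-expression arithmetic: 2^-ddCt with multiple reference
# genes, triplicate SD gating, and the no-RT genomic-contamination check.

#' Gate replicate Ct values by standard deviation
#'
#' Mean of the detected replicates if their standard deviation is strictly
#' below `max_sd`, otherwise rejected (`NA`). Undetermined replicates are
#' passed as `NA` and excluded; at least two detected replicates are
#' required.
#'
#' @param cts Numeric replicate Ct values (`NA` = undetermined).
#' @param max_sd SD acceptance threshold (cycles).
#' @return List with `mean` (`NA` if rejected), `sd`, `n_detected`,
#'   `accepted`.
#' @export
gate_replicates <- function(cts, max_sd = 0.2) {
  det <- cts[!is.na(cts)]
  if (length(det) < 2L)
    stop("gate_replicates needs at least two detected replicates")
  s <- sd(det)
  # strict s < max_sd, robust to floating-point ties at the boundary
  acc <- (max_sd - s) > 1e-9
  list(mean = if (acc) mean(det) else NA_real_, sd = s,
       n_detected = length(det), accepted = acc)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - mean(Ct_refs)` (the arithmetic mean of reference-gene
#' Cts is equivalent to normalizing expression by their geometric mean);
#' `ddCt = dCt - calibrator`; expression is `2^-ddCt`.
#'
#' @param target_ct Gated mean Ct of the target gene.
#' @param ref_cts Gated mean Cts of one or more reference genes.
#' @param calibrator_dct Group-level baseline dCt (e.g. mean or median dCt
#'   of the control group).
#' @return Fold expression relative to the calibrator.
#' @export
ddct_expression <- function(target_ct, ref_cts, calibrator_dct = 0) {
  if (length(ref_cts) < 1L) stop("at least one reference gene is required")
  dct <- target_ct - mean(ref_cts)
  2^-(dct - calibrator_dct)
}

#' RT+/RT- genomic-contamination check
#'
#' Compares the signal with and without the reverse-transcription step:
#' `ratio = 2^(Ct_RT- - Ct_RT+)`. Passes iff the RT+ signal is at least
#' `min_fold` higher. An undetected RT- reaction (`NA`) passes with an
#' infinite ratio (no amplifiable DNA).
#'
#' @param rt_plus_ct,rt_minus_ct Ct values with / without RT.
#' @param min_fold Required fold excess of the RT+ signal.
#' @return List with `ratio` and `pass`.
#' @export
rt_contamination_ratio <- function(rt_plus_ct, rt_minus_ct, min_fold = 10) {
  if (is.na(rt_minus_ct)) return(list(ratio = Inf, pass = TRUE))
  ratio <- 2^(rt_minus_ct - rt_plus_ct)
  list(ratio = ratio, pass = ratio >= min_fold)
}

#' Cohort-level 2^-ddCt analysis from a long-format Ct table
#'
#' Gates replicates per (sample, gene), computes per-sample dCt for the
#' target against the mean of the reference-gene Cts, sets the calibrator
#' to the mean (or median) control-group dCt, and returns per-sample fold
#' expression.
#'
#' @param ct_table Long-format `data.frame`: `sample`, `gene`, `ct`
#'   (replicate rows), plus a `group` column or a separate `groups` map.
#' @param target Target gene name.
#' @param refs Reference gene names.
#' @param control Control group label (defines the calibrator).
#' @param calibrator `"mean"` or `"median"` control-group dCt.
#' @param max_sd Replicate gate, see [gate_replicates()].
#' @return `data.frame` with `sample`, `group`, `dct`, `fold`; samples with
#'   a rejected target or reference measurement get `NA`.
#' @export
qpcr_relative_expression <- function(ct_table, target, refs, control,
                                     calibrator = c("mean", "median"),
                                     max_sd = 0.2) {
  calibrator <- match.arg(calibrator)
  stopifnot(all(c("sample", "gene", "ct", "group") %in% names(ct_table)))
  gated <- aggregate(ct ~ sample + gene + group, data = ct_table,
                     FUN = function(v) gate_replicates(v, max_sd)$mean,
                     na.action = NULL)
  samples <- unique(gated$sample)
  get_ct <- function(s, g) {
    v <- gated$ct[gated$sample == s & gated$gene == g]
    if (length(v) == 0L) NA_real_ else v[1L]
  }
  dct <- vapply(samples, function(s) {
    tc <- get_ct(s, target)
    rc <- vapply(refs, get_ct, numeric(1), s = s)
    if (is.na(tc) || anyNA(rc)) NA_real_ else tc - mean(rc)
  }, numeric(1))
  grp <- gated$group[match(samples, gated$sample)]
  ctrl_dct <- dct[grp == control & !is.na(dct)]
  if (length(ctrl_dct) == 0L) stop("no usable control-group samples")
  cal <- if (calibrator == "mean") mean(ctrl_dct) else median(ctrl_dct)
  data.frame(sample = samples, group = grp, dct = dct,
             fold = 2^-(dct - cal), row.names = NULL)
}
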