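validate_ct <- function(records) {
  assert_columns(records, c("sample_id", "group", "gene", "ct"), "records")
  assert_numeric_finite(records$ct, "ct")
  if (anyDuplicated(records[, c("sample_id", "gene")]))
    stop_validation("records",
                    "one Ct per (sample, gene): average technical replicates first")
  invisible(records)
}

#' Select the most stable reference gene
#'
#' Ranks candidate reference genes by the standard deviation of their raw
#' Ct across all samples and returns the most consistent one (smallest
#' SD). Candidates not measured in every sample are excluded with a
#' warning; SD ties are broken by gene name (lexicographically first) and
#' reported. This is the plain Ct-stability criterion; geNorm-style
#' pairwise metrics are deliberately out of scope.
#'
#' @param records Ct table: `sample_id, group, gene, ct` (one row per
#'   sample-gene).
#' @param candidate_genes Character vector of candidate reference genes.
#' @return A list: `reference` (the chosen gene), `report` (data frame of
#'   per-candidate SD and completeness), `tie` (logical).
#' @export
select_reference <- function(records, candidate_genes) {
  validate_ct(records)
  samples <- unique(records$sample_id)
  report <- do.call(rbind, lapply(sort(candidate_genes), function(g) {
    ct <- records$ct[records$gene == g]
    covered <- unique(records$sample_id[records$gene == g])
    complete <- length(setdiff(samples, covered)) == 0
    data.frame(gene = g, n_samples = length(covered),
               complete = complete,
               sd_ct = if (complete) stats::sd(ct) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(!report$complete))
    warning(sprintf("candidate(s) not measured in every sample, excluded: %s",
                    paste(report$gene[!report$complete], collapse = ", ")))
  usable <- report[report$complete, , drop = FALSE]
  if (nrow(usable) == 0)
    stop("no reference candidate is measured in every sample", call. = FALSE)
  best_sd <- min(usable$sd_ct)
  winners <- usable$gene[usable$sd_ct == best_sd]
  tie <- length(winners) > 1
  if (tie)
    message(sprintf("reference SD tie between %s; choosing %s",
                    paste(winners, collapse = ", "), winners[1]))
  list(reference = winners[1], report = report, tie = tie)
}

#' Delta-delta-Ct relative quantification
#'
#' Classic RQ under perfect per-cycle doubling: per sample,
#' `delta_ct = Ct_target - Ct_reference`, raw `RQ = 2^(-delta_ct)`, and the
#' final relative quantity is the raw RQ divided by the mean raw RQ of the
#' control group — so the control-group mean RQ is exactly 1 by
#' construction. Samples missing either Ct are dropped with a warning.
#' Sample-wide Ct shifts (loading/efficiency offsets shared by target and
#' reference) cancel in the subtraction.
#'
#' @param records Ct table (`sample_id, group, gene, ct`).
#' @param target_gene Gene to quantify.
#' @param reference_gene Normalizer gene (see [select_reference()]).
#' @param control_group Group whose mean raw RQ defines 1 (default
#'   `"LEF"`).
#' @return Data frame: `sample_id, group, gene, delta_ct, rq`.
#' @export
ddct_rq <- function(records, target_gene, reference_gene,
                    control_group = "LEF") {
  validate_ct(records)
  tg <- records[records$gene == target_gene,
                c("sample_id", "group", "ct"), drop = FALSE]
  rf <- records[records$gene == reference_gene,
                c("sample_id", "ct"), drop = FALSE]
  if (nrow(tg) == 0) stop_validation("target_gene", "not present in records")
  if (nrow(rf) == 0) stop_validation("reference_gene", "not present in records")
  merged <- merge(tg, rf, by = "sample_id", suffixes = c("_target", "_ref"))
  dropped <- setdiff(unique(c(tg$sample_id, rf$sample_id)), merged$sample_id)
  if (length(dropped) > 0)
    warning(sprintf("sample(s) missing target or reference Ct, dropped: %s",
                    paste(dropped, collapse = ", ")))
  if (!any(merged$group == control_group))
    stop_validation("control_group", "no complete samples in the control group")
  delta_ct <- merged$ct_target - merged$ct_ref
  raw_rq <- 2^(-delta_ct)
  rq <- raw_rq / mean(raw_rq[merged$group == control_group])
  out <- data.frame(sample_id = merged$sample_id, group = merged$group,
                    gene = target_gene, delta_ct = delta_ct, rq = rq,
                    stringsAsFactors = FALSE)
  out[order(out$group, out$sample_id), , drop = FALSE]
}

#' Compare relative quantities between two groups
#'
#' Two-sample equal-variance t-test (see [ttest_protein()]) on log2(RQ),
#' reporting group means and standard errors on the RQ scale. By the RQ
#' construction the control-group mean is 1.
#'
#' @param rows RQ table from [ddct_rq()].
#' @param case_group,control_group Group labels.
#' @return A list: `gene`, `mean_case`, `mean_ctrl`, `sem_case`,
#'   `sem_ctrl`, `t`, `p`, `status` (`"tested"` or `"untested"` when a
#'   group has fewer than 2 samples).
#' @export
compare_rq <- function(rows, case_group = "HEF", control_group = "LEF") {
  assert_columns(rows, c("sample_id", "group", "gene", "rq"), "rows")
  cs <- rows$rq[rows$group == case_group]
  ks <- rows$rq[rows$group == control_group]
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  res <- list(gene = rows$gene[1],
              mean_case = mean(cs), mean_ctrl = mean(ks),
              sem_case = sem(cs), sem_ctrl = sem(ks),
              t = NA_real_, p = NA_real_, status = "untested")
  if (length(cs) >= 2 && length(ks) >= 2) {
    tt <- ttest_protein(log2(cs), log2(ks))
    res$t <- tt$t
    res$p <- tt$p
    res$status <- "tested"
  }
  res
}
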