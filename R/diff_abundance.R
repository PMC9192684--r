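#' Signed fold change between group means
#'
#' Ratio of arithmetic means on the normalized raw intensity scale,
#' reported in the signed display convention: the ratio itself when it is
#' at least 1, and minus its reciprocal otherwise, so a halving appears as
#' -2 rather than 0.5. `|fc_signed|` is therefore always >= 1 and
#' `fold_change(a, b) == -fold_change(b, a)` off the +/-1 boundary.
#'
#' @param mean_case,mean_ctrl Positive group means (vectorized).
#' @return Signed fold change.
#' @examples
#' fold_change(2, 1)   #  2
#' fold_change(1, 2)   # -2
#' @export
fold_change <- function(mean_case, mean_ctrl) {
  assert_positive(mean_case, "mean_case")
  assert_positive(mean_ctrl, "mean_ctrl")
  r <- mean_case / mean_ctrl
  ifelse(r >= 1, r, -1 / r)
}

#' Two-sample equal-variance t-test on log-scale values
#'
#' Student's pooled-variance t with a two-tailed p-value, as used for
#' per-protein group comparison on log-transformed abundances. Groups with
#' fewer than 2 non-missing values are untestable and return `NA` for both
#' statistics (callers mark such rows, never drop them). When the pooled
#' variance is exactly zero the test is degenerate: equal means give
#' `t = 0, p = 1`; unequal means give an infinite statistic with `p = 0`.
#'
#' @param case_values,ctrl_values Numeric vectors (log scale); `NA`s are
#'   removed.
#' @return A list with elements `t` and `p`.
#' @export
ttest_protein <- function(case_values, ctrl_values) {
  x <- case_values[!is.na(case_values)]
  y <- ctrl_values[!is.na(ctrl_values)]
  if (length(x) < 2 || length(y) < 2)
    return(list(t = NA_real_, p = NA_real_))
  sp2 <- (stats::var(x) * (length(x) - 1) + stats::var(y) * (length(y) - 1)) /
    (length(x) + length(y) - 2)
  stderr <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  d <- mean(x) - mean(y)
  # same degeneracy threshold t.test() applies before erroring on
  # essentially-constant data
  tol <- 10 * .Machine$double.eps * max(abs(mean(x)), abs(mean(y)))
  if (stderr <= tol) {
    if (abs(d) <= tol) return(list(t = 0, p = 1))
    return(list(t = sign(d) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Volcano pi-score
#'
#' Signed volcano ranking score `-log10(p) * log2fc`, combining
#' significance and effect size; zero iff the effect is null or p = 1, and
#' antisymmetric in `log2fc`. A p-value of exactly zero is capped at the
#' smallest representable positive double before taking the log.
#'
#' @param p_value Two-tailed p-value in \[0, 1\] (vectorized).
#' @param log2fc Log2 fold change.
#' @return Numeric pi-score.
#' @export
pi_score <- function(p_value, log2fc) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    stop_validation("p_value", "must lie in [0, 1]")
  p <- pmax(p_value, .Machine$double.xmin)
  -log10(p) * log2fc
}

#' Per-protein differential abundance between two groups
#'
#' For every protein: counts of non-missing observations per group,
#' arithmetic group means on the normalized raw scale, signed fold change
#' ([fold_change()]), the equal-variance t-test on log2 abundances
#' ([ttest_protein()]), a Benjamini-Hochberg adjusted p-value (emitted for
#' optional downstream use; the default significance call uses the raw p,
#' matching common proteomics practice of filtering on p plus fold
#' change), the volcano [pi_score()], and the differential-abundance flag
#' from [call_daps()].
#'
#' Proteins with fewer than 2 observations in either group get status
#' `"untested"` (statistics `NA`) but remain in the output so the full
#' quantified universe is preserved for enrichment backgrounds.
#'
#' @param matrix A raw-scale [protein_matrix()] (normalized abundances).
#' @param groups Data frame with columns `sample_id`, `group` covering all
#'   samples of `matrix`.
#' @param case,control Group labels to compare (fold change = case over
#'   control).
#' @param p_thresh,fc_thresh Significance thresholds passed to
#'   [call_daps()].
#' @return Data frame with one row per protein: `protein_id, n_case,
#'   n_ctrl, mean_case, mean_ctrl, fc_signed, log2fc, t, p, p_bh,
#'   pi_score, is_dap, status`.
#' @export
diff_abundance <- function(matrix, groups, case = "HEF", control = "LEF",
                           p_thresh = 0.05, fc_thresh = 1.5) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (!is.na(matrix$log_base))
    stop_validation("matrix", "supply the raw (unlogged) normalized matrix")
  assert_columns(groups, c("sample_id", "group"), "groups")
  m <- matrix$abundance
  cs <- groups$sample_id[groups$group == case]
  ks <- groups$sample_id[groups$group == control]
  if (length(cs) < 2 || length(ks) < 2)
    stop_validation("groups", "need >= 2 samples per group")
  missing_samples <- setdiff(c(cs, ks), colnames(m))
  if (length(missing_samples) > 0)
    stop_validation("groups", paste0("samples not in matrix: ",
                                     paste(missing_samples, collapse = ", ")))
  mc <- m[, cs, drop = FALSE]
  mk <- m[, ks, drop = FALSE]
  n_case <- rowSums(!is.na(mc))
  n_ctrl <- rowSums(!is.na(mk))
  mean_case <- rowMeans(mc, na.rm = TRUE)
  mean_ctrl <- rowMeans(mk, na.rm = TRUE)
  testable <- n_case >= 2 & n_ctrl >= 2
  np <- nrow(m)
  t_stat <- p_val <- fc <- rep(NA_real_, np)
  for (i in which(testable)) {
    tt <- ttest_protein(log2(mc[i, ]), log2(mk[i, ]))
    t_stat[i] <- tt$t
    p_val[i] <- tt$p
    fc[i] <- fold_change(mean_case[i], mean_ctrl[i])
  }
  res <- data.frame(protein_id = rownames(m),
                    n_case = n_case, n_ctrl = n_ctrl,
                    mean_case = ifelse(n_case > 0, mean_case, NA_real_),
                    mean_ctrl = ifelse(n_ctrl > 0, mean_ctrl, NA_real_),
                    fc_signed = fc,
                    log2fc = ifelse(is.na(fc), NA_real_,
                                    sign(fc) * log2(abs(fc))),
                    t = t_stat, p = p_val,
                    p_bh = NA_real_, pi_score = NA_real_,
                    is_dap = FALSE,
                    status = ifelse(testable, "tested", "untested"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  ok <- res$status == "tested" & !is.na(res$p)
  res$p_bh[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res$pi_score[ok] <- pi_score(res$p[ok], res$log2fc[ok])
  call_daps(res, p_thresh = p_thresh, fc_thresh = fc_thresh)$rows
}

#' Flag differentially abundant proteins
#'
#' A protein is differentially abundant (a DAP) when its two-tailed
#' p-value is at most `p_thresh` AND its absolute signed fold change is at
#' least `fc_thresh`. Both boundaries are inclusive. Untested rows are
#' never flagged.
#'
#' @param rows Data frame with columns `p` and `fc_signed` (e.g. from
#'   [diff_abundance()]).
#' @param p_thresh Maximum p-value (default 0.05).
#' @param fc_thresh Minimum absolute signed fold change (default 1.5).
#' @return A list: `rows` (input with `is_dap` set) and `counts`
#'   (`total`, `up`, `down` — partitioned by the sign of `fc_signed`).
#' @export
call_daps <- function(rows, p_thresh = 0.05, fc_thresh = 1.5) {
  assert_positive(p_thresh, "p_thresh")
  assert_positive(fc_thresh, "fc_thresh")
  if (nrow(rows) == 0) {
    rows$is_dap <- logical(0)
    return(list(rows = rows, counts = c(total = 0L, up = 0L, down = 0L)))
  }
  assert_columns(rows, c("p", "fc_signed"), "rows")
  flag <- !is.na(rows$p) & !is.na(rows$fc_signed) &
    rows$p <= p_thresh & abs(rows$fc_signed) >= fc_thresh
  rows$is_dap <- flag
  list(rows = rows,
       counts = c(total = sum(flag),
                  up = sum(flag & rows$fc_signed > 0),
                  down = sum(flag & rows$fc_signed < 0)))
}

#' Heatmap-ready matrix of differential proteins
#'
#' Restricts a protein matrix to the flagged DAPs and z-scores each
#' protein across samples (sample standard deviation, n - 1 denominator,
#' computed over non-missing values), the form heatmap row-scaling
#' expects. A zero-variance protein cannot be scaled and is exported as an
#' all-zero row with a warning.
#'
#' @param rows Differential table with `protein_id` and `is_dap`.
#' @param matrix A [protein_matrix()] (log scale recommended).
#' @return Numeric matrix, DAPs x samples, row-standardized.
#' @export
export_heatmap_matrix <- function(rows, matrix) {
  stopifnot(inherits(matrix, "protein_matrix"))
  assert_columns(rows, c("protein_id", "is_dap"), "rows")
  ids <- rows$protein_id[rows$is_dap]
  if (length(ids) == 0) stop_validation("rows", "no DAPs to export")
  m <- matrix$abundance[ids, , drop = FALSE]
  z <- t(apply(m, 1, function(v) {
    mu <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(v)))
    (v - mu) / s
  }))
  colnames(z) <- colnames(m)
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning(sprintf("zero-variance protein(s) exported as all-zero rows: %s",
                    paste(ids[!is.na(sds) & sds == 0], collapse = ", ")))
  z
}
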