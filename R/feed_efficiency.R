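#' Coefficients for energy-corrected milk and predicted intake
#'
#' Returns the parameter set used throughout the feed-efficiency module:
#' the per-component energy weights of the energy-corrected-milk (ECM)
#' formula for standard milk (3.5% fat, 3.5% protein, 5% lactose, 0.714
#' Mcal/kg), and the coefficients of the NRC-style predicted dry-matter
#' intake (DMI) equation fitted to Holstein herd intake data.
#'
#' The intake equation is
#' \deqn{\widehat{DMI} = (a\,ECM + b\,BW^{c}) \times
#'       \left(1 - e^{-r\,(DIM/7 + o)}\right)}
#' with `a = 0.36`, `b = 0.123`, `c = 0.73`, lag rate `r = 0.22` and lag
#' offset `o = 5.67` (weeks-equivalent). The lag rate is stored as a
#' positive magnitude: only `1 - exp(-0.22 * (DIM/7 + 5.67))` yields the
#' (0, 1) early-lactation intake ramp expected of NRC-style lactation
#' curves; a negative rate would make the factor large and negative.
#'
#' @param ecm_fat_coef,ecm_protein_coef,ecm_lactose_coef Energy weights of
#'   milk fat, protein and lactose percentages in the ECM formula.
#' @param ecm_divisor Energy density of standard milk used to rescale the
#'   weighted component sum back to kg/d.
#' @param a Weight of ECM (kg/d) in predicted DMI.
#' @param b,c Coefficients of the metabolic body-weight term `b * BW^c`.
#' @param lag_rate Positive rate of the early-lactation intake lag.
#' @param lag_offset Offset (in weeks-equivalent) of the intake lag.
#' @return A list of class `efficiency_params`.
#' @examples
#' efficiency_params()
#' @export
efficiency_params <- function(ecm_fat_coef = 0.3887,
                              ecm_protein_coef = 0.2356,
                              ecm_lactose_coef = 0.1653,
                              ecm_divisor = 3.1338,
                              a = 0.36, b = 0.123, c = 0.73,
                              lag_rate = 0.22, lag_offset = 5.67) {
  p <- list(ecm_fat_coef = ecm_fat_coef, ecm_protein_coef = ecm_protein_coef,
            ecm_lactose_coef = ecm_lactose_coef, ecm_divisor = ecm_divisor,
            a = a, b = b, c = c, lag_rate = lag_rate, lag_offset = lag_offset)
  for (nm in names(p)) assert_numeric_finite(p[[nm]], nm)
  assert_positive(p$lag_rate, "lag_rate")
  assert_positive(p$ecm_divisor, "ecm_divisor")
  structure(p, class = "efficiency_params")
}

#' Energy-corrected milk yield
#'
#' Rescales milk yield to a standard energy density using the component
#' weights of [efficiency_params()]:
#' \deqn{ECM = milk \times (0.3887\,fat\% + 0.2356\,protein\% +
#'       0.1653\,lactose\%) / 3.1338}
#' ECM is linear (homogeneous of degree 1) in milk yield.
#'
#' @param milk Milk yield, kg/d (non-negative; vectorized).
#' @param fat_pct,protein_pct,lactose_pct Milk composition, % (mass/mass).
#' @param params An [efficiency_params()] object.
#' @return ECM, kg/d.
#' @examples
#' compute_ecm(50.3, 2.99, 2.86, 4.86)
#' @export
compute_ecm <- function(milk, fat_pct, protein_pct, lactose_pct,
                        params = efficiency_params()) {
  assert_nonneg(milk, "milk")
  assert_pct(fat_pct, "fat_pct")
  assert_pct(protein_pct, "protein_pct")
  assert_pct(lactose_pct, "lactose_pct")
  milk * (params$ecm_fat_coef * fat_pct +
            params$ecm_protein_coef * protein_pct +
            params$ecm_lactose_coef * lactose_pct) / params$ecm_divisor
}

#' Predicted dry-matter intake
#'
#' NRC-style expected intake given energy-corrected milk, body weight and
#' days in milk; see [efficiency_params()] for the equation and
#' coefficients. Output is strictly positive and monotone increasing in
#' all three inputs.
#'
#' @param ecm Energy-corrected milk, kg/d (non-negative).
#' @param bw Body weight, kg (positive).
#' @param dim Days in milk (positive).
#' @inheritParams compute_ecm
#' @return Predicted DMI, kg/d.
#' @examples
#' predict_dmi(40.4, 575.4, 110)
#' @export
predict_dmi <- function(ecm, bw, dim, params = efficiency_params()) {
  assert_nonneg(ecm, "ecm")
  assert_positive(bw, "bw")
  assert_positive(dim, "dim")
  (params$a * ecm + params$b * bw^params$c) *
    (1 - exp(-params$lag_rate * (dim / 7 + params$lag_offset)))
}

validate_performance <- function(records) {
  assert_columns(records, c("cow_id", "day", "dim", "bw_kg", "dmi_kg",
                            "milk_kg", "fat_pct", "protein_pct",
                            "lactose_pct"), "records")
  assert_positive(records$dim, "dim")
  assert_positive(records$bw_kg, "bw_kg")
  assert_nonneg(records$dmi_kg, "dmi_kg")
  assert_nonneg(records$milk_kg, "milk_kg")
  assert_pct(records$fat_pct, "fat_pct")
  assert_pct(records$protein_pct, "protein_pct")
  assert_pct(records$lactose_pct, "lactose_pct")
  invisible(records)
}

#' Score cows for feed efficiency over an evaluation window
#'
#' Computes, per cow, the window means of dry-matter intake, daily
#' energy-corrected milk and daily predicted intake, residual feed intake
#' `rfi = mean(DMI) - mean(predicted DMI)`, and the efficiency ratio
#' `ECM/DMI`. ECM and predicted DMI are evaluated day by day and then
#' averaged, so body-weight and days-in-milk drift inside the window is
#' honoured. The efficiency class is initialized to `"MID"`; see
#' [classify_efficiency()].
#'
#' @param records Data frame of daily records with columns `cow_id, day,
#'   dim, bw_kg, dmi_kg, milk_kg, fat_pct, protein_pct, lactose_pct`.
#' @param window_days If not `NULL`, only the first `window_days` days of
#'   each cow (by ascending `day`) enter the means.
#' @inheritParams compute_ecm
#' @return Data frame with one row per cow: `cow_id, n_days, mean_dmi,
#'   mean_ecm, mean_bw, pred_dmi, rfi, ecm_per_dmi, class`. `ecm_per_dmi`
#'   is `NA` when the mean intake is zero.
#' @export
score_cows <- function(records, window_days = NULL,
                       params = efficiency_params()) {
  if (nrow(records) == 0) stop_validation("records", "no records supplied")
  validate_performance(records)
  split_recs <- split(records, records$cow_id)
  out <- lapply(split_recs, function(r) {
    r <- r[order(r$day), , drop = FALSE]
    if (!is.null(window_days)) r <- utils::head(r, window_days)
    ecm <- compute_ecm(r$milk_kg, r$fat_pct, r$protein_pct, r$lactose_pct,
                       params)
    pred <- predict_dmi(ecm, r$bw_kg, r$dim, params)
    mean_dmi <- mean(r$dmi_kg)
    data.frame(cow_id = r$cow_id[1], n_days = nrow(r),
               mean_dmi = mean_dmi, mean_ecm = mean(ecm),
               mean_bw = mean(r$bw_kg), pred_dmi = mean(pred),
               rfi = mean_dmi - mean(pred),
               ecm_per_dmi = if (mean_dmi > 0) mean(ecm) / mean_dmi
                             else NA_real_,
               class = "MID", stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, out)
  rownames(scores) <- NULL
  if (anyNA(scores$ecm_per_dmi))
    warning("mean DMI is zero for some cows; ecm_per_dmi set to NA")
  scores
}

#' Classify cows into high-, mid- and low-efficiency groups
#'
#' Sorts cows ascending by residual feed intake and labels the
#' `floor(fraction * N)` cows with the lowest RFI as `"HEF"` (high
#' efficiency: they ate less than predicted), the same number with the
#' highest RFI as `"LEF"`, and everyone else `"MID"`. Ties at a group
#' boundary are broken by ascending `cow_id` so the assignment is
#' deterministic.
#'
#' @param scores Data frame from [score_cows()] (needs `cow_id`, `rfi`).
#' @param fraction Proportion assigned to each extreme group, in (0, 0.5].
#' @return `scores` with the `class` column filled, sorted by ascending
#'   `rfi`.
#' @export
classify_efficiency <- function(scores, fraction = 0.20) {
  assert_columns(scores, c("cow_id", "rfi"), "scores")
  if (!(fraction > 0 && fraction <= 0.5))
    stop_validation("fraction", "must lie in (0, 0.5]")
  n <- nrow(scores)
  if (n < 2) stop_validation("scores", "need at least 2 cows")
  n_grp <- floor(fraction * n)
  if (n_grp == 0) stop("cohort too small: floor(fraction * N) = 0",
                       call. = FALSE)
  ord <- order(scores$rfi, scores$cow_id)
  scores <- scores[ord, , drop = FALSE]
  scores$class <- "MID"
  scores$class[seq_len(n_grp)] <- "HEF"
  scores$class[seq(n - n_grp + 1, n)] <- "LEF"
  rownames(scores) <- NULL
  scores
}

#' Residual feed intake as a regression residual
#'
#' Alternative RFI estimator for users without fitted intake-equation
#' coefficients: residuals of an ordinary least-squares fit of mean intake
#' on mean ECM and metabolic body weight (`bw^0.75`). Residuals sum to
#' zero, so a positive residual marks a cow eating more than the herd
#' regression predicts.
#'
#' @param scores Data frame with `mean_dmi`, `mean_ecm`, `mean_bw`.
#' @return Numeric vector of per-cow residuals (kg/d), in input row order.
#' @export
regression_rfi <- function(scores) {
  assert_columns(scores, c("mean_dmi", "mean_ecm", "mean_bw"), "scores")
  if (nrow(scores) < 3) stop_validation("scores", "need at least 3 cows")
  fit <- stats::lm(mean_dmi ~ mean_ecm + I(mean_bw^0.75), data = scores)
  if (fit$rank < 3)
    stop("rank-deficient design: ECM and metabolic body weight are collinear",
         call. = FALSE)
  unname(stats::residuals(fit))
}
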