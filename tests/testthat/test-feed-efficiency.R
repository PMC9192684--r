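test_that("energy-corrected milk matches the component formula", {
  # zero milk and divisor cancellation
  expect_equal(compute_ecm(0, 3, 3, 5), 0)
  # pick composition so the weighted sum equals the divisor -> ecm = milk
  f <- 3; p <- 3; l <- (3.1338 - 0.3887 * f - 0.2356 * p) / 0.1653
  expect_equal(compute_ecm(28.7, f, p, l), 28.7)
  # hand evaluation on typical high-efficiency group means
  expect_equal(compute_ecm(50.3, 2.99, 2.86, 4.86), 42.3642753526071,
               tolerance = 1e-12)
  # homogeneous of degree 1 in milk
  expect_equal(compute_ecm(2 * 37.2, 3.1, 3.0, 4.9),
               2 * compute_ecm(37.2, 3.1, 3.0, 4.9))
  expect_error(compute_ecm(-1, 3, 3, 5), "milk")
  expect_error(compute_ecm(10, -0.5, 3, 5), "fat_pct")
})

test_that("predicted intake follows the lagged NRC-style equation", {
  expect_equal(predict_dmi(40.4, 575.4, 110), 27.0228401358696,
               tolerance = 1e-12)
  # at zero ECM and late lactation the lag ramp saturates at b * bw^c
  expect_equal(predict_dmi(0, 650, 5000), 0.123 * 650^0.73,
               tolerance = 1e-6)
  # monotone in dim, ecm and bw; finite and positive over the working range
  expect_true(predict_dmi(30, 600, 200) > predict_dmi(30, 600, 100))
  expect_true(predict_dmi(35, 600, 100) > predict_dmi(30, 600, 100))
  expect_true(predict_dmi(30, 650, 100) > predict_dmi(30, 600, 100))
  grid <- expand.grid(bw = c(300, 600, 900), dim = c(1, 250, 500),
                      ecm = c(0, 40, 80))
  v <- predict_dmi(grid$ecm, grid$bw, grid$dim)
  expect_true(all(is.finite(v) & v > 0))
  expect_error(predict_dmi(30, -5, 100), "bw")
  expect_error(predict_dmi(30, 600, 0), "dim")
})

test_that("per-cow scoring averages daily predictions over the window", {
  # intake identical to prediction -> RFI 0; constant over-eating -> RFI 1
  r0 <- make_records()
  expect_equal(score_cows(r0)$rfi, 0, tolerance = 1e-12)
  r1 <- make_records(); r1$dmi_kg <- r1$dmi_kg + 1
  expect_equal(score_cows(r1)$rfi, 1, tolerance = 1e-12)

  # 3-day toy against frozen day-by-day arithmetic
  r <- make_records(days = 1:3, dim0 = 100, bw = 600, milk = 45,
                    fat = 3, protein = 3, lactose = 4.9, dmi = c(27, 28, 26))
  s <- score_cows(r)
  expect_equal(s$mean_ecm, 38.5248420448018, tolerance = 1e-12)
  expect_equal(s$pred_dmi, 26.6652395725463, tolerance = 1e-12)
  expect_equal(s$rfi, 27 - 26.6652395725463, tolerance = 1e-12)
  expect_equal(s$ecm_per_dmi, s$mean_ecm / 27)

  # a single record equals direct formula evaluation
  r1d <- make_records(days = 1, dmi = 25)
  s1 <- score_cows(r1d)
  expect_equal(s1$rfi, 25 - predict_dmi(compute_ecm(45, 3, 3, 4.9), 600, 100))

  # window subsetting takes the first n days by day order
  rw <- make_records(days = 1:10, dmi = c(rep(30, 5), rep(10, 5)))
  expect_equal(score_cows(rw, window_days = 5)$mean_dmi, 30)

  expect_error(score_cows(r0[0, ]), "records")
  rz <- make_records(dmi = c(0, 0, 0), milk = 0)
  expect_warning(sz <- score_cows(rz), "mean DMI is zero")
  expect_true(is.na(sz$ecm_per_dmi))
})

test_that("efficiency classification labels the RFI extremes", {
  mk_scores <- function(rfi) data.frame(
    cow_id = sprintf("c%03d", seq_along(rfi)), rfi = rfi,
    class = "MID", stringsAsFactors = FALSE)

  s10 <- classify_efficiency(mk_scores(c(3, -2, 0, 1, -1, 2, 0.5, -0.5, 4, -3)))
  expect_equal(table(s10$class)[c("HEF", "LEF", "MID")],
               table(factor(c(rep("HEF", 2), rep("LEF", 2), rep("MID", 6)),
                            levels = c("HEF", "LEF", "MID"))),
               ignore_attr = TRUE)
  expect_true(all(diff(s10$rfi) >= 0))
  expect_true(all(s10$rfi[s10$class == "HEF"] <= min(s10$rfi[s10$class == "MID"])))

  # a 155-cow cohort at 20% gives 31 per extreme group
  set.seed(11)
  s155 <- classify_efficiency(mk_scores(rnorm(155)))
  expect_equal(sum(s155$class == "HEF"), 31)
  expect_equal(sum(s155$class == "LEF"), 31)
  expect_equal(sum(s155$class == "MID"), 155 - 62)

  # all-tied RFI: deterministic by cow id, group sizes unchanged
  tied <- classify_efficiency(mk_scores(rep(1, 10)))
  expect_equal(tied$cow_id[tied$class == "HEF"], c("c001", "c002"))
  expect_equal(tied$cow_id[tied$class == "LEF"], c("c009", "c010"))

  expect_error(classify_efficiency(mk_scores(1:4), fraction = 0.2),
               "cohort too small")
  expect_error(classify_efficiency(mk_scores(1:10), fraction = 0.7),
               "fraction")
})

test_that("regression RFI reproduces OLS residual structure", {
  set.seed(5)
  sc <- data.frame(mean_ecm = runif(12, 30, 50),
                   mean_bw = runif(12, 500, 700))
  # intake exactly linear in ECM and metabolic weight -> zero residuals
  sc$mean_dmi <- 2 + 0.4 * sc$mean_ecm + 0.1 * sc$mean_bw^0.75
  expect_equal(regression_rfi(sc), rep(0, 12), tolerance = 1e-9)

  # one over-eater gets the unique large positive residual; residuals sum to 0
  sc2 <- sc; sc2$mean_dmi[4] <- sc2$mean_dmi[4] + 5
  res <- regression_rfi(sc2)
  expect_equal(which.max(res), 4)
  expect_equal(sum(res), 0, tolerance = 1e-9)

  sc3 <- sc; sc3$mean_bw <- 600  # constant bw -> collinear with intercept
  expect_error(regression_rfi(sc3), "rank-deficient")
})
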