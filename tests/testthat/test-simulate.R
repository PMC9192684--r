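test_that("generators are pure functions of their seed", {
  h1 <- simulate_herd(n_cows = 12, seed = 33)
  h2 <- simulate_herd(n_cows = 12, seed = 33)
  expect_identical(h1, h2)
  expect_false(identical(h1$records$dmi_kg,
                         simulate_herd(n_cows = 12, seed = 34)$records$dmi_kg))

  s1 <- simulate_peptides(n_proteins = 60, n_up = 3, n_down = 3, seed = 5)
  s2 <- simulate_peptides(n_proteins = 60, n_up = 3, n_down = 3, seed = 5)
  expect_identical(s1$table$intensities, s2$table$intensities)
  expect_identical(s1$truth, s2$truth)

  a1 <- simulate_annotations(paste0("P", 1:50), paste0("P", 1:5), seed = 2)
  a2 <- simulate_annotations(paste0("P", 1:50), paste0("P", 1:5), seed = 2)
  expect_identical(a1, a2)

  c1 <- simulate_ct(seed = 9)
  c2 <- simulate_ct(seed = 9)
  expect_identical(c1, c2)
})

test_that("herd generator is consistent with the scoring chain", {
  # no offsets, no noise: every cow scores RFI = 0
  h0 <- simulate_herd(n_cows = 10, efficiency_offset_sd = 0,
                      daily_noise_sd = 0, seed = 3)
  s0 <- score_cows(h0$records, window_days = 35)
  expect_equal(s0$rfi, rep(0, 10), tolerance = 1e-10)

  # generated records pass the performance validator (no error)
  h <- simulate_herd(n_cows = 15, seed = 8)
  expect_silent(s <- score_cows(h$records, window_days = 35))
  expect_equal(nrow(s), 15)
  expect_equal(sort(unique(h$records$cow_id)), sort(h$truth$cow_id))

  # true intake offsets drive the estimated RFI ordering
  rho <- sapply(1:5, function(seed) {
    hh <- simulate_herd(seed = seed)
    ss <- score_cows(hh$records, window_days = 35)
    m <- merge(ss, hh$truth, by = "cow_id")
    cor(m$rfi, m$offset, method = "spearman")
  })
  expect_true(all(rho >= 0.9))
})

test_that("peptide generator produces the configured structure", {
  sim <- simulate_peptides(n_proteins = 150, n_up = 5, n_down = 7,
                           missing_rate = 0.1, seed = 6)
  expect_s3_class(sim$table, "peptide_table")
  expect_equal(length(unique(sim$table$protein_id)), 150)
  expect_equal(ncol(sim$table$intensities), 10)
  expect_equal(sum(sim$truth$spiked), 12)
  expect_equal(sum(sim$truth$true_fc > 1), 5)
  expect_equal(sum(sim$truth$true_fc < -1), 7)
  expect_true(all(abs(sim$truth$true_fc[sim$truth$spiked]) >= 1.5 &
                    abs(sim$truth$true_fc[sim$truth$spiked]) <= 80))
  expect_true(all(sim$truth$true_fc[!sim$truth$spiked] == 1))
  # peptides per protein within 1..30
  npep <- table(sim$table$protein_id)
  expect_true(all(npep >= 1 & npep <= 30))
  # missingness near the configured rate and biased toward low intensities
  miss <- mean(is.na(sim$table$intensities))
  expect_gt(miss, 0.05); expect_lt(miss, 0.15)
  # left-censoring: peptide rows that lost values sit lower in intensity
  obs <- sim$table$intensities
  has_na <- rowSums(is.na(obs)) > 0
  expect_lt(median(rowMeans(obs[has_na, ], na.rm = TRUE)),
            median(rowMeans(obs[!has_na, ], na.rm = TRUE)))
  # no spikes, no noise, no missingness: every pipeline fold change is +/-1
  clean <- simulate_peptides(n_proteins = 40, n_up = 0, n_down = 0,
                             group_cv = 0, missing_rate = 0, seed = 2)
  pm <- rollup_top3(tic_normalize(clean$table)$table)
  d <- diff_abundance(pm, clean$groups)
  expect_equal(abs(d$fc_signed), rep(1, 40), tolerance = 1e-9)
})

test_that("annotation generator plants exactly one enriched term", {
  prot <- paste0("P", 1:200)
  spiked <- paste0("P", 1:20)
  sim <- simulate_annotations(prot, spiked, n_terms = 10,
                              enriched_odds = 10, seed = 3)
  expect_equal(length(sim$annotations), 10)
  expect_equal(sim$truth$enriched_term, names(sim$annotations)[1])
  t1 <- sim$annotations[[sim$truth$enriched_term]]
  others <- unlist(sim$annotations[-1])
  expect_gt(mean(t1 %in% spiked), mean(others %in% spiked))
  expect_error(simulate_annotations(prot, spiked, enriched_odds = 0.5),
               "enriched_odds")
  expect_error(simulate_annotations(prot, c("QQ"), seed = 1), "spiked_ids")
})

test_that("Ct generator encodes ratios recoverable by the RQ chain", {
  clean <- simulate_ct(true_ratios = c(G1 = 0.25, G2 = 2),
                       reference_sds = c(REF = 0), ct_noise_sd = 0, seed = 1)
  expect_silent(sel <- select_reference(clean$records, "REF"))
  for (g in c("G1", "G2")) {
    rq <- ddct_rq(clean$records, g, "REF")
    expect_equal(mean(rq$rq[rq$group == "HEF"]),
                 clean$truth$true_ratio[clean$truth$gene == g],
                 tolerance = 1e-12)
    expect_equal(mean(rq$rq[rq$group == "LEF"]), 1, tolerance = 1e-12)
  }
  # the most stable configured reference is the one selected
  sim <- simulate_ct(seed = 21)
  sel <- select_reference(sim$records,
                          c("GAPDH", "UXT", "BRPS2", "EIF4E", "ACTB"))
  expect_equal(sel$reference, "GAPDH")
})
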