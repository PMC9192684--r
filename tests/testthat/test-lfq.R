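test_that("TIC normalization equalizes per-sample totals to the median TIC", {
  # two samples with TICs 100 and 200 -> median 150 -> factors 1.5 and 0.75
  pt <- make_pt(cbind(c(60, 40), c(120, 80)), c("A", "B"))
  out <- tic_normalize(pt)
  expect_equal(out$report$scale_factor, c(1.5, 0.75))
  expect_equal(out$report$post_tic, c(150, 150))

  # already-equal TICs are untouched
  pt_eq <- make_pt(cbind(c(10, 20), c(5, 25), c(14, 16)), c("A", "B"))
  out_eq <- tic_normalize(pt_eq)
  expect_equal(out_eq$report$scale_factor, rep(1, 3))
  expect_identical(out_eq$table$intensities, pt_eq$intensities)

  # scaling one sample and renormalizing recovers the normalized table
  m <- pt_eq$intensities; m[, 2] <- m[, 2] * 2
  renorm <- tic_normalize(make_pt(m, c("A", "B")))
  expect_equal(renorm$table$intensities, out_eq$table$intensities,
               tolerance = 1e-12)

  # missing entries stay missing; post TICs equal within 1e-6 relative
  set.seed(21)
  mm <- matrix(runif(40, 1, 100), 10)
  mm[sample(40, 8)] <- NA
  nn <- tic_normalize(make_pt(mm, rep(c("A", "B"), 5)))
  expect_equal(is.na(nn$table$intensities), is.na(mm), ignore_attr = TRUE)
  tics <- colSums(nn$table$intensities, na.rm = TRUE)
  expect_lt(diff(range(tics)) / mean(tics), 1e-6)

  # an all-missing sample is an error naming the sample
  bad <- make_pt(cbind(c(1, 2), c(NA, NA)), c("A", "B"),
                 samples = c("ok", "empty"))
  expect_error(tic_normalize(bad), "empty")
})

test_that("top-3 rollup averages the globally most abundant peptides", {
  # 5 peptides, global ranking = within-sample order -> mean of top three
  m <- cbind(c(10, 8, 6, 4, 1), c(20, 16, 12, 8, 2))
  pm <- rollup_top3(make_pt(m, rep("P1", 5)))
  expect_equal(unname(pm$abundance["P1", ]), c(8, 16))
  expect_equal(pm$n_peptides_total, 5L)
  expect_equal(pm$n_peptides_used, 3L)

  # the one-or-two-peptide exception: all peptides enter the mean
  pm2 <- rollup_top3(make_pt(cbind(c(4, 6), c(10, 20)), rep("P1", 2)))
  expect_equal(unname(pm2$abundance["P1", ]), c(5, 15))
  expect_equal(pm2$n_peptides_used, 2L)

  # permuting peptide rows and sample columns leaves the matrix unchanged
  set.seed(3)
  mv <- matrix(runif(24, 1, 50), 8)
  prot <- c("P1", "P1", "P2", "P1", "P2", "P3", "P1", "P2")
  base <- rollup_top3(make_pt(mv, prot))
  perm <- sample(8)
  mperm <- mv[perm, c(2, 3, 1)]
  colnames(mperm) <- paste0("S", c(2, 3, 1))
  shuf <- peptide_table(mperm, paste0("pep", seq_len(8))[perm], prot[perm])
  reord <- rollup_top3(shuf)
  expect_equal(reord$abundance[base$protein_id, colnames(base$abundance)],
               base$abundance)

  # abundance lies within [min, max] of the protein's peptides per sample
  for (p in base$protein_id) {
    sub <- mv[prot == p, , drop = FALSE]
    expect_true(all(base$abundance[p, ] >= apply(sub, 2, min) - 1e-12))
    expect_true(all(base$abundance[p, ] <= apply(sub, 2, max) + 1e-12))
  }

  # missing handling: abundance missing iff all selected peptides missing
  m3 <- cbind(c(10, 8, 6), c(NA, NA, NA), c(NA, 4, NA))
  pm3 <- rollup_top3(make_pt(m3, rep("P1", 3)))
  expect_equal(unname(pm3$abundance["P1", ]), c(8, NA, 4))
})

test_that("normalization and rollup commute with per-sample scaling", {
  set.seed(8)
  m <- matrix(rlnorm(60, 3, 1), 15)
  prot <- rep(paste0("P", 1:5), 3)
  pt <- make_pt(m, prot)
  factors <- tic_normalize(pt)$report$scale_factor
  a <- rollup_top3(tic_normalize(pt)$table)$abundance
  b <- sweep(rollup_top3(pt)$abundance, 2, factors, `*`)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("log transform is elementwise and reversible", {
  pm <- rollup_top3(make_pt(cbind(c(1, 8), c(2, NA)), c("A", "B")))
  lg <- log_transform(pm, base = 2)
  expect_equal(unname(lg$abundance), cbind(c(0, 3), c(1, NA)))
  expect_equal(2^lg$abundance, pm$abundance, tolerance = 1e-12)
  expect_error(log_transform(lg), "log scale")
  pm0 <- rollup_top3(make_pt(cbind(c(0, 1), c(2, 3)), c("A", "B")))
  expect_error(log_transform(pm0), "missing upstream")
})

test_that("PCA summary orders variance and separates shifted groups", {
  set.seed(42)
  base <- matrix(rnorm(50 * 6, 10, 1), 50)
  shifted <- base
  shifted[, 4:6] <- shifted[, 4:6] + 3   # strong group shift
  rownames(shifted) <- paste0("P", 1:50)
  colnames(shifted) <- paste0("S", 1:6)
  pm <- protein_matrix(shifted, rep(3, 50), rep(3, 50), log_base = 2)
  res <- pca_summary(pm)
  expect_true(all(diff(res$var_explained) <= 1e-8))
  expect_equal(sum(res$var_explained), 100)
  expect_true(all(res$var_explained >= 0))
  # groups separate on PC1: silhouette along PC1 is positive
  g <- rep(c(1, 2), each = 3)
  pc1 <- res$scores$pc1
  expect_gt(abs(mean(pc1[g == 1]) - mean(pc1[g == 2])),
            max(tapply(pc1, g, sd)))

  # identical samples sit at identical coordinates
  dup <- shifted; dup[, 2] <- dup[, 1]
  res_dup <- pca_summary(protein_matrix(dup, rep(3, 50), rep(3, 50),
                                        log_base = 2))
  expect_equal(res_dup$scores$pc1[1], res_dup$scores$pc1[2], tolerance = 1e-8)
  expect_equal(res_dup$scores$pc2[1], res_dup$scores$pc2[2], tolerance = 1e-8)

  # proteins with missing values are excluded; too few complete -> error
  holey <- shifted; holey[1:49, 1] <- NA
  expect_error(pca_summary(protein_matrix(holey, rep(3, 50), rep(3, 50),
                                          log_base = 2)), "complete-case")
})
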