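with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate a herd of daily performance records with known efficiency
#'
#' Emulates an individual feed-efficiency evaluation: each cow receives a
#' latent intake offset (kg/d of intake above or below her predicted
#' intake — the ground-truth inefficiency the RFI estimator should
#' recover), her milk yield, composition and body weight are drawn around
#' herd means, and daily dry-matter intake is the intake-equation
#' prediction plus the offset plus day-to-day noise. Defaults mirror a
#' 155-cow mid-lactation Holstein cohort evaluated over 35 days.
#'
#' The truth table is emitted alongside the records and is never consumed
#' by the scoring functions under test.
#'
#' @param n_cows Cohort size (>= 10).
#' @param window_days Evaluation window length, days.
#' @param dim_range Range of days-in-milk at window start.
#' @param bw_mean,bw_sd Body weight distribution across cows, kg.
#' @param milk_mean,milk_sd Milk yield distribution across cows, kg/d.
#' @param fat_mean,protein_mean,lactose_mean Herd-mean milk composition, %.
#' @param comp_sd Between-cow SD applied to each composition component, %.
#' @param milk_day_sd Day-to-day milk yield SD within cow, kg/d.
#' @param efficiency_offset_sd Between-cow SD of the latent intake offset,
#'   kg/d.
#' @param daily_noise_sd Day-to-day intake noise SD, kg/d.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param params [efficiency_params()] used for the intake prediction.
#' @return A list: `records` (daily performance table accepted by
#'   [score_cows()]) and `truth` (`cow_id`, `offset`).
#' @export
simulate_herd <- function(n_cows = 155, window_days = 35,
                          dim_range = c(80, 140),
                          bw_mean = 590, bw_sd = 35,
                          milk_mean = 47, milk_sd = 5,
                          fat_mean = 3.05, protein_mean = 2.98,
                          lactose_mean = 4.91, comp_sd = 0.15,
                          milk_day_sd = 1.5,
                          efficiency_offset_sd = 2.0, daily_noise_sd = 1.0,
                          seed = 1, params = efficiency_params()) {
  if (n_cows < 10) stop_validation("n_cows", "must be >= 10")
  for (f in c("window_days")) assert_positive(get(f), f)
  for (f in c("bw_sd", "milk_sd", "comp_sd", "milk_day_sd",
              "efficiency_offset_sd", "daily_noise_sd"))
    assert_nonneg(get(f), f)
  with_seed(seed, {
    cow_id <- sprintf("cow%03d", seq_len(n_cows))
    offset <- stats::rnorm(n_cows, 0, efficiency_offset_sd)
    bw <- pmax(stats::rnorm(n_cows, bw_mean, bw_sd), 350)
    milk_cow <- pmax(stats::rnorm(n_cows, milk_mean, milk_sd), 5)
    fat <- pmax(stats::rnorm(n_cows, fat_mean, comp_sd), 1)
    protein <- pmax(stats::rnorm(n_cows, protein_mean, comp_sd), 1)
    lactose <- pmax(stats::rnorm(n_cows, lactose_mean, comp_sd), 3)
    dim0 <- sample(seq(dim_range[1], dim_range[2]), n_cows, replace = TRUE)
    recs <- lapply(seq_len(n_cows), function(i) {
      day <- seq_len(window_days)
      milk <- pmax(milk_cow[i] + stats::rnorm(window_days, 0, milk_day_sd), 0)
      dim <- dim0[i] + day - 1
      ecm <- compute_ecm(milk, fat[i], protein[i], lactose[i], params)
      pred <- predict_dmi(ecm, bw[i], dim, params)
      dmi <- pmax(pred + offset[i] +
                    stats::rnorm(window_days, 0, daily_noise_sd), 0)
      data.frame(cow_id = cow_id[i], day = day, dim = dim, bw_kg = bw[i],
                 dmi_kg = dmi, milk_kg = milk, fat_pct = fat[i],
                 protein_pct = protein[i], lactose_pct = lactose[i],
                 stringsAsFactors = FALSE)
    })
    list(records = do.call(rbind, recs),
         truth = data.frame(cow_id = cow_id, offset = offset,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a label-free peptide intensity table with spiked proteins
#'
#' Emulates the structure of a quantified bovine adipose proteome in a
#' small two-group design: log-normal protein abundances, a truncated
#' geometric number of peptides per protein, per-peptide response factors,
#' per-sample total-ion-current multipliers, log-normal within-group
#' noise, and left-censored (intensity-dependent) missingness. A
#' configurable subset of proteins is spiked with true fold changes
#' (applied at the protein level, so all of a protein's peptides shift
#' together) whose magnitudes are drawn log-uniformly, allowing the very
#' large ratios a strongly differential protein can show.
#'
#' Defaults mirror the study conditions the package targets: 2,260
#' proteins, 1-30 peptides each (mean about 8), 5 case vs 5 control
#' samples, 43 up- and 58 down-spiked proteins with |FC| in [1.5, 80],
#' about 20% within-group CV and a 10% missing rate.
#'
#' @param n_proteins Number of proteins.
#' @param n_case,n_ctrl Samples per group.
#' @param case,control Group labels.
#' @param peptide_mean Mean peptides per protein (truncated geometric).
#' @param peptide_max Maximum peptides per protein.
#' @param abundance_meanlog,abundance_sdlog Protein abundance log-normal
#'   parameters (natural log).
#' @param response_sdlog Peptide response-factor log-SD.
#' @param tic_sdlog Per-sample TIC multiplier log-SD.
#' @param n_up,n_down Numbers of up- and down-spiked proteins.
#' @param fc_range Range of spiked |FC|, drawn log-uniformly.
#' @param group_cv Within-group coefficient of variation of peptide
#'   intensities.
#' @param missing_rate Overall expected fraction of missing entries;
#'   missingness is biased toward low intensities. Set 0 for clean oracle
#'   tests.
#' @param seed Integer seed.
#' @return A list: `table` (a [peptide_table()]), `groups` (sample_id ->
#'   group data frame) and `truth` (`protein_id, spiked, true_fc` with the
#'   signed convention of [fold_change()]; unspiked proteins have
#'   `true_fc = 1`).
#' @export
simulate_peptides <- function(n_proteins = 2260, n_case = 5, n_ctrl = 5,
                              case = "HEF", control = "LEF",
                              peptide_mean = 8, peptide_max = 30,
                              abundance_meanlog = log(1e6),
                              abundance_sdlog = 1.2,
                              response_sdlog = 1, tic_sdlog = 0.2,
                              n_up = 43, n_down = 58,
                              fc_range = c(1.5, 80),
                              group_cv = 0.2, missing_rate = 0.1,
                              seed = 1) {
  if (n_up + n_down > n_proteins)
    stop_validation("n_up/n_down", "spike counts exceed n_proteins")
  if (any(fc_range < 1)) stop_validation("fc_range", "bounds must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_validation("missing_rate", "must lie in [0, 1)")
  with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    npep <- pmin(stats::rgeom(n_proteins, 1 / peptide_mean) + 1L, peptide_max)
    base <- stats::rlnorm(n_proteins, abundance_meanlog, abundance_sdlog)
    # spikes are drawn from the lower abundance half: TIC normalization
    # assumes the dominant bulk signal is non-differential, and with fold
    # changes reaching 80x a spiked high-abundance protein would move the
    # total ion current itself
    spikeable <- which(base <= stats::quantile(base, 0.5))
    spiked_idx <- sample(spikeable, n_up + n_down)
    up_idx <- spiked_idx[seq_len(n_up)]
    down_idx <- setdiff(spiked_idx, up_idx)
    fc_mag <- exp(stats::runif(n_up + n_down,
                               log(fc_range[1]), log(fc_range[2])))
    ratio <- rep(1, n_proteins)            # case/control abundance ratio
    ratio[up_idx] <- fc_mag[seq_len(n_up)]
    if (n_down > 0) ratio[down_idx] <- 1 / fc_mag[n_up + seq_len(n_down)]
    sample_id <- c(sprintf("%s_%d", case, seq_len(n_case)),
                   sprintf("%s_%d", control, seq_len(n_ctrl)))
    group <- c(rep(case, n_case), rep(control, n_ctrl))
    n_samp <- n_case + n_ctrl
    tic_mult <- stats::rlnorm(n_samp, 0, tic_sdlog)
    noise_sdlog <- sqrt(log(1 + group_cv^2))
    pep_protein <- rep(prot, npep)
    pep_ratio <- rep(ratio, npep)
    pep_base <- rep(base, npep) *
      stats::rlnorm(sum(npep), 0, response_sdlog)
    pep_id <- paste0("pep_", seq_along(pep_protein))
    mean_mat <- outer(pep_base, rep(1, n_samp))
    mean_mat[, group == case] <- mean_mat[, group == case] * pep_ratio
    noise <- matrix(stats::rlnorm(length(mean_mat), 0, noise_sdlog),
                    nrow = nrow(mean_mat))
    m <- sweep(mean_mat * noise, 2, tic_mult, `*`)
    colnames(m) <- sample_id
    if (missing_rate > 0) {
      # left-censored-like: miss prob linear in the intensity rank so the
      # expected overall rate equals missing_rate exactly
      rk <- rank(m, ties.method = "average")
      pmiss <- pmin(2 * missing_rate * (1 - rk / (length(m) + 1)), 1)
      drop <- stats::runif(length(m)) < pmiss
      # never silence a whole sample
      for (j in seq_len(ncol(m))) {
        jj <- (j - 1) * nrow(m) + seq_len(nrow(m))
        if (all(drop[jj])) drop[jj[which.max(m[, j])]] <- FALSE
      }
      m[matrix(drop, nrow = nrow(m))] <- NA_real_
    }
    truth <- data.frame(protein_id = prot,
                        spiked = seq_len(n_proteins) %in% spiked_idx,
                        true_fc = ifelse(ratio >= 1, ratio, -1 / ratio),
                        stringsAsFactors = FALSE)
    list(table = peptide_table(m, pep_id, pep_protein),
         groups = data.frame(sample_id = sample_id, group = group,
                             stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate annotation sets with one enriched term
#'
#' Draws random term memberships over a protein universe; one designated
#' term samples its members with `enriched_odds`-fold higher weight on a
#' supplied "interesting" subset (e.g. the spiked proteins of
#' [simulate_peptides()]). With odds 1 the designated term is an ordinary
#' random term.
#'
#' @param protein_ids Universe of protein ids.
#' @param spiked_ids Ids preferentially sampled into the enriched term.
#' @param n_terms Number of terms (>= 1).
#' @param term_size_range Range of term sizes, drawn uniformly.
#' @param enriched_odds Sampling-weight ratio for `spiked_ids` in the
#'   enriched term (>= 1).
#' @param seed Integer seed.
#' @return A list: `annotations` (named list, GMT-style) and `truth`
#'   (`enriched_term`).
#' @export
simulate_annotations <- function(protein_ids, spiked_ids, n_terms = 20,
                                 term_size_range = c(20, 80),
                                 enriched_odds = 8, seed = 1) {
  if (n_terms < 1) stop_validation("n_terms", "must be >= 1")
  if (enriched_odds < 1) stop_validation("enriched_odds", "must be >= 1")
  if (length(setdiff(spiked_ids, protein_ids)) > 0)
    stop_validation("spiked_ids", "must be a subset of protein_ids")
  with_seed(seed, {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    sizes <- pmin(sizes, length(protein_ids))
    w <- ifelse(protein_ids %in% spiked_ids, enriched_odds, 1)
    sets <- vector("list", n_terms)
    names(sets) <- sprintf("T%03d", seq_len(n_terms))
    sets[[1]] <- sample(protein_ids, sizes[1], prob = w)
    for (i in seq_len(n_terms)[-1])
      sets[[i]] <- sample(protein_ids, sizes[i])
    attr(sets, "description") <- stats::setNames(
      c("enriched term", rep("random term", n_terms - 1))[seq_len(n_terms)],
      names(sets))
    list(annotations = sets,
         truth = list(enriched_term = names(sets)[1]))
  })
}

#' Simulate qPCR Ct tables with known expression ratios
#'
#' Generates cycle-threshold values under perfect per-cycle doubling: per
#' sample a shared loading shift (which must cancel through the reference
#' gene), per gene a base Ct, the configured case/control expression
#' ratios lowering or raising the case samples' target Ct by
#' `-log2(ratio)`, reference genes at configured Ct stability, and
#' Gaussian cycle noise. Default target ratios follow typical
#' feed-efficiency expression contrasts (RBM39 0.37, ITGAV 0.78, STAT2
#' 1.03, DDX39A 0.77 in case vs control).
#'
#' @param true_ratios Named numeric vector: target gene -> case/control
#'   expression ratio.
#' @param reference_sds Named numeric vector: candidate reference gene ->
#'   gene-specific Ct SD (cycles); the most stable should be recoverable
#'   by [select_reference()].
#' @param n_per_group Samples per group.
#' @param case,control Group labels.
#' @param ct_noise_sd Gaussian Ct noise for target genes, cycles.
#' @param sample_effect_sd SD of the per-sample loading shift, cycles.
#' @param target_base_ct,reference_base_ct Baseline Ct levels.
#' @param seed Integer seed.
#' @return A list: `records` (Ct table for [ddct_rq()]) and `truth`
#'   (`gene, true_ratio`).
#' @export
simulate_ct <- function(true_ratios = c(RBM39 = 0.37, ITGAV = 0.78,
                                        STAT2 = 1.03, DDX39A = 0.77),
                        reference_sds = c(GAPDH = 0.1, UXT = 0.4,
                                          BRPS2 = 0.5, EIF4E = 0.6,
                                          ACTB = 0.3),
                        n_per_group = 5, case = "HEF", control = "LEF",
                        ct_noise_sd = 0.2, sample_effect_sd = 0.5,
                        target_base_ct = 26, reference_base_ct = 18,
                        seed = 1) {
  assert_positive(true_ratios, "true_ratios")
  assert_nonneg(reference_sds, "reference_sds")
  assert_nonneg(ct_noise_sd, "ct_noise_sd")
  with_seed(seed, {
    sample_id <- c(sprintf("%s_%d", case, seq_len(n_per_group)),
                   sprintf("%s_%d", control, seq_len(n_per_group)))
    group <- c(rep(case, n_per_group), rep(control, n_per_group))
    shift <- stats::rnorm(length(sample_id), 0, sample_effect_sd)
    rows <- list()
    for (g in names(true_ratios)) {
      dct <- ifelse(group == case, -log2(true_ratios[[g]]), 0)
      rows[[g]] <- data.frame(
        sample_id = sample_id, group = group, gene = g,
        ct = target_base_ct + shift + dct +
          stats::rnorm(length(sample_id), 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
    for (g in names(reference_sds)) {
      rows[[g]] <- data.frame(
        sample_id = sample_id, group = group, gene = g,
        ct = reference_base_ct + shift +
          stats::rnorm(length(sample_id), 0, reference_sds[[g]]),
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    list(records = records,
         truth = data.frame(gene = names(true_ratios),
                            true_ratio = unname(true_ratios),
                            stringsAsFactors = FALSE))
  })
}
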