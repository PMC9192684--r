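#' Construct a peptide intensity table
#'
#' Container for label-free peptide-level quantification: an intensity
#' matrix (peptides x samples) plus the peptide-to-protein map. Missing
#' observations are `NA` and are distinct from zero; zeros in input files
#' are conventionally recoded to `NA` by [read_peptides()] because
#' label-free pipelines report unobserved, not absent, peptides.
#'
#' @param intensities Numeric matrix, peptides in rows, samples in columns
#'   (column names = sample ids). Non-missing values must be non-negative.
#' @param peptide_id Character vector of unique peptide identifiers.
#' @param protein_id Character vector mapping each peptide to one protein.
#' @return An object of class `peptide_table`.
#' @export
peptide_table <- function(intensities, peptide_id, protein_id) {
  intensities <- as.matrix(intensities)
  if (is.null(colnames(intensities)) ||
      anyDuplicated(colnames(intensities)))
    stop_validation("intensities", "columns must carry unique sample ids")
  if (length(peptide_id) != nrow(intensities) ||
      length(protein_id) != nrow(intensities))
    stop_validation("peptide_id/protein_id",
                    "length must equal the number of intensity rows")
  if (anyDuplicated(peptide_id))
    stop_validation("peptide_id", "must be unique")
  if (anyNA(protein_id) || any(!nzchar(protein_id)))
    stop_validation("protein_id", "every peptide must map to one protein")
  v <- intensities[!is.na(intensities)]
  if (any(v < 0) || any(!is.finite(v)))
    stop_validation("intensities", "non-missing values must be finite and >= 0")
  rownames(intensities) <- peptide_id
  structure(list(intensities = intensities,
                 peptide_id = as.character(peptide_id),
                 protein_id = as.character(protein_id),
                 samples = colnames(intensities)),
            class = "peptide_table")
}

#' @export
print.peptide_table <- function(x, ...) {
  cat(sprintf("peptide_table: %d peptides, %d proteins, %d samples (%.1f%% missing)\n",
              nrow(x$intensities), length(unique(x$protein_id)),
              ncol(x$intensities),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Construct a protein abundance matrix
#'
#' @param abundance Numeric matrix, proteins x samples, `NA` = missing.
#' @param n_peptides_total Peptides mapped to each protein.
#' @param n_peptides_used Peptides entering the rollup (at most 3).
#' @param log_base `NA` for the raw intensity scale, or the logarithm base
#'   after [log_transform()].
#' @return An object of class `protein_matrix`.
#' @export
protein_matrix <- function(abundance, n_peptides_total, n_peptides_used,
                           log_base = NA_real_) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    stop_validation("abundance", "rows must carry protein ids")
  structure(list(abundance = abundance,
                 protein_id = rownames(abundance),
                 samples = colnames(abundance),
                 n_peptides_total = n_peptides_total,
                 n_peptides_used = n_peptides_used,
                 log_base = log_base),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$abundance), ncol(x$abundance),
              if (is.na(x$log_base)) "raw" else paste0("log", x$log_base)))
  invisible(x)
}

#' Total-ion-current normalization
#'
#' Scales every sample so its summed (non-missing) peptide intensity — the
#' total ion current, TIC — equals the median raw TIC across samples. The
#' median reference keeps one aberrant injection from dragging all scale
#' factors. Missing entries stay missing.
#'
#' @param table A [peptide_table()].
#' @return A list: `table` (normalized [peptide_table()]) and `report`
#'   (data frame of per-sample raw TIC, scale factor, post TIC).
#' @export
tic_normalize <- function(table) {
  stopifnot(inherits(table, "peptide_table"))
  m <- table$intensities
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0))
    stop(sprintf("sample(s) with no observed intensities: %s",
                 paste(colnames(m)[n_obs == 0], collapse = ", ")),
         call. = FALSE)
  tic <- colSums(m, na.rm = TRUE)
  if (any(tic <= 0))
    stop(sprintf("sample(s) with zero total ion current: %s",
                 paste(colnames(m)[tic <= 0], collapse = ", ")),
         call. = FALSE)
  factor <- stats::median(tic) / tic
  norm <- sweep(m, 2, factor, `*`)
  report <- data.frame(sample_id = colnames(m), raw_tic = unname(tic),
                       scale_factor = unname(factor),
                       post_tic = unname(colSums(norm, na.rm = TRUE)),
                       stringsAsFactors = FALSE)
  list(table = peptide_table(norm, table$peptide_id, table$protein_id),
       report = report)
}

#' Top-3 peptide rollup to protein abundances
#'
#' Protein abundance is the arithmetic mean of its three most abundant
#' peptides (all peptides when only one or two exist). Peptide abundance
#' rank is global: peptides are ordered by their mean intensity across all
#' samples (missing values excluded from both numerator and denominator),
#' so every sample is quantified from the same fixed peptide set — the
#' usual Top3/Hi-3 convention, which stabilizes between-sample ratios.
#' With `per_sample = TRUE` the top peptides are instead re-picked within
#' each sample among its observed values (sensitivity analysis only).
#'
#' A protein's abundance is missing in a sample iff all its selected
#' peptides are missing there.
#'
#' @param table A [peptide_table()].
#' @param top_n Number of peptides in the rollup (default 3).
#' @param per_sample Re-rank peptides within each sample instead of
#'   globally.
#' @return A [protein_matrix()] on the raw intensity scale, rows ordered
#'   by protein id.
#' @export
rollup_top3 <- function(table, top_n = 3, per_sample = FALSE) {
  stopifnot(inherits(table, "peptide_table"))
  m <- table$intensities
  if (nrow(m) == 0) stop_validation("table", "no peptides")
  prot <- sort(unique(table$protein_id))
  rows <- lapply(prot, function(p) {
    idx <- which(table$protein_id == p)
    sub <- m[idx, , drop = FALSE]
    if (per_sample) {
      ab <- apply(sub, 2, function(v) {
        v <- sort(v[!is.na(v)], decreasing = TRUE)
        if (length(v) == 0) NA_real_ else mean(v[seq_len(min(top_n, length(v)))])
      })
      used <- min(top_n, nrow(sub))
    } else {
      gm <- rowMeans(sub, na.rm = TRUE)
      gm[is.nan(gm)] <- -Inf  # fully-missing peptide: ranked last
      ord <- order(-gm, table$peptide_id[idx])
      keep <- ord[seq_len(min(top_n, length(ord)))]
      sel <- sub[keep, , drop = FALSE]
      ab <- colMeans(sel, na.rm = TRUE)
      ab[is.nan(ab)] <- NA_real_
      used <- length(keep)
    }
    list(ab = ab, total = length(idx), used = used)
  })
  abundance <- do.call(rbind, lapply(rows, `[[`, "ab"))
  rownames(abundance) <- prot
  colnames(abundance) <- table$samples
  protein_matrix(abundance,
                 n_peptides_total = vapply(rows, `[[`, 0L, "total"),
                 n_peptides_used = vapply(rows, `[[`, 0L, "used"))
}

#' Log-transform a protein matrix
#'
#' @param matrix A raw-scale [protein_matrix()]; all non-missing values
#'   must be strictly positive (treat zeros as missing upstream).
#' @param base Logarithm base (default 2).
#' @return A [protein_matrix()] on the log scale.
#' @export
log_transform <- function(matrix, base = 2) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (!is.na(matrix$log_base))
    stop_validation("matrix", "already on the log scale")
  v <- matrix$abundance[!is.na(matrix$abundance)]
  if (any(v <= 0))
    stop("non-positive abundances present: treat zeros/negatives as missing upstream",
         call. = FALSE)
  out <- matrix
  out$abundance <- log(matrix$abundance, base = base)
  out$log_base <- base
  out
}

#' PCA summary of a log-scale protein matrix
#'
#' Sample-level principal component analysis for quality control:
#' proteins with any missing value are excluded (complete-case), each
#' protein is centered (not unit-scaled — log intensities are already on a
#' common scale), and samples are projected on the components.
#'
#' @param matrix A log-scale [protein_matrix()].
#' @param scale. Unit-scale proteins before the decomposition.
#' @return A list: `scores` (data frame, per-sample coordinates on PC1 and
#'   PC2), `var_explained` (percentage per component, summing to 100),
#'   `n_proteins_used`.
#' @export
pca_summary <- function(matrix, scale. = FALSE) {
  stopifnot(inherits(matrix, "protein_matrix"))
  m <- matrix$abundance
  if (ncol(m) < 3) stop_validation("matrix", "need at least 3 samples")
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3)
    stop_validation("matrix", "fewer than 3 complete-case proteins")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = scale.)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(sample_id = colnames(matrix$abundance),
                       pc1 = pc$x[, 1], pc2 = pc$x[, 2],
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  list(scores = scores, var_explained = ve, n_proteins_used = nrow(m))
}
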