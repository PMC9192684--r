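#' Read daily cow performance records
#'
#' Expects a UTF-8 CSV with header `cow_id,day,dim,bw_kg,dmi_kg,milk_kg,
#' fat_pct,protein_pct,lactose_pct` and '.' decimals.
#'
#' @param path Path to cow_days.csv.
#' @return Validated data frame of daily records.
#' @export
read_cow_days <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$cow_id <- as.character(df$cow_id)
  validate_performance(df)
  df
}

#' Write per-cow efficiency scores
#'
#' @param scores Data frame from [classify_efficiency()].
#' @param path Output TSV path.
#' @export
write_efficiency <- function(scores, path) {
  scores <- scores[order(scores$rfi, scores$cow_id), , drop = FALSE]
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a peptide intensity table
#'
#' Expects a TSV with columns `peptide_id`, `protein_id`, then one
#' intensity column per sample. Empty cells and zeros are recoded to
#' missing (`NA`): label-free pipelines report unobserved peptides, and a
#' true zero intensity is not measurable.
#'
#' @param path Path to peptides.tsv.
#' @return A [peptide_table()].
#' @export
read_peptides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  assert_columns(df, c("peptide_id", "protein_id"), "peptides")
  samp <- setdiff(names(df), c("peptide_id", "protein_id"))
  if (length(samp) == 0) stop_validation("peptides", "no sample columns")
  m <- as.matrix(df[, samp, drop = FALSE])
  storage.mode(m) <- "double"
  m[!is.na(m) & m == 0] <- NA_real_
  colnames(m) <- samp
  peptide_table(m, as.character(df$peptide_id), as.character(df$protein_id))
}

#' Write a peptide table
#'
#' @param table A [peptide_table()].
#' @param path Output TSV path; missing values become empty cells.
#' @export
write_peptides <- function(table, path) {
  df <- data.frame(peptide_id = table$peptide_id,
                   protein_id = table$protein_id,
                   table$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Read a sample-to-group map
#'
#' @param path TSV with columns `sample_id`, `group`.
#' @return Data frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("sample_id", "group"), "samples")
  if (anyDuplicated(df$sample_id))
    stop_validation("samples", "duplicate sample_id")
  df
}

#' Write a protein matrix with peptide counts
#'
#' @param matrix A [protein_matrix()].
#' @param path Output TSV path.
#' @export
write_proteins <- function(matrix, path) {
  df <- data.frame(protein_id = matrix$protein_id,
                   n_peptides_total = matrix$n_peptides_total,
                   n_peptides_used = matrix$n_peptides_used,
                   matrix$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Read a qPCR Ct table
#'
#' @param path CSV with columns `sample_id, group, gene, ct`; technical
#'   replicates (duplicate sample-gene rows) are averaged on the Ct scale.
#' @return Validated Ct data frame.
#' @export
read_ct <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("sample_id", "group", "gene", "ct"), "ct")
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = df,
                          FUN = mean)
  validate_ct(agg)
  agg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}
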