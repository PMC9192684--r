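# fixture builders shared across test files

# tiny peptide table: values are a matrix (peptides x samples), NA = missing
make_pt <- function(values, protein_id,
                    samples = paste0("S", seq_len(ncol(values)))) {
  colnames(values) <- samples
  peptide_table(values, paste0("pep", seq_len(nrow(values))), protein_id)
}

# daily records for one or more cows at constant inputs
make_records <- function(cow_id = "c1", days = 1:3, dim0 = 100, bw = 600,
                         milk = 45, fat = 3, protein = 3, lactose = 4.9,
                         dmi = NULL, params = efficiency_params()) {
  ecm <- compute_ecm(milk, fat, protein, lactose, params)
  dim <- dim0 + days - 1
  pred <- predict_dmi(rep(ecm, length(days)), bw, dim, params)
  data.frame(cow_id = cow_id, day = days, dim = dim, bw_kg = bw,
             dmi_kg = if (is.null(dmi)) pred else dmi,
             milk_kg = milk, fat_pct = fat, protein_pct = protein,
             lactose_pct = lactose, stringsAsFactors = FALSE)
}

# independent pooled-variance t oracle (closed form, never the package path)
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K carry the annotation
  mean(hits >= k)
}
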