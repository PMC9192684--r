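#' Read annotation sets from a GMT file
#'
#' GMT is the tab-separated gene-set format: one term per line, fields
#' `term, description, member, member, ...`. Duplicate members within a
#' term are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (term id -> member ids), with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_validation("path", "empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stop_validation("path",
                    sprintf("GMT line(s) with fewer than 3 fields: %s",
                            paste(which(bad), collapse = ", ")))
  terms <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(terms)) stop_validation("path", "duplicate term ids")
  desc <- vapply(parts, `[[`, "", 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- terms
  names(desc) <- terms
  attr(sets, "description") <- desc
  sets
}

#' Write annotation sets to a GMT file
#'
#' @param sets Named list of character vectors, as from [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(t)
    paste(c(t, desc[[t]], sets[[t]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, tests whether the differential set contains more of the
#' term's members than expected from drawing `n` proteins at random from
#' the background of `N`, of which `K` carry the annotation: the upper
#' tail `P(X >= k)` of Hypergeometric(N, K, n). Annotation sets are
#' intersected with the background before counting, so proteins never
#' quantified cannot inflate a term. Depletion is not tested.
#'
#' The default background is the full quantified-protein universe (the set
#' actually at risk of being called differential); pass any other id set
#' to change it. Terms with fewer than `min_k` members in the background
#' are degenerate and are skipped (listed in the `skipped` attribute).
#'
#' @param daps Character vector of differential protein ids (must be a
#'   subset of `background`).
#' @param background Character vector: the protein universe.
#' @param annotations Named list of term member vectors ([read_gmt()]).
#' @param min_k Minimum annotated-in-background size for a term to be
#'   tested (default 2).
#' @return Data frame sorted by `p_hyper`: `term_id, term_name, N, K, n,
#'   k, p_hyper, p_adj, fold_enrichment`, with attribute `skipped`.
#' @export
hypergeom_enrich <- function(daps, background, annotations, min_k = 2) {
  background <- unique(as.character(background))
  daps <- unique(as.character(daps))
  if (length(background) == 0) stop_validation("background", "empty")
  stray <- setdiff(daps, background)
  if (length(stray) > 0)
    stop(sprintf("differential ids missing from the background: %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
    stop_validation("annotations", "must be a named list of member vectors")
  desc <- attr(annotations, "description")
  N <- length(background)
  n <- length(daps)
  K <- vapply(annotations, function(s) length(intersect(s, background)), 0L)
  keep <- K >= min_k
  skipped <- names(annotations)[!keep]
  rows <- lapply(names(annotations)[keep], function(term) {
    members <- intersect(annotations[[term]], background)
    k <- length(intersect(members, daps))
    Kt <- length(members)
    data.frame(term_id = term,
               term_name = if (!is.null(desc)) desc[[term]] else term,
               N = N, K = Kt, n = n, k = k,
               p_hyper = stats::phyper(k - 1, Kt, N - Kt, n,
                                       lower.tail = FALSE),
               fold_enrichment = if (n > 0 && Kt > 0)
                 (k / n) / (Kt / N) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      N = integer(0), K = integer(0), n = integer(0),
                      k = integer(0), p_hyper = numeric(0),
                      p_adj = numeric(0), fold_enrichment = numeric(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  out$p_adj <- bh_adjust(out$p_hyper)
  out <- out[order(out$p_hyper, out$term_id),
             c("term_id", "term_name", "N", "K", "n", "k",
               "p_hyper", "p_adj", "fold_enrichment")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; order-preserving, capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop_validation("p_values", "must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Fraction of an id set annotated to each term
#'
#' Pie-chart style category summary: for each term, the percentage of the
#' supplied ids that carry the annotation. Terms overlap, so percentages
#' need not sum to 100.
#'
#' @param ids Character vector of protein ids (nonempty).
#' @param annotations Named list of term member vectors.
#' @return Data frame: `term_id, n_ids, n_annotated, percent`.
#' @export
category_fractions <- function(ids, annotations) {
  ids <- unique(as.character(ids))
  if (length(ids) == 0) stop_validation("ids", "empty id set")
  k <- vapply(annotations, function(s) length(intersect(s, ids)), 0L)
  data.frame(term_id = names(annotations),
             n_ids = length(ids), n_annotated = unname(k),
             percent = unname(100 * k / length(ids)),
             stringsAsFactors = FALSE, row.names = NULL)
}
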