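#' Default pipeline configuration
#'
#' Returns the configuration skeleton [run_pipeline()] expects: input
#' paths, the study's standard thresholds (p <= 0.05, |FC| >= 1.5, 20%
#' extreme-group fraction, 35-day window) and group labels. Any field can
#' be overridden via a YAML/JSON config file or the `...` arguments.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(cow_days = NULL, peptides = NULL, samples = NULL,
              gmt = NULL, ct = NULL, out_dir = "rfiprot_run",
              case = "HEF", control = "LEF",
              p_thresh = 0.05, fc_thresh = 1.5,
              fraction = 0.20, window_days = 35,
              qpcr_candidates = NULL, qpcr_targets = NULL,
              min_term_k = 2)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop_validation("config", paste0("unknown field(s): ",
                                     paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  cfg
}

read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

log_msg <- function(quiet, ...) {
  if (!quiet)
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), "[rfiprot] ", ...)
}

#' Run the feed-efficiency proteomics pipeline end to end
#'
#' Executes the stages in order: RFI scoring and efficiency classification
#' of the herd records; TIC normalization, top-3 rollup and PCA of the
#' peptide table; differential abundance between the case and control
#' groups; hypergeometric enrichment against the GMT annotation sets; and,
#' if a Ct table is supplied, reference-gene selection and delta-delta-Ct
#' relative quantification. All outputs are written under
#' `config$out_dir` and recorded with MD5 content hashes in
#' `manifest.json`; identical configuration and inputs reproduce identical
#' hashes. Any stage failure aborts with the stage name.
#'
#' @param config A list from [pipeline_config()], or a path to a
#'   YAML/JSON file with the same fields.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a run report: per-stage counts, parameter echo and
#'   the file manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts <- list()
  emit <- function(obj, name, writer = write_tsv) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    log_msg(quiet, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(config$cow_days)) {
    scores <- stage("rfi", {
      recs <- read_cow_days(config$cow_days)
      classify_efficiency(score_cows(recs, window_days = config$window_days),
                          fraction = config$fraction)
    })
    emit(scores, "efficiency.tsv", write_efficiency)
    counts$cows <- nrow(scores)
    counts$hef <- sum(scores$class == "HEF")
    counts$lef <- sum(scores$class == "LEF")
  }

  diff <- NULL
  if (!is.null(config$peptides)) {
    if (is.null(config$samples))
      stop_validation("config", "peptides given without a samples map")
    groups <- read_samples(config$samples)
    res <- stage("quantify", {
      pt <- read_peptides(config$peptides)
      norm <- tic_normalize(pt)
      pm <- rollup_top3(norm$table)
      list(norm = norm, pm = pm,
           pca = pca_summary(log_transform(pm)))
    })
    emit(res$norm$report, "normalization_report.tsv")
    emit(res$pm, "proteins.tsv", write_proteins)
    pca_df <- res$pca$scores
    pca_df$var_explained_pc1 <- res$pca$var_explained[1]
    pca_df$var_explained_pc2 <- res$pca$var_explained[2]
    emit(pca_df, "pca.tsv")
    counts$proteins <- nrow(res$pm$abundance)
    counts$samples <- ncol(res$pm$abundance)

    diff <- stage("diffabund",
      diff_abundance(res$pm, groups, case = config$case,
                     control = config$control,
                     p_thresh = config$p_thresh,
                     fc_thresh = config$fc_thresh))
    emit(diff, "differential.tsv")
    emit(diff[diff$status == "tested",
              c("protein_id", "log2fc", "p", "pi_score", "is_dap")],
         "volcano.tsv")
    if (any(diff$is_dap)) {
      hm <- export_heatmap_matrix(diff, log_transform(res$pm))
      emit(data.frame(protein_id = rownames(hm), hm, check.names = FALSE),
           "heatmap.tsv")
    }
    counts$daps <- sum(diff$is_dap)
    counts$daps_up <- sum(diff$is_dap & diff$fc_signed > 0)
    counts$daps_down <- sum(diff$is_dap & diff$fc_signed < 0)

    if (!is.null(config$gmt)) {
      enr <- stage("enrich", {
        ann <- read_gmt(config$gmt)
        hypergeom_enrich(diff$protein_id[diff$is_dap], diff$protein_id,
                         ann, min_k = config$min_term_k)
      })
      emit(enr, "enrichment.tsv")
      emit(category_fractions(diff$protein_id[diff$is_dap],
                              read_gmt(config$gmt)),
           "fractions.tsv")
      counts$terms_tested <- nrow(enr)
      counts$terms_significant <- sum(enr$p_adj < 0.05)
    }
  }

  if (!is.null(config$ct)) {
    qp <- stage("qpcr", {
      ct <- read_ct(config$ct)
      cand <- config$qpcr_candidates %||% unique(ct$gene)
      ref <- select_reference(ct, cand)
      targets <- config$qpcr_targets %||%
        setdiff(unique(ct$gene), cand)
      if (length(targets) == 0)
        stop_validation("qpcr_targets", "no target genes")
      rq <- do.call(rbind, lapply(targets, function(g)
        ddct_rq(ct, g, ref$reference, control_group = config$control)))
      cmp <- do.call(rbind, lapply(targets, function(g) {
        s <- compare_rq(rq[rq$gene == g, ], case_group = config$case,
                        control_group = config$control)
        data.frame(s, stringsAsFactors = FALSE)
      }))
      list(ref = ref, rq = rq, cmp = cmp)
    })
    emit(qp$ref$report, "reference_report.tsv")
    emit(qp$rq, "rq.tsv")
    emit(qp$cmp, "rq_summary.tsv")
    counts$qpcr_targets <- length(unique(qp$rq$gene))
    counts$qpcr_reference <- qp$ref$reference
  } else {
    log_msg(quiet, "stage: qpcr skipped (no Ct table)")
    counts$qpcr_skipped <- TRUE
  }

  manifest <- list(parameters = config[!vapply(config, is.null, TRUE)],
                   counts = counts,
                   files = lapply(stats::setNames(outputs, basename(outputs)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg(quiet, "done: ", length(outputs), " output file(s)")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
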