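# End-to-end pipeline: load -> collapse -> detect -> de -> classify ->
# consensus -> panel, with per-stage outputs and a JSON summary.

#' Assemble a pipeline run configuration
#'
#' @param datasets Named list of dataset descriptions; each element is a
#'   list with `matrix` (TSV path or wide expression tibble), `meta`
#'   (CSV path or metadata tibble) and `family` (`"expansion"` or
#'   `"licensing"`). One or two datasets; consensus and panel stages need
#'   two.
#' @param annotation Optional probe annotation (path or tibble); when
#'   given, matrices are treated as probe-level and collapsed.
#' @param signature Optional signature (path, tibble or character
#'   vector) restricting the classification summary.
#' @param evidence Optional evidence table (path or tibble) enabling the
#'   panel stage.
#' @param alpha,fold Significance thresholds (defaults 0.05, 2).
#' @param epsilon Detection tolerance above the floor (default 0.01).
#' @param min_studies Panel evidence threshold (default 2).
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit progress messages.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(datasets, annotation = NULL, signature = NULL,
                       evidence = NULL, alpha = 0.05, fold = 2,
                       epsilon = 0.01, min_studies = 2L,
                       out_dir = tempfile("msclineage_run_"), verbose = FALSE) {
  if (length(datasets) == 0 || is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    abort("datasets must be a non-empty named list")
  }
  if (alpha <= 0 || fold < 1 || epsilon < 0) abort("thresholds must be positive")
  structure(list(datasets = datasets, annotation = annotation,
                 signature = signature, evidence = evidence,
                 alpha = alpha, fold = fold, epsilon = epsilon,
                 min_studies = as.integer(min_studies),
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

#' @noRd
stage <- function(name, verbose, expr) {
  if (verbose) inform(paste0("[", name, "] ..."))
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' @noRd
load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full signature-stability pipeline
#'
#' For each configured dataset: optional probe collapse, background-floor
#' detection calls, moderated pairwise contrasts, and per-gene
#' reliability classification. With two datasets, reliability calls are
#' intersected into a consensus and, when an evidence table is supplied,
#' refined into an identity panel. Per-stage TSV tables, a JSON summary
#' and a run log are written under `config$out_dir`; any stage error
#' aborts with the failing stage named.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with per-dataset results (`expr`, `calls`,
#'   `de`, `statuses`, `summary`), `consensus`, `panel` and
#'   `summary_json` (the path of the written summary).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  annotation <- stage("load", v, {
    if (is.null(config$annotation)) NULL
    else load_input(config$annotation, read_probe_annotation)
  })
  signature <- stage("load", v, {
    if (is.null(config$signature)) NULL
    else if (is.character(config$signature) && length(config$signature) == 1 &&
             file.exists(config$signature)) read_signature(config$signature)
    else if (is.character(config$signature)) make_signature(config$signature)
    else config$signature
  })
  evidence <- stage("load", v, {
    if (is.null(config$evidence)) NULL else load_input(config$evidence, read_evidence)
  })

  results <- list()
  for (ds in names(config$datasets)) {
    d <- config$datasets[[ds]]
    expr <- stage("load", v, {
      m <- load_input(d$matrix, function(p) {
        read_expression_tsv(p, level = if (is.null(annotation)) "gene" else "probe")
      })
      validate_expr(m)
      m
    })
    meta <- stage("load", v, {
      mt <- load_input(d$meta, read_sample_meta)
      validate_meta(mt, expr)
      mt
    })
    if (!is.null(annotation) && expr_level(expr) == "probe") {
      expr <- stage("collapse", v, collapse_probes(expr, annotation))
      map <- probe_map(expr)
      readr::write_tsv(map, file.path(config$out_dir, paste0(ds, "_probe_map.tsv")),
                       progress = FALSE)
    }
    calls <- stage("detect", v, call_detection(expr, epsilon = config$epsilon))
    de <- stage("de", v, fit_contrasts(expr, meta, family = d$family))
    readr::write_tsv(
      dplyr::mutate(de$results, significant = .data$p_adj < config$alpha &
                      abs(.data$signed_fc) > config$fold),
      file.path(config$out_dir, paste0(ds, "_de.tsv")), progress = FALSE)
    statuses <- stage("classify", v,
      classify_genes(calls, meta, de = de, family = d$family,
                     alpha = config$alpha, fold = config$fold))
    flat <- dplyr::mutate(statuses,
      silenced_conditions = purrr::map_chr(.data$silenced_conditions,
                                           paste, collapse = ";"),
      downregulated_in = purrr::map_chr(.data$downregulated_in,
                                        ~ paste(.x$contrast, collapse = ";")),
      induced_in = purrr::map_chr(.data$induced_in, paste, collapse = ";"))
    readr::write_tsv(flat, file.path(config$out_dir, paste0(ds, "_status.tsv")),
                     progress = FALSE)
    summ <- stage("classify", v,
      summarize_classification(statuses, signature = signature, dataset_id = ds))
    results[[ds]] <- list(expr = expr, calls = calls, de = de,
                          statuses = statuses, summary = summ)
  }

  consensus <- NULL; panel <- NULL
  if (length(results) >= 2) {
    nm <- names(results)[1:2]
    consensus <- stage("consensus", v,
      consensus_reliability(results[[nm[1]]]$statuses, results[[nm[2]]]$statuses))
    if (!is.null(evidence)) {
      panel <- stage("panel", v,
        refine_panel(consensus, evidence, min_studies = config$min_studies))
      readr::write_csv(panel$panel, file.path(config$out_dir, "panel.csv"),
                       progress = FALSE)
      readr::write_csv(panel$excluded, file.path(config$out_dir, "panel_excluded.csv"),
                       progress = FALSE)
    }
  }

  summary_obj <- stage("report", v, {
    per_ds <- lapply(results, function(r) {
      s <- r$summary
      list(n_assessed = s$n_assessed, n_reliable = s$n_reliable,
           n_sporadic = s$n_sporadic, n_never_detected = s$n_never_detected,
           n_condition_silenced = s$n_condition_silenced,
           pct_reliable = s$pct_reliable,
           genes = lapply(s$genes[[1]], sort))
    })
    obj <- list(datasets = per_ds,
                thresholds = list(alpha = signif(config$alpha, 6),
                                  fold = signif(config$fold, 6),
                                  epsilon = signif(config$epsilon, 6),
                                  min_studies = config$min_studies))
    if (!is.null(consensus)) obj$overlap <- lapply(consensus, sort)
    if (!is.null(panel)) {
      obj$panel <- list(genes = panel$panel$gene,
                        n = nrow(panel$panel),
                        excluded = panel$excluded$gene)
    }
    obj
  })
  summary_json <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary_obj, summary_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(
    paste0("msclineage version: ", as.character(utils::packageVersion("msclineage"))),
    paste0("run time (UTC): recorded at run"),
    paste0("datasets: ", paste(names(config$datasets), collapse = ", ")),
    paste0("alpha=", config$alpha, " fold=", config$fold,
           " epsilon=", config$epsilon, " min_studies=", config$min_studies)
  ), file.path(config$out_dir, "run_log.txt"))

  invisible(list(datasets = results, consensus = consensus, panel = panel,
                 summary = summary_obj, summary_json = summary_json))
}
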