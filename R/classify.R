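# Reliability taxonomy: per-gene status from detection calls, with
# downregulation, condition-silencing and induction annotations, plus
# per-dataset and cross-dataset (consensus) summaries.

STATUS_LEVELS <- c("reliable", "sporadic", "never_detected", "condition_silenced")

#' Classify detection reliability of every gene
#'
#' Assigns each gene exactly one status for a dataset:
#' * `never_detected` — detected in zero samples;
#' * `condition_silenced` — undetected in every sample of at least one
#'   complete culture condition while detected elsewhere. For the
#'   licensing design a condition is a (tissue, treatment) group; for the
#'   expansion design it is the tail of the passage series: undetected at
#'   every sample from some passage onward (at least two fully
#'   undetected passages, to distinguish true silencing from sporadic
#'   dropout) after being detected earlier;
#' * `reliable` — detected in every sample;
#' * `sporadic` — any other mixture of detected and undetected calls.
#'
#' Precedence when patterns co-occur: never_detected, then
#' condition_silenced, then sporadic.
#'
#' When a contrast fit is supplied, reliable and sporadic genes
#' significantly downregulated in any contrast (adjusted p and
#' fold-change filter) carry those contrasts in `downregulated_in`;
#' silenced and never-detected genes never do. On licensing
#' data, genes silent at rest but detected after priming carry the
#' responsible conditions in `induced_in`.
#'
#' @param calls Long detection-call tibble from [call_detection()].
#' @param meta Sample metadata tibble covering exactly the samples of
#'   `calls`.
#' @param de Optional `"mscl_de"` fit (or its [tidy()] tibble) for the
#'   same dataset.
#' @param family `"expansion"` or `"licensing"`; inferred from the
#'   metadata when omitted.
#' @param alpha,fold Thresholds passed to [significant_genes()] for the
#'   downregulation annotation (defaults 0.05 and 2).
#' @param min_silenced_passages Minimum number of consecutive fully
#'   undetected passages closing the series for passage silencing
#'   (default 2).
#' @return A tibble with columns `gene`, `status`, and list-columns
#'   `silenced_conditions`, `downregulated_in` (tibbles with `contrast`,
#'   `p_adj`, `signed_fc`) and `induced_in`.
#' @export
classify_genes <- function(calls, meta, de = NULL, family = NULL,
                           alpha = 0.05, fold = 2,
                           min_silenced_passages = 2L) {
  validate_meta(meta)
  samp <- unique(calls$sample_id)
  if (!setequal(samp, meta$sample_id)) {
    abort("detection calls and metadata cover different sample sets")
  }
  if (is.null(family)) {
    family <- if ("passage" %in% names(meta) && any(!is.na(meta$passage)))
      "expansion" else "licensing"
  }
  cm <- dplyr::left_join(calls, meta, by = "sample_id")

  overall <- cm |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_det = sum(.data$detected), n_tot = dplyr::n(), .groups = "drop")

  if (family == "licensing") {
    grp <- cm |>
      dplyr::group_by(.data$gene, .data$tissue, .data$treatment) |>
      dplyr::summarise(all_undet = !any(.data$detected), .groups = "drop")
    sil <- grp |>
      dplyr::filter(.data$all_undet) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(
        silenced_conditions = list(paste0(.data$tissue, ":", .data$treatment)),
        .groups = "drop")
  } else {
    by_pass <- cm |>
      dplyr::group_by(.data$gene, .data$passage) |>
      dplyr::summarise(all_undet = !any(.data$detected), .groups = "drop") |>
      dplyr::arrange(.data$gene, .data$passage)
    sil <- by_pass |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(silenced_conditions = {
        undet <- .data$all_undet
        pass <- .data$passage
        # longest fully-undetected suffix of the passage series
        run <- rev(cumprod(rev(undet))) == 1
        if (sum(run) >= min_silenced_passages && any(!run)) {
          list(paste0("P>=", min(pass[run])))
        } else list(character(0))
      }, .groups = "drop") |>
      dplyr::filter(lengths(.data$silenced_conditions) > 0)
  }

  out <- overall |>
    dplyr::left_join(sil, by = "gene") |>
    dplyr::mutate(
      silenced_conditions = purrr::map(.data$silenced_conditions, ~ .x %||% character(0)),
      status = dplyr::case_when(
        .data$n_det == 0 ~ "never_detected",
        lengths(.data$silenced_conditions) > 0 & .data$n_det < .data$n_tot ~ "condition_silenced",
        .data$n_det == .data$n_tot ~ "reliable",
        TRUE ~ "sporadic"
      ),
      silenced_conditions = purrr::map2(.data$silenced_conditions, .data$status,
        ~ if (.y == "condition_silenced") .x else character(0))
    )

  down_tbl <- tibble::tibble(gene = character(), contrast = character(),
                             p_adj = numeric(), signed_fc = numeric())
  if (!is.null(de)) {
    res <- if (inherits(de, "mscl_de")) de$results else tibble::as_tibble(de)
    down_tbl <- res |>
      dplyr::filter(.data$p_adj < alpha, abs(.data$signed_fc) >= fold,
                    .data$signed_fc < 0) |>
      dplyr::select("gene", "contrast", "p_adj", "signed_fc")
  }
  down_nested <- down_tbl |>
    tidyr::nest(downregulated_in = c("contrast", "p_adj", "signed_fc"))
  out <- out |>
    dplyr::left_join(down_nested, by = "gene") |>
    dplyr::mutate(downregulated_in = purrr::map2(
      .data$downregulated_in, .data$status,
      function(d, s) {
        # only genes that stay measurable carry a downregulation record;
        # silenced and never-detected genes are described by their status
        if (!s %in% c("reliable", "sporadic") || is.null(d)) {
          tibble::tibble(contrast = character(), p_adj = numeric(), signed_fc = numeric())
        } else d
      }))

  if (family == "licensing") {
    ind <- annotate_induction(calls, meta) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(induced_in = list(paste0(.data$tissue, ":", .data$treatment)),
                       .groups = "drop")
    out <- out |>
      dplyr::left_join(ind, by = "gene") |>
      dplyr::mutate(induced_in = purrr::map(.data$induced_in, ~ .x %||% character(0)))
  } else {
    out$induced_in <- rep(list(character(0)), nrow(out))
  }
  dplyr::select(out, "gene", "status", "silenced_conditions",
                "downregulated_in", "induced_in") |>
    dplyr::arrange(.data$gene)
}

#' Flag treatment-induced expression from a silent resting baseline
#'
#' On licensing data, a gene undetected in every resting sample of a
#' tissue but detected in at least one cytokine-primed sample of that
#' tissue is flagged as induced by the responsible treatment(s).
#'
#' @param calls Long detection-call tibble.
#' @param meta Licensing sample metadata.
#' @return A tidy tibble with columns `gene`, `tissue`, `treatment`, one
#'   row per induced (gene, condition).
#' @export
annotate_induction <- function(calls, meta) {
  validate_meta(meta)
  if (!"treatment" %in% names(meta) || all(is.na(meta$treatment))) {
    abort("induction annotation needs licensing metadata with a 'treatment' column")
  }
  cm <- dplyr::left_join(calls, meta, by = "sample_id")
  grp <- cm |>
    dplyr::group_by(.data$gene, .data$tissue, .data$treatment) |>
    dplyr::summarise(any_det = any(.data$detected), .groups = "drop")
  resting <- grp |>
    dplyr::filter(.data$treatment == "resting") |>
    dplyr::select("gene", "tissue", rest_det = "any_det")
  grp |>
    dplyr::filter(.data$treatment != "resting") |>
    dplyr::inner_join(resting, by = c("gene", "tissue")) |>
    dplyr::filter(!.data$rest_det, .data$any_det) |>
    dplyr::select("gene", "tissue", "treatment") |>
    dplyr::arrange(.data$gene, .data$tissue, .data$treatment)
}

#' Summarize a classification against a signature
#'
#' Counts per status, integer percent reliable (half-up rounding), and
#' per-status gene lists for the signature genes assessed in one
#' dataset. Signature genes that are neither classified nor listed as
#' absent from the platform are an error.
#'
#' @param statuses Tibble from [classify_genes()].
#' @param signature Signature tibble or character vector; defaults to all
#'   classified genes.
#' @param not_on_platform Genes of the signature absent from the array.
#' @param dataset_id Label for the dataset.
#' @return One-row tibble: `dataset_id`, `n_assessed`, counts and percent
#'   per status, and a `genes` list-column mapping status to sorted gene
#'   lists.
#' @export
summarize_classification <- function(statuses, signature = NULL,
                                     not_on_platform = character(),
                                     dataset_id = "dataset") {
  sig <- if (is.null(signature)) statuses$gene
         else if (is.data.frame(signature)) signature$gene else signature
  on_platform <- setdiff(sig, not_on_platform)
  missing <- setdiff(on_platform, statuses$gene)
  if (length(missing) > 0) {
    abort(paste0("unclassified on-platform gene(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  st <- statuses[statuses$gene %in% on_platform, , drop = FALSE]
  counts <- vapply(STATUS_LEVELS, function(s) sum(st$status == s), integer(1))
  n <- nrow(st)
  tibble::tibble(
    dataset_id = dataset_id,
    n_assessed = n,
    n_reliable = counts[["reliable"]],
    n_sporadic = counts[["sporadic"]],
    n_never_detected = counts[["never_detected"]],
    n_condition_silenced = counts[["condition_silenced"]],
    pct_reliable = as.integer(round_half_up(100 * counts[["reliable"]] / n)),
    genes = list(lapply(stats::setNames(STATUS_LEVELS, STATUS_LEVELS),
                        function(s) sort(st$gene[st$status == s])))
  )
}

#' Cross-dataset consensus of reliability calls
#'
#' For genes assessed in both datasets: consensus-reliable genes are
#' reliable in both; consensus-unreliable genes are non-reliable in
#' either. The genes non-reliable in both datasets are also reported, as
#' the sternest subset.
#'
#' @param statuses_a,statuses_b Tibbles from [classify_genes()] for the
#'   two datasets.
#' @return A list with sorted character vectors `assessed_both`,
#'   `consensus_reliable`, `consensus_unreliable`, `unreliable_in_both`.
#' @export
consensus_reliability <- function(statuses_a, statuses_b) {
  both <- intersect(statuses_a$gene, statuses_b$gene)
  rel_a <- statuses_a$gene[statuses_a$status == "reliable"]
  rel_b <- statuses_b$gene[statuses_b$status == "reliable"]
  cons_rel <- intersect(intersect(rel_a, rel_b), both)
  list(
    assessed_both = sort(both),
    consensus_reliable = sort(cons_rel),
    consensus_unreliable = sort(setdiff(both, cons_rel)),
    unreliable_in_both = sort(intersect(setdiff(both, rel_a), setdiff(both, rel_b)))
  )
}
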