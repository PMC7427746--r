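# Probe-to-gene collapse and detection-above-background calling.

#' Collapse probe-level rows to one row per gene
#'
#' For transcripts measured by multiple probe sets, keeps the probe set
#' with the highest average log2 intensity across all samples; ties are
#' broken by the lexicographically smallest probe id so the result does
#' not depend on input row order. The chosen row is carried over
#' unchanged (bit-identical values), only renamed to the gene symbol.
#' Probes without an annotated symbol are excluded and reported in the
#' mapping.
#'
#' @param expr Probe-level wide expression tibble.
#' @param annotation Tibble from [read_probe_annotation()] (columns
#'   `probe_id`, `gene_symbol`, optionally `annotated`).
#' @return A gene-level wide expression tibble (first column `gene`);
#'   the gene-to-probe mapping is attached as the `"probe_map"` attribute
#'   (a tibble with `gene`, `probe_id`, `mean_intensity`, `n_probes`)
#'   and retrievable with [probe_map()].
#' @export
collapse_probes <- function(expr, annotation) {
  validate_expr(expr, "probe-level matrix")
  if (expr_level(expr) != "probe") {
    abort("collapse_probes() expects a probe-level matrix (expr_level attribute 'probe')")
  }
  ann <- tibble::as_tibble(annotation)
  if ("annotated" %in% names(ann)) ann <- dplyr::filter(ann, .data$annotated)
  ann <- dplyr::filter(ann, !is.na(.data$gene_symbol), nzchar(.data$gene_symbol))
  m <- expr_to_matrix(expr)
  ann <- dplyr::filter(ann, .data$probe_id %in% rownames(m))
  if (nrow(ann) == 0) abort("no annotated probes present in the matrix")
  means <- rowMeans(m)
  map <- ann |>
    dplyr::mutate(mean_intensity = means[.data$probe_id]) |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      probe_id = {
        best <- .data$probe_id[.data$mean_intensity == max(.data$mean_intensity)]
        sort(best)[1]
      },
      mean_intensity = max(.data$mean_intensity),
      .groups = "drop"
    ) |>
    dplyr::rename(gene = "gene_symbol") |>
    dplyr::arrange(.data$gene)
  out_m <- m[map$probe_id, , drop = FALSE]
  rownames(out_m) <- map$gene
  out <- matrix_to_expr(out_m, id_col = "gene", level = "gene")
  attr(out, "probe_map") <- map
  out
}

#' Retrieve the gene-to-probe mapping from a collapsed matrix
#'
#' @param expr Gene-level tibble returned by [collapse_probes()].
#' @return The mapping tibble, or `NULL` when absent.
#' @export
probe_map <- function(expr) attr(expr, "probe_map")

#' Estimate the array-set background floor
#'
#' GCRMA-normalized intensities are censored at a dataset-wide minimum;
#' the floor is therefore the global minimum of the matrix, estimated per
#' dataset rather than per sample.
#'
#' @param expr Wide expression tibble.
#' @return The floor value (log2 scale).
#' @export
estimate_floor <- function(expr) {
  validate_expr(expr)
  min(expr_to_matrix(expr))
}

#' Call detection above background
#'
#' A gene is called detected in a sample when its value strictly exceeds
#' the detection threshold: `absolute_threshold` when supplied, otherwise
#' `floor_value + epsilon`. Values at the censoring floor (within
#' `epsilon`) are undetected.
#'
#' @param expr Gene-level wide expression tibble.
#' @param floor_value Background floor; defaults to [estimate_floor()].
#' @param epsilon Non-negative tolerance above the floor (log2 units)
#'   below which a value still counts as background. Default 0.01.
#' @param absolute_threshold Optional absolute intensity threshold that
#'   overrides the floor-plus-epsilon rule (for normalizations without a
#'   hard floor). A threshold below the floor triggers a warning, not an
#'   error.
#' @return A long tibble with columns `gene`, `sample_id`, `detected`
#'   (logical); attributes `floor_value`, `epsilon`, `threshold`.
#' @export
call_detection <- function(expr, floor_value = NULL, epsilon = 0.01,
                           absolute_threshold = NULL) {
  validate_expr(expr)
  if (epsilon < 0) abort("epsilon must be >= 0")
  m <- expr_to_matrix(expr)
  if (is.null(floor_value)) floor_value <- min(m)
  if (!is.null(absolute_threshold)) {
    if (absolute_threshold < floor_value) {
      warn("absolute_threshold is below the estimated floor; all values will be detected")
    }
    threshold <- absolute_threshold
  } else {
    threshold <- floor_value + epsilon
  }
  det <- m > threshold
  out <- tibble::tibble(
    gene = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    detected = as.vector(det)
  )
  attr(out, "floor_value") <- floor_value
  attr(out, "epsilon") <- epsilon
  attr(out, "threshold") <- threshold
  out
}
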