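# Internal helpers shared across modules.

#' Round half away from zero to integer percent
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Convert a wide expression tibble to a numeric matrix
#'
#' The first column holds feature identifiers; all remaining columns are
#' numeric sample columns.
#' @noRd
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  ids <- as.character(expr[[1]])
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert a numeric matrix back to a wide expression tibble
#' @noRd
matrix_to_expr <- function(m, id_col = "feature_id", level = NULL) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
  if (!is.null(level)) attr(out, "expr_level") <- level
  out
}

#' Validate a wide expression tibble
#'
#' Enforces unique feature ids, unique sample ids, and finite non-missing
#' numeric values throughout.
#' @noRd
validate_expr <- function(expr, what = "expression matrix") {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    abort(paste0(what, " must be a data frame with an id column and at least one sample column"))
  }
  ids <- as.character(expr[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicated feature id(s) in ", what, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  samp <- names(expr)[-1]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s) > 0) {
    abort(paste0("duplicated sample id(s) in ", what, ": ",
                 paste(head(dup_s, 5), collapse = ", ")))
  }
  for (j in seq_along(samp)) {
    col <- expr[[j + 1]]
    if (!is.numeric(col)) {
      abort(paste0("non-numeric values in column '", samp[j], "' of ", what))
    }
    bad <- which(!is.finite(col))
    if (length(bad) > 0) {
      abort(paste0("missing or non-finite value in ", what, " at row '",
                   ids[bad[1]], "', column '", samp[j], "'"))
    }
  }
  invisible(expr)
}

#' Level attribute accessor ("probe" or "gene")
#' @noRd
expr_level <- function(expr) attr(expr, "expr_level") %||% "gene"

#' Validate sample metadata against an expression tibble
#' @noRd
validate_meta <- function(meta, expr = NULL) {
  req <- "sample_id"
  if (!is.data.frame(meta) || !all(req %in% names(meta))) {
    abort("sample metadata must contain a 'sample_id' column")
  }
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated sample_id(s) in metadata: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(expr)) {
    samp <- names(expr)[-1]
    missing <- setdiff(samp, meta$sample_id)
    if (length(missing) > 0) {
      abort(paste0("samples absent from metadata: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  invisible(meta)
}

#' Derive independent sub-seeds from one master seed
#'
#' Each generator component (baseline, donor, effects, noise, dropout)
#' consumes its own stream so that enlarging one component does not
#' perturb draws in another. Sub-seeds stay below 2^31.
#' @noRd
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 99991L * seq_len(n)) %% .Machine$integer.max
}
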