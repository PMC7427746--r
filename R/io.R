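# Readers and writers for expression matrices, sample metadata, probe
# annotation, signature lists and prior-evidence tables. All readers return
# tibbles; expression tibbles are wide (feature id column + one numeric
# column per sample) with the measurement level kept in the "expr_level"
# attribute.

#' Read a tab-separated expression matrix
#'
#' Reads a plain TSV with feature identifiers (probe set ids or gene
#' symbols) in the first column and one named sample column per array.
#' Values are normalized log2 intensities. Duplicate feature or sample
#' ids, missing cells and non-numeric cells are load errors, never
#' silently repaired.
#'
#' @param path Path to a TSV file. First row is the header of sample ids.
#' @param level Measurement level of the rows, `"probe"` or `"gene"`.
#' @return A tibble with the first column `feature_id` and one numeric
#'   column per sample; the `expr_level` attribute records `level`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "g1\t5.1\t6.2", "g2\t7.0\t7.3"), tf)
#' read_expression_tsv(tf, level = "gene")
read_expression_tsv <- function(path, level = c("gene", "probe")) {
  level <- match.arg(level)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) abort("expression TSV needs an id column and at least one sample column")
  ids <- raw[[1]]
  vals <- raw[, -1, drop = FALSE]
  out <- tibble::tibble(feature_id = as.character(ids))
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col))
    if (length(bad) > 0) {
      abort(paste0("missing or non-numeric value at row '", ids[bad[1]],
                   "', column '", names(vals)[j], "'"))
    }
    out[[names(vals)[j]]] <- col
  }
  attr(out, "expr_level") <- level
  validate_expr(out)
  out
}

#' Write an expression tibble as TSV
#'
#' @param expr Wide expression tibble as returned by [read_expression_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expr(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read a GEO Series Matrix text file
#'
#' Parses the plain-text Series Matrix dialect used by GEO deposits: the
#' expression table lives between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`, identifiers may or may not be quoted, and
#' line endings may be CRLF or LF. Sample annotation lines
#' (`!Sample_geo_accession`, `!Sample_title`,
#' `!Sample_characteristics_ch1`) are scanned for passage numbers (e.g.
#' "P3"), tissue source (UC/BM) and licensing treatment keywords, giving a
#' partial metadata tibble; fields that cannot be recovered are `NA` and
#' must be supplied by the user for real analyses.
#'
#' @param path Path to a series matrix text file.
#' @param level Measurement level of table rows (GEO deposits are
#'   probe-level; default `"probe"`).
#' @return A list with elements `expr` (wide expression tibble) and
#'   `meta` (partial sample metadata tibble with columns `sample_id`,
#'   `title`, `donor`, `tissue`, `passage`, `treatment`).
#' @export
read_series_matrix <- function(path, level = c("probe", "gene")) {
  level <- match.arg(level)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  begin <- grep("^!series_matrix_table_begin\\s*$", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end\\s*$", lines, ignore.case = TRUE)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    abort("no complete !series_matrix_table_begin/!series_matrix_table_end block found")
  }
  tab <- lines[(begin + 1):(end - 1)]
  cells <- strsplit(tab, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1) {
    abort(paste0("ragged series matrix table: rows have ", paste(unique(widths), collapse = "/"),
                 " fields"))
  }
  unq <- function(x) gsub('^"|"$', "", x)
  header <- unq(cells[[1]])
  sample_ids <- header[-1]
  body <- cells[-1]
  ids <- vapply(body, function(r) unq(r[1]), character(1))
  vals <- vapply(body, function(r) suppressWarnings(as.numeric(unq(r[-1]))),
                 numeric(length(sample_ids)))
  m <- if (length(sample_ids) == 1) matrix(vals, ncol = 1) else t(vals)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("missing or non-numeric value at row '", ids[bad[1, 1]],
                 "', column '", sample_ids[bad[1, 2]], "'"))
  }
  dimnames(m) <- list(ids, sample_ids)
  expr <- matrix_to_expr(m, level = level)
  validate_expr(expr)

  meta_line <- function(tag) {
    ln <- grep(paste0("^!", tag, "\\b"), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    unq(strsplit(ln[1], "\t", fixed = TRUE)[[1]][-1])
  }
  acc <- meta_line("Sample_geo_accession")
  title <- meta_line("Sample_title")
  chars <- meta_line("Sample_characteristics_ch1")
  n <- length(sample_ids)
  pad <- function(x) if (is.null(x)) rep(NA_character_, n) else c(x, rep(NA_character_, n))[seq_len(n)]
  acc <- pad(acc); title <- pad(title); chars <- pad(chars)
  text <- paste(ifelse(is.na(title), "", title), ifelse(is.na(chars), "", chars))
  passage <- ifelse(grepl("\\bP([0-9]+)\\b", text),
                    as.integer(sub(".*\\bP([0-9]+)\\b.*", "\\1", text)), NA_integer_)
  treatment <- rep(NA_character_, n)
  treatment[grepl("TNF", text, ignore.case = TRUE)] <- "TNFa"
  treatment[grepl("IFN", text, ignore.case = TRUE)] <- "IFNg"
  treatment[grepl("IL-?1", text, ignore.case = TRUE)] <- "IL1b"
  treatment[grepl("rest|naive|naïve|untreated", text, ignore.case = TRUE)] <- "resting"
  tissue <- rep(NA_character_, n)
  tissue[grepl("\\bUC\\b|umbilical", text, ignore.case = TRUE)] <- "UC"
  tissue[grepl("\\bBM\\b|bone marrow", text, ignore.case = TRUE)] <- "BM"
  donor <- ifelse(grepl("donor[ _]?([A-Za-z0-9]+)", text, ignore.case = TRUE),
                  sub(".*donor[ _]?([A-Za-z0-9]+).*", "\\1", text, ignore.case = TRUE),
                  NA_character_)
  meta <- tibble::tibble(
    sample_id = sample_ids,
    title = dplyr::na_if(title, ""),
    donor = donor, tissue = tissue,
    passage = passage, treatment = treatment
  )
  list(expr = expr, meta = meta)
}

#' Write a minimal GEO-style Series Matrix file
#'
#' Emits `!Sample_geo_accession` and `!Sample_title` annotation lines
#' followed by a quoted expression table inside the standard
#' begin/end markers, the dialect accepted by [read_series_matrix()].
#' Titles are assembled from the metadata (donor, tissue, passage or
#' treatment) so that the parser can round-trip the design.
#'
#' @param expr Wide expression tibble.
#' @param meta Sample metadata tibble with `sample_id` and any of `donor`,
#'   `tissue`, `passage`, `treatment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(expr, meta, path) {
  validate_expr(expr)
  validate_meta(meta, expr)
  samp <- names(expr)[-1]
  meta <- meta[match(samp, meta$sample_id), , drop = FALSE]
  fld <- function(col) if (col %in% names(meta)) meta[[col]] else rep(NA, nrow(meta))
  title <- trimws(paste(
    ifelse(is.na(fld("tissue")), "", as.character(fld("tissue"))),
    ifelse(is.na(fld("donor")), "", paste0("donor ", fld("donor"))),
    ifelse(is.na(fld("passage")), "", paste0("P", fld("passage"))),
    ifelse(is.na(fld("treatment")), "", as.character(fld("treatment")))
  ))
  q <- function(x) paste0('"', x, '"')
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("!Sample_title", q(title)), collapse = "\t"), con)
  writeLines(paste(c("!Sample_geo_accession", q(samp)), collapse = "\t"), con)
  writeLines("!series_matrix_table_begin", con)
  writeLines(paste(c(q("ID_REF"), q(samp)), collapse = "\t"), con)
  m <- expr_to_matrix(expr)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(q(rownames(m)[i]), format(m[i, ], trim = TRUE)), collapse = "\t"), con)
  }
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Read per-sample metadata
#'
#' CSV with header `sample_id,donor,tissue,passage,treatment`. Empty
#' fields become `NA` ("absent"), never empty strings: the expansion
#' design carries passages but no treatment, the licensing design carries
#' treatments but no passage.
#'
#' @param path Path to the metadata CSV.
#' @return A tibble with columns `sample_id`, `donor`, `tissue`
#'   (`"UC"`/`"BM"`), `passage` (integer) and `treatment` (one of
#'   `"resting"`, `"TNFa"`, `"IFNg"`, `"IL1b"`).
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  meta <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), donor = readr::col_character(),
    tissue = readr::col_character(), passage = readr::col_integer(),
    treatment = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  meta <- dplyr::mutate(meta, dplyr::across(dplyr::where(is.character),
                                            ~ dplyr::na_if(trimws(.x), "")))
  bad_t <- setdiff(stats::na.omit(unique(meta$tissue)), c("UC", "BM"))
  if (length(bad_t) > 0) abort(paste0("unknown tissue value(s): ", paste(bad_t, collapse = ", ")))
  bad_tr <- setdiff(stats::na.omit(unique(meta$treatment)),
                    c("resting", "TNFa", "IFNg", "IL1b"))
  if (length(bad_tr) > 0) abort(paste0("unknown treatment value(s): ", paste(bad_tr, collapse = ", ")))
  validate_meta(meta)
  meta
}

#' Read probe-to-gene annotation
#'
#' Two-column TSV (`probe_id`, `gene_symbol`). Symbols are upper-cased
#' and alias-resolved; probes with an empty symbol are retained in the
#' returned tibble but flagged `annotated = FALSE` and excluded from
#' probe collapse.
#'
#' @param path Path to the annotation TSV.
#' @param alias_map Two-column data frame (`alias`, `symbol`) applied
#'   after upper-casing; defaults to [default_alias_map()].
#' @return A tibble with columns `probe_id`, `gene_symbol`, `annotated`.
#' @export
read_probe_annotation <- function(path, alias_map = default_alias_map()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(ann) < 2) abort("annotation needs columns probe_id and gene_symbol")
  names(ann)[1:2] <- c("probe_id", "gene_symbol")
  dup <- unique(ann$probe_id[duplicated(ann$probe_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated probe id(s) in annotation: ", paste(head(dup, 5), collapse = ", ")))
  }
  sym <- resolve_aliases(ann$gene_symbol, alias_map, keep_na = TRUE)
  tibble::tibble(probe_id = ann$probe_id, gene_symbol = sym,
                 annotated = !is.na(sym) & nzchar(sym))
}

#' Default gene-symbol alias map
#'
#' Ships with the single alias the candidate signature lists mix in
#' (KIAA1199, now CEMIP). Users supply a larger two-column map for other
#' platforms.
#'
#' @return A tibble with columns `alias` and `symbol`.
#' @export
default_alias_map <- function() {
  tibble::tibble(alias = "KIAA1199", symbol = "CEMIP")
}

#' Upper-case and alias-resolve gene symbols
#'
#' @param genes Character vector of symbols.
#' @param alias_map Two-column data frame (`alias`, `symbol`) or `NULL`.
#' @param keep_na Keep missing/empty entries as `NA` instead of erroring.
#' @return Character vector of canonical upper-case symbols.
#' @export
resolve_aliases <- function(genes, alias_map = default_alias_map(), keep_na = FALSE) {
  g <- toupper(trimws(as.character(genes)))
  g[!nzchar(g)] <- NA_character_
  if (!keep_na && anyNA(g)) abort("empty gene symbol")
  if (!is.null(alias_map) && nrow(alias_map) > 0) {
    al <- toupper(trimws(alias_map[[1]]))
    to <- toupper(trimws(alias_map[[2]]))
    hit <- match(g, al)
    g[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  g
}

#' Read a signature gene list
#'
#' Accepts one symbol per line, or a CSV with a `gene`/`gene_symbol`
#' column. Symbols are upper-cased, alias-resolved and de-duplicated
#' preserving first occurrence.
#'
#' @param path Path to the list.
#' @param alias_map Alias map passed to [resolve_aliases()].
#' @param name Signature name; defaults to the file name.
#' @return A tibble with one column `gene`; the signature name is kept in
#'   the `"signature_name"` attribute.
#' @export
read_signature <- function(path, alias_map = default_alias_map(), name = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty signature file")
  if (grepl(",", lines[1])) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
    col <- intersect(c("gene", "gene_symbol", "symbol"), names(df))
    if (length(col) == 0) abort("signature CSV needs a gene/gene_symbol column")
    genes <- df[[col[1]]]
  } else {
    genes <- lines
  }
  make_signature(genes, name = name %||% basename(path), alias_map = alias_map)
}

#' Build a signature from a character vector
#'
#' @param genes Character vector of symbols.
#' @param name Signature name.
#' @param alias_map Alias map passed to [resolve_aliases()].
#' @return A tibble with one column `gene` (attribute `signature_name`).
#' @export
make_signature <- function(genes, name = "signature", alias_map = default_alias_map()) {
  g <- resolve_aliases(genes, alias_map)
  g <- g[!duplicated(g)]
  if (length(g) == 0) abort("empty signature")
  out <- tibble::tibble(gene = g)
  attr(out, "signature_name") <- name
  out
}

#' Read a prior-evidence table
#'
#' CSV with header `gene_symbol,n_studies,fibroblast_discriminant` listing,
#' for each candidate identity gene, how many independent studies
#' previously validated it and whether it discriminates MSCs from
#' fibroblasts.
#'
#' @param path Path to the CSV.
#' @param alias_map Alias map passed to [resolve_aliases()].
#' @return A tibble with columns `gene_symbol` (unique), `n_studies`
#'   (integer >= 0) and `fibroblast_discriminant` (logical).
#' @export
read_evidence <- function(path, alias_map = default_alias_map()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ev <- readr::read_csv(path, col_types = readr::cols(
    gene_symbol = readr::col_character(),
    n_studies = readr::col_integer(),
    fibroblast_discriminant = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE)
  ev$gene_symbol <- resolve_aliases(ev$gene_symbol, alias_map)
  if (anyDuplicated(ev$gene_symbol)) abort("duplicated gene_symbol in evidence table")
  if (any(ev$n_studies < 0, na.rm = TRUE)) abort("n_studies must be >= 0")
  ev
}
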