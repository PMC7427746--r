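# Signature platform-coverage accounting and refined-panel derivation.

#' Platform coverage of a signature
#'
#' Splits a signature into the genes measurable on the array and those
#' not represented, with the integer percent assessed (half-up
#' rounding).
#'
#' @param signature Signature tibble (from [read_signature()] /
#'   [make_signature()]) or character vector of symbols.
#' @param platform_genes Character vector of gene symbols measurable on
#'   the platform (after alias resolution), e.g. the `gene` column of a
#'   collapsed matrix.
#' @return One-row tibble: `signature`, `n_total`, `n_on_platform`,
#'   `n_not_represented`, `pct_assessed`, and a `missing` list-column
#'   with the absent genes.
#' @export
platform_coverage <- function(signature, platform_genes) {
  name <- if (is.data.frame(signature)) {
    attr(signature, "signature_name") %||% "signature"
  } else "signature"
  sig <- if (is.data.frame(signature)) signature$gene else signature
  if (length(platform_genes) == 0) abort("empty platform gene set")
  on <- intersect(sig, platform_genes)
  off <- setdiff(sig, platform_genes)
  tibble::tibble(
    signature = name,
    n_total = length(sig),
    n_on_platform = length(on),
    n_not_represented = length(off),
    pct_assessed = as.integer(round_half_up(100 * length(on) / length(sig))),
    missing = list(sort(off))
  )
}

#' Derive a refined identity panel from consensus reliability and prior
#' evidence
#'
#' Candidates are the evidence genes independently validated in at least
#' `min_studies` prior studies; a candidate is admitted only when it is
#' consensus-reliable, i.e. classified reliable in both datasets. Every
#' rejected candidate is listed with its reason. Admitted genes are
#' ordered with the fibroblast-discriminating markers first, then
#' alphabetically.
#'
#' @param consensus List from [consensus_reliability()], or a character
#'   vector of consensus-reliable genes.
#' @param evidence Evidence tibble (see [read_evidence()]).
#' @param min_studies Minimum number of supporting studies (default 2).
#' @return A list with `panel` (tibble: `gene`, `n_studies`,
#'   `fibroblast_discriminant`) and `excluded` (tibble: `gene`,
#'   `reason`).
#' @export
refine_panel <- function(consensus, evidence, min_studies = 2L) {
  if (min_studies < 0) abort("min_studies must be >= 0")
  reliable <- if (is.list(consensus) && !is.data.frame(consensus)) {
    consensus$consensus_reliable
  } else if (is.data.frame(consensus)) consensus$gene else consensus
  ev <- tibble::as_tibble(evidence) |> dplyr::arrange(.data$gene_symbol)
  cand <- ev[ev$n_studies >= min_studies, , drop = FALSE]
  admitted <- cand[cand$gene_symbol %in% reliable, , drop = FALSE]
  panel <- tibble::tibble(
    gene = admitted$gene_symbol,
    n_studies = admitted$n_studies,
    fibroblast_discriminant = admitted$fibroblast_discriminant
  ) |>
    dplyr::arrange(dplyr::desc(.data$fibroblast_discriminant), .data$gene)
  excluded <- dplyr::bind_rows(
    tibble::tibble(gene = ev$gene_symbol[ev$n_studies < min_studies],
                   reason = "insufficient_prior_studies"),
    tibble::tibble(gene = setdiff(cand$gene_symbol, reliable),
                   reason = "not_consensus_reliable")
  ) |> dplyr::arrange(.data$gene)
  list(panel = panel, excluded = excluded)
}
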