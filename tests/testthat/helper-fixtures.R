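# Shared in-code fixtures.

# Wide expression tibble from a named matrix.
make_expr <- function(m, id_col = "gene", level = "gene") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
  attr(out, "expr_level") <- level
  out
}

# Long detection-call tibble from a logical matrix (genes x samples).
make_calls <- function(det) {
  tibble::tibble(
    gene = rep(rownames(det), times = ncol(det)),
    sample_id = rep(colnames(det), each = nrow(det)),
    detected = as.vector(det)
  )
}

# Minimal licensing metadata: n donors per tissue x (resting + cytokines).
make_licensing_meta <- function(n_per_tissue = 3,
                                treatments = c("resting", "TNFa", "IFNg", "IL1b")) {
  tidyr::expand_grid(tissue = c("UC", "BM"), idx = seq_len(n_per_tissue),
                     treatment = treatments) |>
    dplyr::mutate(donor = paste0(tissue, idx),
                  sample_id = paste0(donor, "_", treatment),
                  passage = NA_integer_) |>
    dplyr::select(sample_id, donor, tissue, passage, treatment)
}

# Minimal expansion metadata: donors x passages, one array each.
make_expansion_meta <- function(donors = paste0("D", 1:4), passages = 2:12) {
  tidyr::expand_grid(donor = donors, passage = as.integer(passages)) |>
    dplyr::mutate(sample_id = paste0(donor, "_P", passage), tissue = "UC",
                  treatment = NA_character_) |>
    dplyr::select(sample_id, donor, tissue, passage, treatment)
}

# Independent step-up adjustment by literal enumeration of the minima.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m / j * ps[j], numeric(1))
    adj_sorted[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}
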