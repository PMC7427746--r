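# Synthetic floor-censored expression datasets with known per-gene truth.
#
# The generator emulates the two study designs end to end: a serial
# expansion series (4 umbilical-cord MSC donor populations arrayed at
# every passage from P2 through pre-senescence, some donors exiting
# culture early) and a licensing matrix (3 UC and 3 BM populations at
# rest and after priming with TNF-alpha, IFN-gamma or IL-1beta). Each
# gene belongs to one truth class: reliable, reliable but downregulated,
# never detected, sporadically dropped out, or silenced in one complete
# condition. Values are baseline + donor effect + class effect + noise,
# hard-censored at the background floor.

TRUTH_CLASSES <- c("reliable", "reliable_downregulated", "never_detected",
                   "sporadic", "condition_silenced")

#' Simulation configuration
#'
#' Defaults describe a realistic GCRMA-like dataset: log2 baselines
#' uniform on 6-12, a hard background floor at 2.0, donor random effects
#' of 0.3 log2 units, residual array noise of 0.25, implanted
#' downregulation of -1.8 log2 (about 3.5-fold), and 5% sporadic dropout.
#'
#' @param n_genes Number of genes.
#' @param class_fractions Named fractions over
#'   `reliable`, `reliable_downregulated`, `never_detected`, `sporadic`,
#'   `condition_silenced`; must sum to 1.
#' @param baseline_range Log2 baseline expression range (uniform).
#' @param donor_sd SD of per-donor, per-gene random effects (log2).
#' @param noise_sd SD of residual array noise (log2).
#' @param floor Hard detection floor (log2); must lie below the baseline
#'   range.
#' @param down_logfc Implanted log2 fold change for downregulated genes
#'   (at late passages, or under the assigned cytokine).
#' @param dropout_prob Per-sample dropout probability for sporadic genes
#'   (each sporadic gene is guaranteed at least one and at most n-1
#'   dropouts, so its truth class is realizable).
#' @param down_shape `"ramp"` (linear decline from `ramp_start` to the
#'   final passage) or `"step"` (full effect from `ramp_start` on);
#'   licensing downregulation is always a step on the treated samples.
#' @param ramp_start First passage affected by downregulation.
#' @param silencing_passages Range of passages from which
#'   passage-silenced genes switch off (inclusive bounds).
#' @param n_donors Expansion donors.
#' @param passages Expansion passage series.
#' @param n_per_tissue Licensing donors per tissue.
#' @param treatments Licensing cytokines applied beside resting.
#' @param seed Master seed; component streams (design, baseline, donor,
#'   effects, noise, dropout) are derived from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 1000L,
                       class_fractions = c(reliable = 0.80,
                                           reliable_downregulated = 0.05,
                                           never_detected = 0.05,
                                           sporadic = 0.05,
                                           condition_silenced = 0.05),
                       baseline_range = c(6, 12),
                       donor_sd = 0.3,
                       noise_sd = 0.25,
                       floor = 2.0,
                       down_logfc = -1.8,
                       dropout_prob = 0.05,
                       down_shape = c("ramp", "step"),
                       ramp_start = 10L,
                       silencing_passages = c(6L, 10L),
                       n_donors = 4L,
                       passages = 2:12,
                       n_per_tissue = 3L,
                       treatments = c("TNFa", "IFNg", "IL1b"),
                       seed = 1L) {
  down_shape <- match.arg(down_shape)
  if (!setequal(names(class_fractions), TRUTH_CLASSES)) {
    abort(paste0("class_fractions must be named over: ",
                 paste(TRUTH_CLASSES, collapse = ", ")))
  }
  class_fractions <- class_fractions[TRUTH_CLASSES]
  if (abs(sum(class_fractions) - 1) > 1e-8 || any(class_fractions < 0)) {
    abort("class_fractions must be non-negative and sum to 1")
  }
  if (donor_sd < 0 || noise_sd < 0 || dropout_prob < 0 || dropout_prob > 1) {
    abort("donor_sd/noise_sd must be >= 0 and dropout_prob in [0, 1]")
  }
  if (floor >= baseline_range[1]) abort("floor must lie below the baseline range")
  structure(list(
    n_genes = as.integer(n_genes), class_fractions = class_fractions,
    baseline_range = baseline_range, donor_sd = donor_sd,
    noise_sd = noise_sd, floor = floor, down_logfc = down_logfc,
    dropout_prob = dropout_prob, down_shape = down_shape,
    ramp_start = as.integer(ramp_start),
    silencing_passages = as.integer(silencing_passages),
    n_donors = as.integer(n_donors), passages = as.integer(passages),
    n_per_tissue = as.integer(n_per_tissue), treatments = treatments,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Deterministic class assignment by configured fractions
#' @noRd
assign_classes <- function(cfg) {
  n <- cfg$n_genes
  counts <- diff(c(0L, round(cumsum(cfg$class_fractions) * n)))
  rep(TRUTH_CLASSES, times = counts)
}

#' Forced-dropout mask for sporadic genes
#'
#' Each row: dropped where u < p, adjusted to keep at least one and at
#' most n-1 dropouts.
#' @noRd
sporadic_mask <- function(u, p) {
  drop <- u < p
  none <- rowSums(drop) == 0
  if (any(none)) {
    j <- apply(u[none, , drop = FALSE], 1, which.min)
    drop[cbind(which(none), j)] <- TRUE
  }
  all_drop <- rowSums(drop) == ncol(drop)
  if (any(all_drop)) {
    j <- apply(u[all_drop, , drop = FALSE], 1, which.max)
    drop[cbind(which(all_drop), j)] <- FALSE
  }
  drop
}

#' Assemble the shared value matrix (baseline + donor effect + noise)
#' @noRd
sim_base_matrix <- function(cfg, donor_idx, n_samples, seeds) {
  n <- cfg$n_genes
  set.seed(seeds[["baseline"]])
  baseline <- runif(n, cfg$baseline_range[1], cfg$baseline_range[2])
  set.seed(seeds[["donor"]])
  donor_eff <- matrix(rnorm(n * max(donor_idx), sd = cfg$donor_sd),
                      nrow = n, byrow = TRUE)
  set.seed(seeds[["noise"]])
  noise <- matrix(rnorm(n * n_samples, sd = cfg$noise_sd), nrow = n, byrow = TRUE)
  baseline + donor_eff[, donor_idx, drop = FALSE] + noise
}

#' Finish a simulated matrix: class overrides, censoring, packaging
#' @noRd
sim_package <- function(vals, cfg, classes, meta, affected, gene_ids, seeds) {
  n <- cfg$n_genes
  # never-detected genes sit at the floor in every sample
  vals[classes == "never_detected", ] <- cfg$floor
  # sporadic dropout
  spo <- which(classes == "sporadic")
  if (length(spo) > 0) {
    set.seed(seeds[["dropout"]])
    u <- matrix(runif(n * ncol(vals)), nrow = n, byrow = TRUE)[spo, , drop = FALSE]
    mask <- sporadic_mask(u, cfg$dropout_prob)
    sub <- vals[spo, , drop = FALSE]
    sub[mask] <- cfg$floor
    vals[spo, ] <- sub
  }
  vals <- pmax(vals, cfg$floor)
  rownames(vals) <- gene_ids
  colnames(vals) <- meta$sample_id
  truth <- tibble::tibble(
    gene = gene_ids, class = classes,
    true_logfc = ifelse(classes == "reliable_downregulated", cfg$down_logfc, NA_real_),
    affected = affected
  )
  list(expr = matrix_to_expr(vals, id_col = "gene", level = "gene"),
       meta = meta, truth = truth)
}

#' Simulate a serial-expansion dataset
#'
#' One array per donor per passage from P2 until the donor's final
#' passage; donors other than the first may exit culture at a random
#' late passage, mimicking senescence. Downregulated genes decline
#' linearly from `ramp_start` onward (or step down, per
#' `down_shape`); passage-silenced genes drop to the floor from a random
#' passage in `silencing_passages` through the end of the series.
#'
#' @param cfg A [sim_config()].
#' @return A list with `expr` (gene-level wide tibble), `meta` (sample
#'   metadata) and `truth` (per-gene truth table with `class`,
#'   `true_logfc`, `affected`).
#' @export
generate_expansion <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- setNames(derive_seeds(cfg$seed, 6),
                    c("design", "baseline", "donor", "effect", "noise", "dropout"))
  pas <- cfg$passages
  set.seed(seeds[["design"]])
  last <- c(max(pas), sample(pas[pas >= max(pas) - 2], cfg$n_donors - 1, replace = TRUE))
  design <- dplyr::bind_rows(purrr::map(seq_len(cfg$n_donors), function(d) {
    p <- pas[pas <= last[d]]
    tibble::tibble(donor = paste0("D", d), passage = p)
  })) |>
    dplyr::mutate(sample_id = paste0(.data$donor, "_P", .data$passage),
                  tissue = "UC", treatment = NA_character_) |>
    dplyr::select("sample_id", "donor", "tissue", "passage", "treatment")

  donor_idx <- as.integer(factor(design$donor, levels = paste0("D", seq_len(cfg$n_donors))))
  vals <- sim_base_matrix(cfg, donor_idx, nrow(design), seeds)
  classes <- assign_classes(cfg)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  affected <- rep(NA_character_, cfg$n_genes)

  set.seed(seeds[["effect"]])
  dn <- which(classes == "reliable_downregulated")
  if (length(dn) > 0) {
    p_end <- max(pas)
    frac <- ifelse(design$passage >= cfg$ramp_start,
                   if (cfg$down_shape == "ramp") {
                     (design$passage - cfg$ramp_start + 1) / (p_end - cfg$ramp_start + 1)
                   } else 1, 0)
    vals[dn, ] <- vals[dn, , drop = FALSE] +
      matrix(cfg$down_logfc * frac, nrow = length(dn), ncol = nrow(design), byrow = TRUE)
    affected[dn] <- paste0("P>=", cfg$ramp_start)
  }
  cs <- which(classes == "condition_silenced")
  if (length(cs) > 0) {
    k <- sample(seq(cfg$silencing_passages[1], cfg$silencing_passages[2]),
                length(cs), replace = TRUE)
    for (i in seq_along(cs)) {
      vals[cs[i], design$passage >= k[i]] <- cfg$floor
    }
    affected[cs] <- paste0("P>=", k)
  }
  sim_package(vals, cfg, classes, design, affected, gene_ids, seeds)
}

#' Simulate a licensing (cytokine-priming) dataset
#'
#' `n_per_tissue` donor populations per tissue (UC and BM), each arrayed
#' at rest and after each configured cytokine. Downregulated genes carry
#' the implanted log2 fold change in all samples primed with their
#' assigned cytokine (both tissues); condition-silenced genes sit at the
#' floor in every sample of one randomly assigned (tissue, cytokine)
#' group and are expressed elsewhere.
#'
#' @param cfg A [sim_config()].
#' @return As [generate_expansion()].
#' @export
generate_licensing <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- setNames(derive_seeds(cfg$seed, 6),
                    c("design", "baseline", "donor", "effect", "noise", "dropout"))
  treatments <- c("resting", cfg$treatments)
  design <- tidyr::expand_grid(
    tissue = c("UC", "BM"), idx = seq_len(cfg$n_per_tissue), treatment = treatments
  ) |>
    dplyr::mutate(donor = paste0(.data$tissue, .data$idx),
                  sample_id = paste0(.data$donor, "_", .data$treatment),
                  passage = NA_integer_) |>
    dplyr::select("sample_id", "donor", "tissue", "passage", "treatment")

  donors <- unique(design$donor)
  donor_idx <- as.integer(factor(design$donor, levels = donors))
  vals <- sim_base_matrix(cfg, donor_idx, nrow(design), seeds)
  classes <- assign_classes(cfg)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  affected <- rep(NA_character_, cfg$n_genes)

  set.seed(seeds[["effect"]])
  dn <- which(classes == "reliable_downregulated")
  if (length(dn) > 0) {
    if (length(cfg$treatments) == 0) {
      abort("downregulated genes need at least one cytokine treatment")
    }
    pool <- intersect(c("TNFa", "IFNg"), cfg$treatments)
    if (length(pool) == 0) pool <- cfg$treatments
    tr <- sample(pool, length(dn), replace = TRUE)
    for (i in seq_along(dn)) {
      vals[dn[i], design$treatment == tr[i]] <-
        vals[dn[i], design$treatment == tr[i]] + cfg$down_logfc
    }
    affected[dn] <- tr
  }
  cs <- which(classes == "condition_silenced")
  if (length(cs) > 0) {
    if (length(cfg$treatments) == 0) {
      abort("condition_silenced genes need at least one cytokine treatment")
    }
    groups <- tidyr::expand_grid(tissue = c("UC", "BM"), treatment = cfg$treatments)
    gi <- sample(nrow(groups), length(cs), replace = TRUE)
    for (i in seq_along(cs)) {
      sel <- design$tissue == groups$tissue[gi[i]] &
        design$treatment == groups$treatment[gi[i]]
      vals[cs[i], sel] <- cfg$floor
    }
    affected[cs] <- paste0(groups$tissue[gi], ":", groups$treatment[gi])
  }
  sim_package(vals, cfg, classes, design, affected, gene_ids, seeds)
}
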