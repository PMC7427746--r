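# Moderated two-group contrasts with empirical-Bayes variance shrinkage.
#
# The moderation model treats each gene's true residual variance as drawn
# from a scaled inverse chi-square prior with d0 degrees of freedom and
# scale s0^2; sample variances are shrunk toward s0^2 and the t statistic
# gains d0 extra degrees of freedom. The prior is estimated per contrast
# by moment-matching log sample variances to a scaled F distribution.

#' Build the pairwise contrasts implied by a study design
#'
#' For the expansion design (serial passaging), one contrast per passage
#' later than the reference: all passage-2 arrays versus all arrays at
#' that passage, donors serving as replicates. For the licensing design,
#' one contrast per tissue and cytokine: resting arrays of that tissue
#' versus cytokine-primed arrays of the same tissue.
#'
#' @param meta Sample metadata tibble (see [read_sample_meta()]).
#' @param family `"expansion"` (passage contrasts) or `"licensing"`
#'   (cytokine contrasts).
#' @param reference_passage Reference passage for the expansion family
#'   (default 2).
#' @param min_test Minimum test-group size; smaller groups (donors that
#'   exited culture before a late passage) are skipped with a warning.
#' @return A tibble with columns `name`, `family`, `tissue`, `treatment`,
#'   `passage`, and list-columns `reference` and `test` holding sample
#'   ids. Zero rows when nothing is comparable.
#' @export
build_contrasts <- function(meta, family = c("expansion", "licensing"),
                            reference_passage = 2L, min_test = 2L) {
  family <- match.arg(family)
  validate_meta(meta)
  empty <- tibble::tibble(name = character(), family = character(),
                          tissue = character(), treatment = character(),
                          passage = integer(),
                          reference = list(), test = list())
  if (family == "expansion") {
    if (!"passage" %in% names(meta) || all(is.na(meta$passage))) {
      abort("expansion contrasts need a 'passage' column in the metadata")
    }
    ref <- meta$sample_id[!is.na(meta$passage) & meta$passage == reference_passage]
    if (length(ref) == 0) {
      abort(paste0("no samples at reference passage P", reference_passage))
    }
    later <- sort(unique(meta$passage[!is.na(meta$passage) & meta$passage > reference_passage]))
    rows <- purrr::map(later, function(k) {
      test <- meta$sample_id[!is.na(meta$passage) & meta$passage == k]
      if (length(test) < min_test) {
        warn(paste0("skipping P", reference_passage, " vs P", k,
                    ": only ", length(test), " test sample(s)"))
        return(NULL)
      }
      tibble::tibble(name = paste0("P", reference_passage, "_vs_P", k),
                     family = "expansion", tissue = NA_character_,
                     treatment = NA_character_, passage = as.integer(k),
                     reference = list(ref), test = list(test))
    })
    out <- dplyr::bind_rows(rows)
  } else {
    if (!"treatment" %in% names(meta) || all(is.na(meta$treatment))) {
      abort("licensing contrasts need a 'treatment' column in the metadata")
    }
    cytokines <- c("TNFa", "IFNg", "IL1b")
    tissues <- sort(unique(meta$tissue[!is.na(meta$tissue)]))
    rows <- purrr::map(tissues, function(ti) {
      sub <- meta[!is.na(meta$tissue) & meta$tissue == ti, ]
      ref <- sub$sample_id[!is.na(sub$treatment) & sub$treatment == "resting"]
      present <- intersect(cytokines, unique(sub$treatment))
      if (length(ref) == 0 && length(present) > 0) {
        abort(paste0("no resting samples for tissue ", ti))
      }
      purrr::map(present, function(tr) {
        test <- sub$sample_id[!is.na(sub$treatment) & sub$treatment == tr]
        if (length(test) < min_test) {
          warn(paste0("skipping ", ti, " resting vs ", tr, ": only ",
                      length(test), " test sample(s)"))
          return(NULL)
        }
        tibble::tibble(name = paste0(ti, "_resting_vs_", tr),
                       family = "licensing", tissue = ti, treatment = tr,
                       passage = NA_integer_,
                       reference = list(ref), test = list(test))
      }) |> dplyr::bind_rows()
    })
    out <- dplyr::bind_rows(rows)
  }
  if (nrow(out) == 0) return(empty)
  out
}

#' Per-gene two-group summary statistics
#'
#' Computes group means, the pooled within-group sample variance and its
#' residual degrees of freedom for every gene, the inputs to variance
#' moderation.
#'
#' @param expr Gene-level wide expression tibble.
#' @param reference,test Character vectors of sample ids (disjoint,
#'   non-empty, all present in `expr`).
#' @param shared_variance Allow singleton groups (no within-group degrees
#'   of freedom); the pooled variance is then 0 with `d_g = 0` and a
#'   user-supplied prior must carry the moderation.
#' @return A tibble with columns `gene`, `mean_ref`, `mean_test`,
#'   `s_g_sq`, `d_g`, `n_ref`, `n_test`.
#' @export
fit_group_stats <- function(expr, reference, test, shared_variance = FALSE) {
  validate_expr(expr)
  m <- expr_to_matrix(expr)
  missing <- setdiff(c(reference, test), colnames(m))
  if (length(missing) > 0) {
    abort(paste0("sample(s) not in matrix: ", paste(head(missing, 5), collapse = ", ")))
  }
  if (length(intersect(reference, test)) > 0) abort("reference and test groups overlap")
  n_ref <- length(reference); n_test <- length(test)
  if (n_ref == 0 || n_test == 0) abort("both groups must be non-empty")
  d_g <- n_ref + n_test - 2L
  if (d_g < 1 && !shared_variance) {
    abort("no residual degrees of freedom; set shared_variance = TRUE or enlarge groups")
  }
  group_ss <- function(cols) {
    x <- m[, cols, drop = FALSE]
    mu <- rowMeans(x)
    list(mean = unname(mu), ss = unname(rowSums((x - mu)^2)))
  }
  r <- group_ss(reference); t_ <- group_ss(test)
  s_g_sq <- if (d_g >= 1) (r$ss + t_$ss) / d_g else rep(0, nrow(m))
  tibble::tibble(gene = rownames(m), mean_ref = r$mean, mean_test = t_$mean,
                 s_g_sq = s_g_sq, d_g = as.integer(d_g),
                 n_ref = n_ref, n_test = n_test)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on the
#' reciprocal (globally convergent for this convex decreasing function),
#' started from the asymptotic solution `1/sqrt(x)`.
#'
#' @param x Positive numeric vector.
#' @param tol Convergence tolerance on the relative step (default 1e-8).
#' @param max_iter Iteration cap.
#' @return Numeric vector `y` with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50L) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (is.na(xi)) NA_real_ else 0)
    if (xi <= 0) abort("trigamma_inverse() needs positive input")
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 1 / sqrt(xi)
    for (i in seq_len(max_iter)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (abs(dif) / y < tol) break
    }
    y
  }, numeric(1))
}

#' Construct a variance prior
#'
#' @param d0 Prior degrees of freedom (> 0, may be `Inf`; 0 is accepted
#'   to express the no-moderation limit).
#' @param s0_sq Prior variance (> 0).
#' @return An object of class `"variance_prior"`.
#' @export
variance_prior <- function(d0, s0_sq) {
  if (is.na(d0) || d0 < 0) abort("d0 must be >= 0 (Inf allowed)")
  if (!is.finite(s0_sq) || s0_sq <= 0) abort("s0_sq must be positive and finite")
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat("Variance prior: d0 =", format(x$d0), ", s0_sq =", format(x$s0_sq), "\n")
  invisible(x)
}

#' Estimate the variance prior across genes
#'
#' Moment-matches the log sample variances to their scaled-F sampling
#' distribution: the excess spread of `log(s_g^2)` beyond the chi-square
#' sampling component `trigamma(d_g/2)` determines `d0` through a
#' trigamma inversion, and the mean (with digamma corrections) determines
#' `s0^2`. When the empirical spread does not exceed the sampling
#' component, `d0` is infinite and all genes share `s0^2`.
#'
#' @param s_g_sq Per-gene sample variances (zeros are offset by the
#'   smallest positive variance times 1e-6 before taking logs).
#' @param d_g Residual degrees of freedom, scalar or per-gene vector.
#' @param min_genes Minimum usable genes (default 10).
#' @return A `"variance_prior"` object with fields `d0`, `s0_sq`,
#'   `n_genes`.
#' @export
estimate_variance_prior <- function(s_g_sq, d_g, min_genes = 10L) {
  d_g <- rep_len(d_g, length(s_g_sq))
  keep <- is.finite(s_g_sq) & d_g >= 1
  s2 <- s_g_sq[keep]; d <- d_g[keep]
  if (length(s2) < min_genes) {
    abort(paste0("need at least ", min_genes, " genes with d_g >= 1 to estimate the prior"))
  }
  if (any(s2 < 0)) abort("negative sample variance")
  if (any(s2 == 0)) {
    pos <- s2[s2 > 0]
    if (length(pos) == 0) abort("all sample variances are zero")
    s2[s2 == 0] <- min(pos) * 1e-6
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else if (var(log(s2)) == 0) {
    # literally identical variances: no sampling spread at all, so the
    # common value is the prior itself
    d0 <- Inf
    s0_sq <- s2[1]
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  out <- variance_prior(d0, s0_sq)
  out$n_genes <- length(s2)
  out
}

#' Moderated t statistics for a fitted contrast
#'
#' Shrinks each gene's pooled variance toward the prior,
#' `s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` (the limit `s0^2` when
#' `d0` is infinite), forms
#' `t = (mean_test - mean_ref) / sqrt(s~^2 (1/n_ref + 1/n_test))`, and
#' takes two-sided p-values on `d0 + d_g` degrees of freedom (standard
#' normal when infinite). With `d0 = 0` this is the ordinary pooled
#' two-sample t test.
#'
#' @param group_stats Tibble from [fit_group_stats()].
#' @param prior A `"variance_prior"` object.
#' @return `group_stats` extended with `logFC` (log2 fold change,
#'   test minus reference), `s_tilde_sq`, `t_mod`, `df_total`, `p`, and
#'   `signed_fc` (linear fold change, `2^logFC` for increases,
#'   `-2^(-logFC)` for decreases, so its magnitude is always >= 1).
#' @export
moderated_t <- function(group_stats, prior) {
  if (!inherits(prior, "variance_prior")) abort("prior must be a variance_prior object")
  gs <- tibble::as_tibble(group_stats)
  d0 <- prior$d0; s0 <- prior$s0_sq
  s_tilde <- if (is.infinite(d0)) rep(s0, nrow(gs)) else {
    (d0 * s0 + gs$d_g * gs$s_g_sq) / (d0 + gs$d_g)
  }
  diff <- gs$mean_test - gs$mean_ref
  se <- sqrt(s_tilde * (1 / gs$n_ref + 1 / gs$n_test))
  t_mod <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df_total <- d0 + gs$d_g
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t_mod)) else 2 * pt(-abs(t_mod), df = df_total)
  p[se == 0 & diff == 0] <- 1
  dplyr::mutate(gs,
    logFC = diff,
    s_tilde_sq = s_tilde,
    t_mod = t_mod,
    df_total = df_total,
    p = p,
    signed_fc = ifelse(.data$logFC >= 0, 2^.data$logFC, -(2^(-.data$logFC)))
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment across the genes of one contrast. Validates the
#' input range and delegates to the standard implementation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select significantly changed genes with sequential filtering
#'
#' Applies the adjusted-p cutoff first, then the linear fold-change
#' cutoff (the selected set equals the joint filter; stage counts are
#' attached so the attrition is reportable).
#'
#' @param result Tibble with columns `gene`, `p_adj`, `signed_fc`.
#' @param alpha Adjusted-p threshold (default 0.05, strict `<`).
#' @param fold Linear fold-change threshold on the magnitude, inclusive
#'   (default 2; 1.5 is the conventional setting for aging-gene
#'   reports).
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of gene symbols, with attributes `n_tested`,
#'   `n_fdr` (past the adjusted-p stage) and `n_selected`.
#' @export
significant_genes <- function(result, alpha = 0.05, fold = 2,
                              direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (alpha <= 0 || fold < 1) abort("need alpha > 0 and fold >= 1")
  stage1 <- result[result$p_adj < alpha, , drop = FALSE]
  stage2 <- stage1[abs(stage1$signed_fc) >= fold, , drop = FALSE]
  stage2 <- switch(direction,
    both = stage2,
    up = stage2[stage2$signed_fc > 0, , drop = FALSE],
    down = stage2[stage2$signed_fc < 0, , drop = FALSE]
  )
  out <- stage2$gene
  attr(out, "n_tested") <- nrow(result)
  attr(out, "n_fdr") <- nrow(stage1)
  attr(out, "n_selected") <- length(out)
  out
}

#' Fit moderated contrasts across a design
#'
#' Runs [fit_group_stats()], [estimate_variance_prior()],
#' [moderated_t()] and [bh_adjust()] for every contrast; the prior is
#' estimated separately within each contrast and adjustment is per
#' contrast.
#'
#' @param expr Gene-level wide expression tibble.
#' @param meta Sample metadata tibble.
#' @param family Design family passed to [build_contrasts()] when
#'   `contrasts` is not supplied.
#' @param contrasts Optional contrast tibble from [build_contrasts()].
#' @param prior Optional fixed `"variance_prior"` applied to every
#'   contrast instead of per-contrast estimation.
#' @return An object of class `"mscl_de"`: list with `results` (long
#'   tibble over gene x contrast with `p_adj`) and `priors` (one row per
#'   contrast). Use [tidy()] for the gene-level table, [glance()] for the
#'   per-contrast priors, and [autoplot()] for a volcano display.
#' @export
fit_contrasts <- function(expr, meta, family = c("expansion", "licensing"),
                          contrasts = NULL, prior = NULL) {
  if (is.null(contrasts)) contrasts <- build_contrasts(meta, match.arg(family))
  if (nrow(contrasts) == 0) {
    abort("no contrasts to fit")
  }
  fits <- purrr::pmap(list(contrasts$name, contrasts$reference, contrasts$test),
    function(nm, ref, test) {
      gs <- fit_group_stats(expr, ref, test)
      pr <- prior %||% estimate_variance_prior(gs$s_g_sq, gs$d_g[1])
      res <- moderated_t(gs, pr)
      res$p_adj <- bh_adjust(res$p)
      res$contrast <- nm
      list(result = res, prior = tibble::tibble(
        contrast = nm, d0 = pr$d0, s0_sq = pr$s0_sq,
        n_genes = nrow(gs), n_ref = length(ref), n_test = length(test)))
    })
  out <- structure(list(
    results = dplyr::bind_rows(purrr::map(fits, "result")) |>
      dplyr::relocate("contrast"),
    priors = dplyr::bind_rows(purrr::map(fits, "prior")),
    contrasts = contrasts
  ), class = "mscl_de")
  out
}

#' @export
print.mscl_de <- function(x, ...) {
  cat("Moderated contrast fit:", nrow(x$priors), "contrast(s),",
      length(unique(x$results$gene)), "genes\n")
  print(x$priors)
  invisible(x)
}

#' Tidy gene-level results of a contrast fit
#'
#' @param x An `"mscl_de"` object.
#' @param ... Unused.
#' @return Long tibble over gene x contrast with effect sizes and
#'   (adjusted) p-values.
#' @method tidy mscl_de
#' @export
tidy.mscl_de <- function(x, ...) x$results

#' One-row-per-contrast summary of a fit
#'
#' @param x An `"mscl_de"` object.
#' @param ... Unused.
#' @return Tibble with the estimated prior (`d0`, `s0_sq`), group sizes
#'   and gene count per contrast.
#' @method glance mscl_de
#' @export
glance.mscl_de <- function(x, ...) x$priors
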