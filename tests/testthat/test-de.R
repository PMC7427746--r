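test_that("contrast construction mirrors both study designs", {
  meta_e <- make_expansion_meta(paste0("D", 1:4), 2:12)
  ce <- build_contrasts(meta_e, "expansion")
  expect_equal(nrow(ce), 10L)
  expect_equal(ce$name[1], "P2_vs_P3")
  expect_equal(ce$name[10], "P2_vs_P12")
  expect_true(all(lengths(ce$reference) == 4))

  meta_l <- make_licensing_meta()
  cl <- build_contrasts(meta_l, "licensing")
  expect_equal(nrow(cl), 6L)
  expect_setequal(cl$name, c(outer(c("UC", "BM"), c("TNFa", "IFNg", "IL1b"),
                                   function(a, b) paste0(a, "_resting_vs_", b))))
  expect_true(all(lengths(cl$reference) == 3))

  single <- make_expansion_meta("D1", 2)
  expect_equal(nrow(build_contrasts(single, "expansion")), 0L)

  expect_error(build_contrasts(make_expansion_meta("D1", 5:8), "expansion"),
               "reference passage")
  no_rest <- make_licensing_meta(treatments = c("TNFa"))
  expect_error(build_contrasts(no_rest, "licensing"), "resting")
})

test_that("donors missing a passage shrink or skip that contrast", {
  meta <- make_expansion_meta(paste0("D", 1:3), 2:4)
  meta <- meta[!(meta$donor %in% c("D2", "D3") & meta$passage == 4), ]
  expect_warning(ct <- build_contrasts(meta, "expansion"), "P2 vs P4")
  expect_equal(ct$name, "P2_vs_P3")
})

test_that("group statistics match hand-computed pooled variance", {
  m <- rbind(g1 = c(4, 6, 5, 7), g2 = c(1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  gs <- fit_group_stats(make_expr(m), reference = c("s1", "s2"), test = c("s3", "s4"))
  expect_equal(gs$mean_ref[1], 5)
  expect_equal(gs$mean_test[1], 6)
  expect_equal(gs$s_g_sq[1], 2)       # pooled: (2 + 2) / 2
  expect_equal(gs$d_g[1], 2L)
  expect_equal(gs$s_g_sq[2], 0)       # identical groups allowed; moderation rescues

  m8 <- matrix(rnorm(16), 2, dimnames = list(c("a", "b"), paste0("s", 1:8)))
  gs8 <- fit_group_stats(make_expr(m8), paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(gs8$d_g[1], 6L)

  expect_error(fit_group_stats(make_expr(m), "s1", "s3"), "degrees of freedom")
})

test_that("trigamma inversion round-trips and the prior estimator has correct limits", {
  for (x in c(1e-3, 0.1, 1, 5)) {
    expect_lt(abs(trigamma(trigamma_inverse(x)) - x), 1e-8)
  }
  # identical sample variances: no excess spread, infinite prior df
  pr <- estimate_variance_prior(rep(0.3, 50), d_g = 4)
  expect_true(is.infinite(pr$d0))
  expect_equal(pr$s0_sq, 0.3, tolerance = 1e-10)

  expect_error(estimate_variance_prior(rep(0.3, 5), d_g = 4), "at least 10")
})

test_that("prior estimation recovers hierarchical-model parameters", {
  set.seed(2024)
  d0 <- 4; s0 <- 0.05; d_g <- 4
  s2 <- s0 * stats::rf(10000, d_g, d0)
  pr <- estimate_variance_prior(s2, d_g)
  expect_lt(abs(pr$d0 - d0) / d0, 0.10)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.10)
})

test_that("moderated t reduces to the ordinary pooled t when d0 = 0", {
  set.seed(5)
  m <- matrix(rnorm(10 * 8, mean = 8), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  ref <- paste0("s", 1:4); test <- paste0("s", 5:8)
  gs <- fit_group_stats(make_expr(m), ref, test)
  res <- moderated_t(gs, variance_prior(d0 = 0, s0_sq = 1))
  for (i in 1:10) {
    tt <- t.test(m[i, test], m[i, ref], var.equal = TRUE)
    expect_lt(abs(res$t_mod[i] - unname(tt$statistic)), 1e-10)
    expect_lt(abs(res$p[i] - tt$p.value), 1e-10)
  }
})

test_that("moderated t handles equal means and the infinite-prior limit", {
  m <- rbind(g1 = c(5, 6, 5, 6), g2 = c(1, 2, 3, 4))
  colnames(m) <- paste0("s", 1:4)
  gs <- fit_group_stats(make_expr(m), c("s1", "s2"), c("s3", "s4"))
  res <- moderated_t(gs, variance_prior(3, 0.05))
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p[1], 1)

  res_inf <- moderated_t(gs, variance_prior(Inf, 0.05))
  expect_true(all(abs(res_inf$s_tilde_sq - 0.05) < 1e-10))
})

test_that("a fixed case matches an independent step-by-step evaluation", {
  ref <- c(10.1, 10.3, 9.9, 10.2); test <- c(8.9, 9.2, 9.0, 9.1)
  m <- rbind(g = c(ref, test))
  colnames(m) <- paste0("s", 1:8)
  gs <- fit_group_stats(make_expr(m), paste0("s", 1:4), paste0("s", 5:8))
  res <- moderated_t(gs, variance_prior(3, 0.05))
  # independent scalar evaluation
  s2 <- (sum((ref - mean(ref))^2) + sum((test - mean(test))^2)) / 6
  st <- (3 * 0.05 + 6 * s2) / (3 + 6)
  tt <- (mean(test) - mean(ref)) / sqrt(st * (1/4 + 1/4))
  pp <- 2 * pt(-abs(tt), df = 9)
  expect_equal(res$t_mod, tt, tolerance = 1e-12)
  expect_equal(res$p, pp, tolerance = 1e-12)
  expect_equal(res$df_total, 9)
})

test_that("BH adjustment matches step-up enumeration and preserves rank order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute_force(p))
    # monotone: sorting by raw p never decreases the adjusted values
    expect_false(is.unsorted(adj[order(p)]))
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("sequential significance filtering applies FDR then fold change", {
  res <- tibble::tibble(
    gene = c("EMP2", "bigNS", "smallFC"),
    p_adj = c(0.046, 0.2, 0.01),
    signed_fc = c(-2.89, -10, -1.5))
  expect_equal(as.character(significant_genes(res)), "EMP2")
  got <- significant_genes(res)
  expect_equal(attr(got, "n_tested"), 3L)
  expect_equal(attr(got, "n_fdr"), 2L)
  # the relaxed 1.5-fold aging-gene setting admits the smaller change
  expect_setequal(as.character(significant_genes(res, fold = 1.5)),
                  c("EMP2", "smallFC"))
  expect_equal(as.character(significant_genes(res, fold = 1.5, direction = "up")),
               character(0))
})

test_that("signed fold change round-trips through log2 magnitude", {
  logfc <- c(-3.2, -0.5, 0, 0.5, 4.1)
  gs <- tibble::tibble(gene = letters[1:5], mean_ref = 0, mean_test = logfc,
                       s_g_sq = 1, d_g = 4L, n_ref = 3L, n_test = 3L)
  res <- moderated_t(gs, variance_prior(4, 1))
  expect_true(all(abs(res$signed_fc) >= 1))
  expect_equal(log2(abs(res$signed_fc)), abs(logfc), tolerance = 1e-12)
})

test_that("the fit agrees with limma's empirical-Bayes implementation", {
  set.seed(77)
  n <- 300; nr <- 4; nt <- 4
  sigma2 <- 0.05 * stats::rf(n, nr + nt - 2, 4)
  m <- t(sapply(seq_len(n), function(i) rnorm(nr + nt, mean = 8, sd = sqrt(sigma2[i]))))
  dimnames(m) <- list(paste0("g", seq_len(n)), paste0("s", seq_len(nr + nt)))
  ref <- paste0("s", 1:nr); test <- paste0("s", nr + 1:nt)

  gs <- fit_group_stats(make_expr(m), ref, test)
  pr <- estimate_variance_prior(gs$s_g_sq, gs$d_g[1])
  res <- moderated_t(gs, pr)

  design <- cbind(Intercept = 1, grp = rep(c(0, 1), c(nr, nt)))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(pr$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, "grp"]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, "grp"]), tolerance = 1e-8)
})

test_that("fit_contrasts assembles per-contrast priors and adjusted p-values", {
  sim <- generate_licensing(sim_config(n_genes = 120, seed = 8))
  fit <- fit_contrasts(sim$expr, sim$meta, family = "licensing")
  expect_s3_class(fit, "mscl_de")
  pri <- glance(fit)
  expect_equal(nrow(pri), 6L)
  res <- tidy(fit)
  expect_equal(nrow(res), 6L * 120L)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_true(all(res$p >= 0 & res$p_adj <= 1))
  # adjustment is per contrast
  one <- res[res$contrast == pri$contrast[1], ]
  expect_equal(one$p_adj, bh_adjust(one$p))
})
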