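# Hand-built detection patterns exercising the reliability taxonomy.

licensing_det <- function(pattern) {
  meta <- make_licensing_meta()
  det <- matrix(TRUE, nrow = length(pattern), ncol = nrow(meta),
                dimnames = list(names(pattern), meta$sample_id))
  for (g in names(pattern)) det[g, pattern[[g]]] <- FALSE
  list(calls = make_calls(det), meta = meta)
}

test_that("licensing statuses follow the taxonomy with correct precedence", {
  meta <- make_licensing_meta()
  all_ids <- meta$sample_id
  fx <- licensing_det(list(
    CXCL2 = character(0),                                  # detected everywhere
    SMIM14 = all_ids,                                      # never detected
    LAMA4 = meta$sample_id[meta$tissue == "UC" & meta$treatment == "TNFa"],
    ONEOFF = "UC1_TNFa"                                    # single dropout
  ))
  st <- classify_genes(fx$calls, fx$meta, family = "licensing")
  got <- setNames(st$status, st$gene)
  expect_equal(got[["CXCL2"]], "reliable")
  expect_equal(got[["SMIM14"]], "never_detected")
  expect_equal(got[["LAMA4"]], "condition_silenced")
  expect_equal(st$silenced_conditions[st$gene == "LAMA4"][[1]], "UC:TNFa")
  # a single undetected sample is sporadic, never silencing
  expect_equal(got[["ONEOFF"]], "sporadic")
  # exactly one status per gene, lists empty where the taxonomy demands
  expect_equal(anyDuplicated(st$gene), 0L)
  expect_length(st$downregulated_in[st$gene == "SMIM14"][[1]]$contrast, 0)
})

test_that("passage silencing needs at least two consecutive silent passages", {
  meta <- make_expansion_meta(paste0("D", 1:4), 2:12)
  det <- matrix(TRUE, nrow = 3, ncol = nrow(meta),
                dimnames = list(c("ISLR", "TAIL1", "MID"), meta$sample_id))
  det["ISLR", meta$sample_id[meta$passage > 8]] <- FALSE     # off after P8
  det["TAIL1", meta$sample_id[meta$passage == 12]] <- FALSE  # only final passage off
  det["MID", meta$sample_id[meta$passage %in% 6:7]] <- FALSE # silent gap, detected after
  st <- classify_genes(make_calls(det), meta, family = "expansion")
  got <- setNames(st$status, st$gene)
  expect_equal(got[["ISLR"]], "condition_silenced")
  expect_equal(st$silenced_conditions[st$gene == "ISLR"][[1]], "P>=9")
  expect_equal(got[["TAIL1"]], "sporadic")
  expect_equal(got[["MID"]], "sporadic")
})

test_that("downregulation annotations come from significant negative contrasts only", {
  sim <- generate_expansion(sim_config(n_genes = 300, seed = 13))
  calls <- call_detection(sim$expr)
  de <- fit_contrasts(sim$expr, sim$meta, family = "expansion")
  st <- classify_genes(calls, sim$meta, de = de, family = "expansion")
  down <- st$gene[lengths(purrr::map(st$downregulated_in, "contrast")) > 0]
  truth_down <- sim$truth$gene[sim$truth$class == "reliable_downregulated"]
  # most implanted late-passage declines are flagged (power is limited:
  # 4 reference arrays against the few donors still in culture late),
  # and no silenced or never-detected gene carries a downregulation record
  expect_gte(mean(truth_down %in% down), 0.7)
  off <- sim$truth$gene[sim$truth$class %in% c("never_detected", "condition_silenced")]
  expect_length(intersect(down, off), 0)
  flagged <- dplyr::bind_rows(st$downregulated_in[st$gene %in% down])
  expect_true(all(flagged$signed_fc < 0 & flagged$p_adj < 0.05))
})

test_that("induction is flagged only from a silent resting baseline", {
  meta <- make_licensing_meta()
  det <- matrix(TRUE, nrow = 3, ncol = nrow(meta),
                dimnames = list(c("SAA2", "RESTON", "ALWAYSOFF"), meta$sample_id))
  det["SAA2", meta$sample_id[meta$treatment == "resting"]] <- FALSE
  det["SAA2", meta$sample_id[meta$tissue == "UC"]] <- FALSE
  det["SAA2", c("BM1_TNFa", "BM2_TNFa")] <- TRUE
  det["SAA2", meta$sample_id[meta$tissue == "BM" & meta$treatment %in% c("IFNg", "IL1b")]] <- FALSE
  det["ALWAYSOFF", ] <- FALSE
  ind <- annotate_induction(make_calls(det), meta)
  expect_equal(ind$gene, "SAA2")
  expect_equal(ind$tissue, "BM")
  expect_equal(ind$treatment, "TNFa")
  # detected at rest (RESTON) and undetected everywhere (ALWAYSOFF): no flag
  expect_false(any(c("RESTON", "ALWAYSOFF") %in% ind$gene))
})

test_that("summaries count, round half-up and partition the assessed genes", {
  st <- tibble::tibble(gene = paste0("g", 1:10),
                       status = c(rep("reliable", 9), "sporadic"))
  s <- summarize_classification(st, dataset_id = "toy")
  expect_equal(s$n_assessed, 10L)
  expect_equal(s$n_reliable, 9L)
  expect_equal(s$pct_reliable, 90L)

  # 435/445 rounds 97.75 up to 98
  big <- tibble::tibble(gene = paste0("g", 1:445),
                        status = c(rep("reliable", 435), rep("sporadic", 10)))
  expect_equal(summarize_classification(big)$pct_reliable, 98L)

  # counts always partition n_assessed
  tot <- s$n_reliable + s$n_sporadic + s$n_never_detected + s$n_condition_silenced
  expect_equal(tot, s$n_assessed)

  # unclassified on-platform gene is an error; not-on-platform genes are not
  expect_error(summarize_classification(st, signature = c(st$gene, "MISSING")),
               "unclassified")
  s2 <- summarize_classification(st, signature = c(st$gene, "OFFCHIP"),
                                 not_on_platform = "OFFCHIP")
  expect_equal(s2$n_assessed, 10L)
})

test_that("consensus intersects reliable sets and unions unreliable ones", {
  a <- tibble::tibble(gene = c("A", "B", "C"), status = c("reliable", "reliable", "reliable"))
  b <- tibble::tibble(gene = c("B", "C", "D"), status = c("reliable", "reliable", "reliable"))
  cons <- consensus_reliability(a, b)
  expect_equal(cons$consensus_reliable, c("B", "C"))
  expect_equal(cons$consensus_unreliable, character(0))

  a2 <- tibble::tibble(gene = c("A", "B", "C"),
                       status = c("reliable", "sporadic", "never_detected"))
  b2 <- tibble::tibble(gene = c("A", "B", "C"),
                       status = c("reliable", "reliable", "never_detected"))
  cons2 <- consensus_reliability(a2, b2)
  expect_equal(cons2$consensus_reliable, "A")
  expect_equal(cons2$consensus_unreliable, c("B", "C"))
  expect_equal(cons2$unreliable_in_both, "C")
  # consensus-reliable is contained in each per-dataset reliable set
  expect_true(all(cons2$consensus_reliable %in% a2$gene[a2$status == "reliable"]))
  expect_true(all(cons2$consensus_reliable %in% b2$gene[b2$status == "reliable"]))
})
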