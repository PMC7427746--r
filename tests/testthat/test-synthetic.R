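test_that("generation is deterministic and censored at the floor", {
  cfg <- sim_config(n_genes = 150, seed = 404)
  a <- generate_expansion(cfg); b <- generate_expansion(cfg)
  expect_identical(a, b)
  l1 <- generate_licensing(cfg); l2 <- generate_licensing(cfg)
  expect_identical(l1, l2)
  expect_true(all(as.matrix(a$expr[, -1]) >= cfg$floor))
  expect_true(all(as.matrix(l1$expr[, -1]) >= cfg$floor))
})

test_that("truth classes are exhaustive and mutually exclusive", {
  sim <- generate_expansion(sim_config(n_genes = 200, seed = 2))
  expect_equal(nrow(sim$truth), 200L)
  expect_equal(anyDuplicated(sim$truth$gene), 0L)
  expect_true(all(sim$truth$class %in% c("reliable", "reliable_downregulated",
                                         "never_detected", "sporadic",
                                         "condition_silenced")))
  expect_setequal(sim$truth$gene, sim$expr$gene)
})

test_that("the zero-noise, all-reliable limit yields constant detected genes", {
  cfg <- sim_config(n_genes = 40, donor_sd = 0, noise_sd = 0,
                    class_fractions = c(reliable = 1, reliable_downregulated = 0,
                                        never_detected = 0, sporadic = 0,
                                        condition_silenced = 0),
                    seed = 9)
  sim <- generate_expansion(cfg)
  m <- as.matrix(sim$expr[, -1])
  expect_true(all(apply(m, 1, function(r) diff(range(r)) == 0)))
  # no gene touches the floor here, so the known floor is supplied
  st <- classify_genes(call_detection(sim$expr, floor_value = cfg$floor),
                       sim$meta, family = "expansion")
  expect_true(all(st$status == "reliable"))
})

test_that("censoring fraction rises monotonically with the floor", {
  frac <- vapply(c(2, 4, 6, 8), function(fl) {
    sim <- generate_expansion(sim_config(n_genes = 150, floor = fl, seed = 5,
                                         baseline_range = c(9, 12)))
    mean(as.matrix(sim$expr[, -1]) == fl)
  }, numeric(1))
  expect_false(is.unsorted(frac))
})

test_that("licensing silencing hits exactly one complete cytokine group per gene", {
  sim <- generate_licensing(sim_config(n_genes = 200, seed = 31))
  calls <- call_detection(sim$expr)
  cm <- dplyr::left_join(calls, sim$meta, by = "sample_id")
  cs_genes <- sim$truth$gene[sim$truth$class == "condition_silenced"]
  grp <- cm |>
    dplyr::filter(gene %in% cs_genes) |>
    dplyr::group_by(gene, tissue, treatment) |>
    dplyr::summarise(all_off = !any(detected), .groups = "drop") |>
    dplyr::group_by(gene) |>
    dplyr::summarise(n_off = sum(all_off), off_is_cytokine = all(treatment[all_off] != "resting"))
  expect_true(all(grp$n_off == 1))
  expect_true(all(grp$off_is_cytokine))
  # and matches the recorded truth annotation
  ann <- sim$truth$affected[match(grp$gene, sim$truth$gene)]
  off <- cm |>
    dplyr::filter(gene %in% cs_genes) |>
    dplyr::group_by(gene, tissue, treatment) |>
    dplyr::summarise(all_off = !any(detected), .groups = "drop") |>
    dplyr::filter(all_off)
  expect_equal(paste0(off$tissue, ":", off$treatment)[match(grp$gene, off$gene)], ann)
})

test_that("a resting-only design yields no buildable contrasts", {
  cfg <- sim_config(n_genes = 30, treatments = character(0),
                    class_fractions = c(reliable = 0.9, reliable_downregulated = 0,
                                        never_detected = 0.1, sporadic = 0,
                                        condition_silenced = 0),
                    seed = 3)
  sim <- generate_licensing(cfg)
  expect_equal(sort(unique(sim$meta$treatment)), "resting")
  expect_equal(nrow(sim$meta), 6L)
  expect_equal(nrow(build_contrasts(sim$meta, "licensing")), 0L)
})

test_that("sporadic genes always carry at least one and never all dropouts", {
  sim <- generate_licensing(sim_config(n_genes = 300, seed = 17))
  calls <- call_detection(sim$expr)
  spo <- sim$truth$gene[sim$truth$class == "sporadic"]
  rates <- calls |>
    dplyr::filter(gene %in% spo) |>
    dplyr::group_by(gene) |>
    dplyr::summarise(n_det = sum(detected), n = dplyr::n())
  expect_true(all(rates$n_det >= 1 & rates$n_det < rates$n))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_fractions = c(reliable = 0.9, reliable_downregulated = 0,
                                              never_detected = 0, sporadic = 0,
                                              condition_silenced = 0)), "sum to 1")
  expect_error(sim_config(floor = 7), "floor")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})
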