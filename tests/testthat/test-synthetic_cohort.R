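test_that("default programmed effects match the study design", {
  eff <- default_ptccrcc_effects()
  by_label <- setNames(eff, vapply(eff, `[[`, character(1), "gene_label"))
  b <- by_label[["CLDN10B-like"]]
  expect_lt(b$control_mean, 0.20)
  expect_gt(b$tumor_delta, 0.40)
  a <- by_label[["CLDN10A-like"]]
  expect_lt(a$tumor_delta, 0)
  expect_lte(abs(a$tumor_delta), 0.15)
  expect_equal(by_label[["RASSF1A-like"]]$tumor_delta, 0.30,
               tolerance = 0.02)
  expect_identical(by_label[["BACKGROUND-NULL"]]$tumor_delta, 0)
})

test_that("build_manifest lays out genes, probes and regions", {
  cfg <- cohort_config(n_background_genes = 10, probes_per_gene = 4)
  eff <- default_ptccrcc_effects()
  man <- build_manifest(cfg, eff)
  expect_equal(length(unique(man$gene)), 14)
  expect_equal(nrow(man), 56)
  expect_false(any(duplicated(man$probe_id)))
  expect_true(all(vapply(eff, `[[`, character(1), "gene_label") %in%
                    man$gene))
  # positions strictly increasing per contig
  for (ctg in unique(man$contig)) {
    expect_true(all(diff(man$position[man$contig == ctg]) > 0))
  }
  # effect genes carry their programmed region on every probe
  expect_true(all(man$cgi_relation[man$gene == "CLDN10B-like"] == "island"))
  expect_true(all(man$cgi_relation[man$gene == "BACKGROUND-NULL"] ==
                    "open_sea"))
})

test_that("build_manifest rejects duplicate gene labels by name", {
  cfg <- cohort_config(n_background_genes = 0)
  eff <- list(effect_spec("GENEX"), effect_spec("GENEX"))
  expect_error(build_manifest(cfg, eff), "GENEX")
})

test_that("simulate_cohort shapes, pairing and support", {
  cfg <- cohort_config(n_background_genes = 10, seed = 3)
  eff <- default_ptccrcc_effects()
  man <- build_manifest(cfg, eff)
  ch <- simulate_cohort(man, eff, cfg)
  expect_equal(dim(ch$beta), c(nrow(man), 10))
  expect_true(all(ch$beta > 0 & ch$beta < 1))
  expect_silent(validate_sample_sheet(ch$sheet))
  # pairing is a bijection: 5 pairs, each with one tumor and one normal
  expect_equal(length(unique(ch$sheet$pair_id)), 5)
  # rejection names the absent effect gene
  stray <- c(eff, list(effect_spec("NOT-IN-MANIFEST")))
  expect_error(simulate_cohort(man, stray, cfg), "NOT-IN-MANIFEST")
})

test_that("same configuration gives bit-identical cohorts", {
  a <- small_cohort(seed = 11, n_background = 20)
  b <- small_cohort(seed = 11, n_background = 20)
  expect_identical(a$beta, b$beta)
  expect_identical(a$manifest, b$manifest)
})

test_that("per-gene sub-streams are stable when other genes are added", {
  cfg <- cohort_config(n_background_genes = 5, seed = 9)
  eff <- default_ptccrcc_effects()
  man <- build_manifest(cfg, eff)
  ch1 <- simulate_cohort(man, eff, cfg)
  cfg2 <- cohort_config(n_background_genes = 25, seed = 9)
  ch2 <- simulate_cohort(build_manifest(cfg2, eff), eff, cfg2)
  shared <- rownames(ch1$beta)
  expect_identical(ch1$beta[shared, ], ch2$beta[shared, ])
})

test_that("noise-free limit recovers the programmed deltas", {
  cfg <- cohort_config(n_background_genes = 0, noise_precision = 1e6,
                       seed = 2)
  eff <- default_ptccrcc_effects()
  man <- build_manifest(cfg, eff)
  ch <- simulate_cohort(man, eff, cfg)
  tum <- ch$sheet$sample_id[ch$sheet$condition == "tumor"]
  nor <- ch$sheet$sample_id[ch$sheet$condition == "normal"]
  for (e in eff) {
    rows <- man$probe_id[man$gene == e$gene_label]
    emp <- mean(ch$beta[rows, tum]) - mean(ch$beta[rows, nor])
    expect_equal(emp, e$tumor_delta, tolerance = 0.005)
  }
})

test_that("per-probe variance decreases with noise precision", {
  eff <- list(effect_spec("GENEX", control_mean = 0.3))
  vars <- vapply(c(50, 500, 5000), function(s) {
    cfg <- cohort_config(n_pairs = 100, n_background_genes = 0,
                         probes_per_gene = 2, noise_precision = s,
                         seed = 5)
    ch <- simulate_cohort(build_manifest(cfg, eff), eff, cfg)
    mean(apply(ch$beta, 1, var))
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("generate_template honors explicit sequences and states", {
  tpl <- generate_template(sequence = "ATCGAT", methylation = "all")
  expect_identical(tpl$cpg_positions, 3L)
  expect_true(tpl$methylation)
  expect_error(generate_template(sequence = "ATCGAT",
                                 cpg_positions = c(1)), "non-CG")
})

test_that("generate_template random mode is reproducible and honors density", {
  t1 <- generate_template(length = 300, cpg_density = 0.05, seed = 7)
  t2 <- generate_template(length = 300, cpg_density = 0.05, seed = 7)
  expect_identical(t1$sequence, t2$sequence)
  expect_identical(t1$methylation, t2$methylation)
  # CpG position list always equals the CG occurrences in the sequence
  expect_identical(t1$cpg_positions,
                   as.integer(scan_oracle(t1$sequence, "CG")))
  t0 <- generate_template(length = 200, cpg_density = 0, seed = 8)
  expect_length(t0$cpg_positions, 0)
  tp <- generate_template(length = 100, cpg_positions = c(10, 40, 71),
                          seed = 9)
  expect_identical(tp$cpg_positions, c(10L, 40L, 71L))
})

test_that("signature panel reproduces programmed class geometry", {
  pan <- simulate_signature_panel(n_per_class = 5, seed = 3)
  expect_equal(ncol(pan$beta), 15)
  aggA <- aggregate_cgi(pan$beta, pan$manifest, "CLDN10A-like", "A")
  dA <- aggA$mean_beta - pan$reference[["A"]]
  expect_true(all(dA[pan$classes == "ccRCC_pRCC_like"] < -0.05))
  expect_true(all(abs(dA[pan$classes == "non_RCC_like"]) < 0.05))
})
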