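test_that("same seed reproduces the fixture bundle byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(sim_config(seed = 1), out_dir = d1)
  simulate_dataset(sim_config(seed = 1), out_dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 14)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("truth manifest bookkeeping matches the configuration", {
  cfg <- sim_config(seed = 3, n_hypodmr_true = 20)
  b <- simulate_dataset(cfg)
  expect_length(b$truth$true_hypodmr_ids, 20)
  expect_true(all(b$truth$true_hypodmr_ids %in% b$regions$name))
  expect_true(all(b$truth$qualifying_hypodmr_ids %in%
                    b$truth$motif_hypodmr_ids))
  expect_true(all(b$truth$qualifying_hypodmr_ids %in%
                    b$truth$atac_hypodmr_ids))
  expect_true(all(b$truth$regulon[[1]] %in% rownames(b$expr)))
  expect_true(all(b$truth$immune_program_genes %in% rownames(b$expr)))
  expect_length(b$truth$immune_program_genes, cfg$immune_program_size)
  # betas in [0,1], expression non-negative
  expect_true(all(b$beta >= 0 & b$beta <= 1))
  expect_true(all(b$expr >= 0))
  expect_true(all(b$kd_expr >= 0))
})

test_that("planted hypoDMRs realize the configured beta drop", {
  # group-mean difference within hypo_delta +/- noise sd for >= 95% of true
  # regions, pooled over seeds
  hits <- 0; tot <- 0
  for (s in 1:10) {
    b <- simulate_dataset(sim_config(seed = s))
    tum <- names(b$beta_groups)[b$beta_groups == "tumor"]
    nor <- names(b$beta_groups)[b$beta_groups == "normal"]
    diff <- rowMeans(b$beta[b$truth$true_hypodmr_ids, nor, drop = FALSE]) -
      rowMeans(b$beta[b$truth$true_hypodmr_ids, tum, drop = FALSE])
    hits <- hits + sum(abs(diff - 0.4) <= 0.05)
    tot <- tot + length(diff)
  }
  expect_gte(hits / tot, 0.95)
})

test_that("non-DMR regions have exchangeable tumor/normal betas", {
  b <- simulate_dataset(sim_config(seed = 5))
  other <- setdiff(rownames(b$beta), b$truth$true_hypodmr_ids)
  tum <- names(b$beta_groups)[b$beta_groups == "tumor"]
  nor <- names(b$beta_groups)[b$beta_groups == "normal"]
  diff <- rowMeans(b$beta[other, tum, drop = FALSE]) -
    rowMeans(b$beta[other, nor, drop = FALSE])
  expect_lt(abs(mean(diff)), 0.01)
})

test_that("motif instances are planted in the configured hypoDMR subset", {
  b <- simulate_dataset(sim_config(seed = 2))
  active <- b$truth$active_tf_ids[1]
  cons <- pwm_consensus(b$pwms[[active]])
  has_inst <- vapply(b$region_seqs, function(s)
    grepl(cons, s, fixed = TRUE) || grepl(revcomp(cons), s, fixed = TRUE),
    TRUE)
  expect_true(all(has_inst[b$truth$motif_hypodmr_ids]))
  # planted instances are rare outside the designated regions
  expect_lt(mean(has_inst[setdiff(names(has_inst),
                                  b$truth$motif_hypodmr_ids)]), 0.05)
})

test_that("configured ATAC overlap holds for true hypoDMRs", {
  b <- simulate_dataset(sim_config(seed = 4))
  hypo <- b$regions[b$regions$name %in% b$truth$true_hypodmr_ids, ]
  class(hypo) <- c("interval_set", "data.frame")
  ov <- intersect_intervals(hypo, b$atac)
  frac <- length(unique(ov$a_idx)) / nrow(hypo)
  expect_gte(frac, 0.9)
})

test_that("null generator (no planted expression effects) is exchangeable", {
  # pooled two-sample p-values approximately uniform across seeds
  ps <- c()
  for (s in 1:5) {
    cfg <- sim_config(seed = s, regulon_log2fc = 0,
                      immune_anticorr_log2fc = 0, tf_activity_sd = 0)
    b <- simulate_dataset(cfg)
    de <- differential_expression(b$expr, b$expr_groups)
    ps <- c(ps, de$p_value)
  }
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("infeasible geometry and invalid configs are rejected", {
  expect_error(sim_config(n_regions = 5000, chrom_length_bp = 1e5),
               "infeasible")
  expect_error(sim_config(hypo_delta = 0), "hypo_delta")
  expect_error(sim_config(planted_motif_fraction = 1.2), "fraction")
  expect_error(sim_config(n_hypodmr_true = 600), "exceeds")
})
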