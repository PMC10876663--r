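test_that("consensus of identical sets is the merged set; disjoint sets are empty", {
  a <- interval_set("chr1", c(10, 15, 100), c(20, 30, 120))
  cons <- consensus_peaks(list(a, a, a))
  expect_equal(as.data.frame(cons)[c("start", "end")],
               as.data.frame(merge_intervals(a))[c("start", "end")])
  b <- interval_set("chr1", 500, 600)
  expect_equal(nrow(consensus_peaks(list(a, b))), 0)
  expect_error(consensus_peaks(list(a)), ">= 2")
})

test_that("three-way consensus matches the manual interval arithmetic", {
  A <- interval_set("chr1", 10, 50, name = "A")
  B <- interval_set("chr1", 30, 70, name = "B")
  C <- interval_set("chr1", 40, 90, name = "C")
  cons <- consensus_peaks(list(A, B, C))
  expect_equal(cons$start, 40)
  expect_equal(cons$end, 50)
  # order-invariance
  cons2 <- consensus_peaks(list(C, A, B))
  expect_equal(as.data.frame(cons), as.data.frame(cons2))
})

test_that("every consensus interval lies inside a merged interval of each input", {
  set.seed(71)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) random_interval_set(15, chrom_len = 2000))
    cons <- consensus_peaks(sets)
    for (s in sets) {
      m <- merge_intervals(s)
      for (i in seq_len(nrow(cons))) {
        inside <- any(m$chrom == cons$chrom[i] & m$start <= cons$start[i] &
                        m$end >= cons$end[i])
        expect_true(inside)
      }
    }
  }
})

test_that("peaks_to_genes respects the distance cutoff and matches brute force", {
  genes <- gene_annotation(c("gA", "gB"), "chr1", c(1000, 60000),
                           c(1500, 60500), c("+", "+"))
  near <- interval_set("chr1", 900, 1000)     # midpoint 950, 50 bp from gA
  far <- interval_set("chr1", 31000, 31100)   # ~30 kb from either gene
  expect_equal(peaks_to_genes(near, genes), "gA")
  expect_equal(peaks_to_genes(far, genes), character())
  set.seed(81)
  for (rep in 1:20) {
    peaks <- random_interval_set(20, chrom_len = 50000)
    g <- gene_annotation(sprintf("G%02d", 1:10), "chr1",
                         sort(sample.int(50000, 10)),
                         51000 + sample.int(100, 10),
                         sample(c("+", "-"), 10, replace = TRUE))
    got <- peaks_to_genes(peaks, g, max_assign_distance = 5000)
    want <- unique(unlist(lapply(seq_len(nrow(peaks)), function(i) {
      mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
      o <- oracle_nearest("chr1", mid, g)
      if (!is.na(o$gene_id) && abs(o$distance) <= 5000) o$gene_id else NULL
    })))
    expect_setequal(got, want)
  }
})

test_that("signature construction is the documented intersection", {
  de <- data.frame(gene_id = sprintf("g%d", 3:8),
                   log2fc = rep(-1, 6), q_value = rep(0.01, 6),
                   stringsAsFactors = FALSE)
  sig <- build_signature(sprintf("g%d", 1:5), de)
  expect_equal(sig$signature, c("g3", "g4", "g5"))
  # disjoint sets give an empty signature with a warning
  de2 <- data.frame(gene_id = "x1", log2fc = -2, q_value = 0.001,
                    stringsAsFactors = FALSE)
  expect_warning(sig2 <- build_signature(c("y1", "y2"), de2), "empty")
  expect_length(sig2$signature, 0)
  # fc_min and q_max thresholds are honored
  de3 <- data.frame(gene_id = c("g1", "g2", "g3"),
                    log2fc = c(-0.2, -2, -2), q_value = c(0.01, 0.5, 0.01),
                    stringsAsFactors = FALSE)
  sig3 <- build_signature(c("g1", "g2", "g3"), de3, fc_min = 0.5, q_max = 0.05)
  expect_equal(sig3$signature, "g3")
  expect_lte(length(sig3$signature),
             min(length(sig3$occupied_genes), length(sig3$down_genes)))
})

test_that("sample scores are zero for constant expression and z-invariant", {
  m <- matrix(16, 4, 6, dimnames = list(sprintf("g%d", 1:4),
                                        sprintf("s%d", 1:6)))
  sc <- score_samples(m, c("g1", "g2"))
  expect_true(all(sc$scores$score == 0))
  # gene-wise affine rescaling on the log scale leaves z-scores unchanged
  set.seed(91)
  m2 <- matrix(2^rnorm(24, 5, 1), 4, 6,
               dimnames = dimnames(m))
  s1 <- score_samples(m2, c("g1", "g3"))$scores$score
  lg <- log2(m2 + 1)
  m3 <- 2^(3 * lg + 2) - 1  # per-gene affine map on the log scale
  s2 <- score_samples(m3, c("g1", "g3"))$scores$score
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("a planted signature shift separates the sample groups", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    genes <- sprintf("g%02d", 1:40)
    sig <- genes[1:10]
    m <- matrix(2^rnorm(40 * 20, 5, 0.5), 40, 20,
                dimnames = list(genes, sprintf("s%02d", 1:20)))
    amp <- sprintf("s%02d", 1:10)
    m[sig, amp] <- m[sig, amp] * 2   # +1 log2 shift on signature genes
    g <- setNames(ifelse(colnames(m) %in% amp, "amplified", "diploid"),
                  colnames(m))
    sc <- score_samples(m, sig, g)
    cmp <- sc$comparison
    diff <- if (cmp$group1 == "amplified") cmp$mean_diff else -cmp$mean_diff
    if (diff > 0 && cmp$p_value < 0.01) hits <- hits + 1
  }
  expect_equal(hits, 20)
})

test_that("signature genes absent from the matrix are dropped with a warning", {
  m <- matrix(2^rnorm(12, 5, 1), 2, 6,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  expect_warning(sc <- score_samples(m, c("g1", "gX")), "absent")
  expect_error(score_samples(m, "gX"), "no signature gene")
})

test_that("stratification partitions correctly and validates the fraction", {
  set.seed(101)
  m <- matrix(2^rnorm(20 * 10, 5, 0.5), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  out <- stratified_pathway_screen(m, "g01", list(P = sprintf("g%02d", 2:5)),
                                   fraction = 0.5, n_perm = 100)
  grp <- out$groups$group
  expect_equal(sum(grp == "high", na.rm = TRUE), 5)
  expect_equal(sum(grp == "low", na.rm = TRUE), 5)
  expect_false(any(is.na(grp)))  # fraction 0.5, even n -> full partition
  v <- m["g01", ]
  expect_true(min(v[out$groups$group == "high"]) >=
                max(v[out$groups$group == "low"]))
  expect_error(stratified_pathway_screen(m, "g01", list(P = "g02"),
                                         fraction = 0.05), ">= 2")
  expect_error(stratified_pathway_screen(m, "nope", list(P = "g02")),
               "stratifier")
})

test_that("a planted anticorrelated program screens negative", {
  b <- simulate_dataset(sim_config(seed = 6))
  tum <- names(b$expr_groups)[b$expr_groups == "tumor"]
  scr <- stratified_pathway_screen(b$expr[, tum], b$truth$active_tf_ids[1],
                                   b$pathways, n_perm = 500, seed = 6)
  row <- scr$gsea[scr$gsea$set_id == "IMMUNE_PROGRAM", ]
  expect_lt(row$nes, 0)
  expect_lt(row$q_fdr, 0.05)
})

test_that("a stratifier independent of all pathways rarely flags sets", {
  flagged <- total <- 0
  for (s in 1:5) {
    set.seed(s + 200)
    m <- matrix(2^rnorm(300 * 20, 5, 0.5), 300, 20,
                dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:20)))
    sets <- lapply(1:6, function(i) sample(rownames(m)[-1], 20))
    names(sets) <- sprintf("S%d", 1:6)
    scr <- stratified_pathway_screen(m, "g001", sets, fraction = 0.3,
                                     n_perm = 200, seed = s)
    flagged <- flagged + sum(scr$gsea$q_fdr < 0.25, na.rm = TRUE)
    total <- total + nrow(scr$gsea)
  }
  expect_lte(flagged / total, 0.10)
})
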