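strong_pwm <- function(id, cons) {
  m <- matrix(0.03, 4, nchar(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
  ch <- strsplit(cons, "")[[1]]
  m[cbind(match(ch, c("A", "C", "G", "T")), seq_along(ch))] <- 0.91
  pwm(id, m)
}

test_that("pwm columns renormalize to 1 and the consensus attains max score", {
  p <- strong_pwm("X", "ACCGTAAC")
  expect_true(all(abs(colSums(p$mat) - 1) < 1e-9))
  hits <- scan_pwm("ACCGTAAC", p)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$offset, 0)
  expect_equal(fwd$score, p$max_score, tolerance = 1e-12)
})

test_that("reverse-complemented consensus hits on '-' at the mirrored offset", {
  p <- strong_pwm("X", "ACCGTAAC")
  s <- paste0(strrep("A", 12), "ACCGTAAC", strrep("A", 10))  # offset 12, len 30
  h1 <- scan_pwm(s, p)
  expect_equal(h1$offset[h1$strand == "+"], 12)
  h2 <- scan_pwm(revcomp(s), p)
  expect_equal(h2$offset[h2$strand == "-"], 30 - 8 - 12)
  expect_equal(h2$score[h2$strand == "-"],
               h1$score[h1$strand == "+"], tolerance = 1e-12)
})

test_that("windows containing N are skipped; bad inputs are rejected", {
  p <- strong_pwm("X", "ACCG")
  h <- scan_pwm("ACCGNACCG", p)
  expect_equal(h$offset[h$strand == "+"], c(0, 5))  # N windows skipped
  expect_equal(nrow(scan_pwm("NNNNNNNN", p)), 0)
  expect_error(scan_pwm("ACGT", p, threshold_frac = 0), "threshold_frac")
  expect_error(scan_pwm("ACGT", p, threshold_frac = 1.1), "threshold_frac")
  expect_error(scan_pwm("AC", p), "shorter")
  expect_error(scan_pwm("ACGU", p), "A/C/G/T/N")
})

test_that("scan matches the exhaustive per-window brute-force oracle", {
  set.seed(13)
  for (rep in 1:30) {
    p <- random_pwm(sprintf("M%02d", rep), len = 6)
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    thr <- sample(c(0.5, 0.7, 0.8), 1)
    got <- scan_pwm(s, p, thr)
    want <- oracle_scan(s, p, thr)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("MEME round trip preserves PWMs", {
  p1 <- strong_pwm("TFA", "ACCGTAAC")
  p2 <- random_pwm("TFB", 5)
  f <- withr::local_tempfile()
  write_meme(list(TFA = p1, TFB = p2), f)
  back <- read_meme(f)
  expect_named(back, c("TFA", "TFB"))
  # written probabilities are rounded to 6 digits and re-pseudocounted on read
  expect_lt(max(abs(back$TFA$mat - p1$mat)), 5e-4)
  expect_lt(max(abs(back$TFB$mat - p2$mat)), 5e-4)
})

test_that("Fisher enrichment p equals the hypergeometric tail", {
  hits <- data.frame(tf_id = "T1",
                     region_id = sprintf("h%02d", 1:10))
  hypo <- sprintf("h%02d", 1:20)
  bg <- sprintf("b%02d", 1:20)
  # balanced 10/10 vs 0/20 table variants, checked against the closed form
  hits2 <- rbind(hits, data.frame(tf_id = "T1",
                                  region_id = sprintf("b%02d", 1:10)))
  r <- motif_enrichment(hits2, hypo, bg)
  expect_equal(r$p_value, oracle_fisher_tail(10, 10, 10, 10), tolerance = 1e-12)
  expect_equal(r$p_value, 0.6238144, tolerance = 1e-6)
  expect_equal(r$odds_ratio, 1)
  # maximal enrichment: 10/0 vs 0/10 -> 1 / choose(20, 10)
  r2 <- motif_enrichment(data.frame(tf_id = "T1", region_id = sprintf("h%02d", 1:10)),
                         sprintf("h%02d", 1:10), sprintf("b%02d", 1:10))
  expect_equal(r2$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # zero hits everywhere: corrected OR, p = 1
  r3 <- motif_enrichment(data.frame(tf_id = character(), region_id = character()),
                         hypo, bg, tf_ids = "T1")
  expect_equal(r3$p_value, 1)
  expect_true(is.finite(r3$odds_ratio))
})

test_that("enrichment input contracts are enforced", {
  h <- data.frame(tf_id = "T1", region_id = "r1")
  expect_error(motif_enrichment(h, c("r1"), character()), "background")
  expect_error(motif_enrichment(h, character(), "r2"), "hypoDMR")
  expect_error(motif_enrichment(h, c("r1", "r2"), c("r2", "r3")), "disjoint")
})

test_that("candidate selection filters and orders as specified", {
  enr <- data.frame(
    tf_id = c("T1", "T2", "T3", "T4", "T5"),
    odds_ratio = c(5, 9, 2, 7, 4),
    p_value = c(0.001, 0.001, 0.002, 0.2, 0.004),
    q_value = c(0.01, 0.01, 0.03, 0.40, 0.04),
    stringsAsFactors = FALSE)
  expr <- matrix(10, 5, 4, dimnames = list(enr$tf_id, c("T01", "T02", "N01", "N02")))
  expr["T5", c("T01", "T02")] <- 2   # fails expr > 5
  g <- setNames(c("tumor", "tumor", "normal", "normal"), colnames(expr))
  out <- select_candidates(enr, expr, g, q_max = 0.05, expr_min = 5, top_k = 2)
  # q filter drops T4, expression drops T5; order: q asc then OR desc -> T2, T1, (T3 cut by top_k)
  expect_equal(out$tf_id, c("T2", "T1"))
  out_all <- select_candidates(enr, expr, g, top_k = 30)
  expect_equal(out_all$tf_id, c("T2", "T1", "T3"))
  none <- select_candidates(enr, expr, g, q_max = 1e-6)
  expect_equal(nrow(none), 0)
})

test_that("null motif enrichment is never anti-conservative", {
  # no planted motifs: exact Fisher tests are conservative under the null
  # (discrete tails), so the rejection fraction at 0.05 must not exceed it
  set.seed(99)
  frac <- replicate(50, {
    n_reg <- 60
    seqs <- setNames(vapply(1:n_reg, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
      ""), sprintf("r%03d", 1:n_reg))
    pwms <- lapply(sprintf("TF%02d", 1:8), random_pwm, len = 6)
    names(pwms) <- sprintf("TF%02d", 1:8)
    hits <- scan_regions(seqs, pwms, threshold_frac = 0.7)
    hypo <- sprintf("r%03d", 1:20)
    bg <- sprintf("r%03d", 21:60)
    enr <- motif_enrichment(hits, hypo, bg, tf_ids = names(pwms))
    mean(enr$p_value <= 0.05)
  })
  expect_lte(mean(frac), 0.07)
})
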