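# Independent brute-force oracles. Deliberately naive, loop-based code paths
# kept separate from the package implementation.

# all-pairs interval overlap
oracle_intersect <- function(a, b, min_overlap_bp = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap_bp)
      out[[length(out) + 1]] <- c(i, j, ov)
  }
  if (length(out) == 0)
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  m <- do.call(rbind, out)
  d <- data.frame(a_idx = m[, 1], b_idx = m[, 2], overlap_bp = m[, 3])
  d[order(d$a_idx, d$b_idx), , drop = FALSE]
}

# argmin over all genes; tie -> lexicographically smaller id (C locale)
oracle_nearest <- function(chrom, mid, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(list(gene_id = NA_character_, distance = NA_integer_))
  d <- abs(g$tss - mid)
  best <- which(d == min(d))
  ids <- sort(g$gene_id[best], method = "radix")
  gid <- ids[1]
  list(gene_id = gid, distance = g$tss[g$gene_id == gid] - mid)
}

# literal single-pass GSEA running-sum walk
oracle_es <- function(ranked, gene_set, p = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  k <- sum(hit)
  stopifnot(k >= 1, k < N)
  w <- abs(ranked$score)^p
  denom <- sum(w[hit])
  if (denom == 0) { w[] <- 1; denom <- k }
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- if (hit[i]) run + w[i] / denom else run - 1 / (N - k)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# explicit hypergeometric upper-tail sum for a 2x2 table (one-sided greater)
oracle_fisher_tail <- function(a, b, c_, d) {
  K <- a + c_   # total with hit
  n <- a + b    # hypo margin
  N <- a + b + c_ + d
  ks <- a:min(K, n)
  sum(stats::dhyper(ks, K, N - K, n))
}

# naive per-window PWM scan, both strands, score by direct product lookup
oracle_scan <- function(sequence, p, threshold_frac = 0.8) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- ncol(p$mat)
  chars <- strsplit(toupper(sequence), "")[[1]]
  thr <- threshold_frac * p$max_score
  hits <- list()
  for (off in seq_len(length(chars) - L + 1)) {
    win <- chars[off:(off + L - 1)]
    if (any(win == "N")) next
    sf <- sum(vapply(seq_len(L), function(j)
      log2(p$mat[win[j], j] / p$background[win[j]]), 0))
    rc <- rev(unname(comp[win]))
    sr <- sum(vapply(seq_len(L), function(j)
      log2(p$mat[rc[j], j] / p$background[rc[j]]), 0))
    if (sf >= thr) hits[[length(hits) + 1]] <-
        data.frame(offset = off - 1L, strand = "+", score = sf)
    if (sr >= thr) hits[[length(hits) + 1]] <-
        data.frame(offset = off - 1L, strand = "-", score = sr)
  }
  if (length(hits) == 0)
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  d <- do.call(rbind, hits)
  d[order(d$offset, d$strand), , drop = FALSE]
}

random_interval_set <- function(n, chrom_len = 10000, chroms = "chr1",
                                max_width = 400) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  interval_set(chrom, start, start + width,
               name = sprintf("iv%04d", seq_len(n)))
}

random_pwm <- function(id, len = 6) {
  m <- matrix(stats::runif(4 * len), 4, len)
  pwm(id, sweep(m, 2, colSums(m), "/"))
}

toy_dir <- function() {
  d <- system.file("extdata", "toy", package = "hypoTF")
  stopifnot(nzchar(d))
  d
}
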