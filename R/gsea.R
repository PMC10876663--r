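#' Ranked gene list for preranked GSEA
#'
#' Genes ordered by descending score (the ranking metric, e.g. tumor/normal
#' log2 fold change); ties are broken by gene id in C locale so the order is
#' deterministic.
#'
#' @param gene_id character vector of unique gene ids.
#' @param score numeric ranking metric, one per gene.
#' @return A `data.frame` of class `ranked_genes` with columns `gene_id`,
#'   `score`, sorted by descending score.
#' @export
ranked_genes <- function(gene_id, score) {
  gene_id <- as.character(gene_id)
  score <- as.numeric(score)
  stopifnot(length(gene_id) == length(score))
  if (anyDuplicated(gene_id)) stop("ranked_genes: duplicate gene ids")
  if (any(is.na(score))) stop("ranked_genes: NA scores not allowed")
  o <- order(-score, gene_id, method = "radix")
  df <- data.frame(gene_id = gene_id[o], score = score[o],
                   stringsAsFactors = FALSE)
  class(df) <- c("ranked_genes", "data.frame")
  df
}

#' GSEA enrichment score of one gene set in a ranked list
#'
#' Walks the ranked list; at a set member ("hit") the running sum increases
#' by `|score|^weight_exponent / sum over hits of |score|^weight_exponent`,
#' at a miss it decreases by `1 / (N - n_hits)`. The enrichment score is the
#' running-sum value of maximal absolute deviation from zero (signed; the
#' earliest extremum on ties). When all hit scores are zero and
#' `weight_exponent > 0`, unweighted (exponent 0) increments are used so the
#' score stays defined.
#'
#' @param ranked a [ranked_genes()] object (the universe).
#' @param gene_set character vector of gene ids; its intersection with the
#'   universe must be non-empty and smaller than the universe.
#' @param weight_exponent hit-weight exponent (GSEA "weighted" = 1, the
#'   default; 0 gives the classic Kolmogorov-Smirnov walk).
#' @return A list with `es`, `running` (length-N running sum), and
#'   `leading_edge` (set members at or before the extremum for positive es;
#'   at or after it for negative es).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_genes"))
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  k <- sum(hit)
  if (k == 0) stop("enrichment_score: gene set does not intersect the universe")
  if (k == N) stop("enrichment_score: gene set covers the whole universe")
  w <- abs(ranked$score)^weight_exponent
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1  # all-zero hit scores: fall back to exponent 0
  inc <- w / sum(w)
  dec <- rep(1 / (N - k), N)
  dec[hit] <- 0
  running <- cumsum(inc - dec)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  le <- if (es >= 0) ranked$gene_id[seq_len(i_max)][hit[seq_len(i_max)]]
  else ranked$gene_id[i_max:N][hit[i_max:N]]
  list(es = es, running = running, leading_edge = le)
}

# ES for many random position sets at once (the permutation null).
# pos: k x n_perm matrix of sorted hit positions; wts: |score|^p over the
# ranked universe. O(k) per permutation: the running-sum extremes occur
# immediately before/after hits.
null_es_matrix <- function(pos, wts, N) {
  k <- nrow(pos)
  W <- matrix(wts[pos], nrow = k)
  sw <- colSums(W)
  zero <- sw == 0
  if (any(zero)) { W[, zero] <- 1; sw[zero] <- k }
  CW <- apply(W, 2, cumsum) / rep(sw, each = k)
  if (k == 1L) CW <- matrix(CW, nrow = 1L)
  miss <- (pos - seq_len(k)) / (N - k)   # misses before each hit
  top <- CW - miss                        # value just after hit j
  bot <- rbind(0, CW[-k, , drop = FALSE]) - miss  # value just before hit j
  hi <- apply(top, 2, max)
  lo <- apply(bot, 2, min)
  ifelse(hi >= -lo, hi, lo)
}

#' Preranked GSEA with permutation significance and FDR
#'
#' For each gene set, computes the enrichment score and a permutation null
#' of `n_perm` random gene sets of the same size drawn uniformly without
#' replacement from the ranked universe. NES is the ES divided by the mean
#' absolute null ES of matching sign; the nominal p-value is
#' `(1 + #same-sign null ES at least as extreme) / (1 + #same-sign null
#' ES)`. The FDR q-value uses the sign-stratified ratio-of-tails estimator
#' over pooled null NES across all sets, clipped to \[0, 1\]. A set with no
#' same-sign null ES gets `NA` NES/p/q and `undefined = TRUE`, never a
#' silent zero.
#'
#' @param ranked a [ranked_genes()] object.
#' @param gene_sets named list of character vectors. Sets with empty
#'   intersection with the universe, or covering it entirely, are dropped
#'   with a warning.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param weight_exponent hit-weight exponent (default 1).
#' @param seed integer seed making the permutation null reproducible.
#' @return A `data.frame` with one row per retained set: `set_id`, `size`
#'   (genes in the universe), `es`, `nes`, `p_nominal`, `q_fdr`,
#'   `leading_edge` (comma-separated), `undefined`.
#' @export
gsea_prerank <- function(ranked, gene_sets, n_perm = 1000,
                         weight_exponent = 1, seed = 1L) {
  stopifnot(inherits(ranked, "ranked_genes"), is.list(gene_sets))
  if (n_perm < 100) stop("gsea_prerank: n_perm must be >= 100")
  N <- nrow(ranked)
  sizes <- vapply(gene_sets, function(s) sum(ranked$gene_id %in% s), 0L)
  drop <- sizes == 0L | sizes >= N
  if (any(drop)) {
    warning("gsea_prerank: dropping sets with empty or full-universe overlap: ",
            paste(names(gene_sets)[drop], collapse = ", "))
    gene_sets <- gene_sets[!drop]
    sizes <- sizes[!drop]
  }
  if (length(gene_sets) == 0)
    return(data.frame(set_id = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_nominal = numeric(),
                      q_fdr = numeric(), leading_edge = character(),
                      undefined = logical(), stringsAsFactors = FALSE))
  wts <- abs(ranked$score)^weight_exponent
  set.seed(as.integer(seed))
  n_sets <- length(gene_sets)
  es <- numeric(n_sets)
  nes <- rep(NA_real_, n_sets)
  p_nom <- rep(NA_real_, n_sets)
  undef <- logical(n_sets)
  le <- character(n_sets)
  null_nes <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    r <- enrichment_score(ranked, gene_sets[[i]], weight_exponent)
    es[i] <- r$es
    le[i] <- paste(r$leading_edge, collapse = ",")
    k <- sizes[i]
    pos <- vapply(seq_len(n_perm),
                  function(j) sort.int(sample.int(N, k)), integer(k))
    if (k == 1L) pos <- matrix(pos, nrow = 1L)
    ne <- null_es_matrix(pos, wts, N)
    pos_mean <- mean(ne[ne > 0])
    neg_mean <- mean(abs(ne[ne < 0]))
    nn <- rep(NA_real_, n_perm)
    nn[ne > 0] <- ne[ne > 0] / pos_mean
    nn[ne < 0] <- ne[ne < 0] / neg_mean
    nn[ne == 0] <- 0
    null_nes[[i]] <- nn
    if (es[i] == 0) { nes[i] <- 0; p_nom[i] <- 1; next }
    same <- if (es[i] > 0) ne[ne > 0] else ne[ne < 0]
    if (length(same) == 0) { undef[i] <- TRUE; next }
    nes[i] <- if (es[i] > 0) es[i] / pos_mean else es[i] / neg_mean
    p_nom[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }
  pool <- unlist(null_nes)
  pool <- pool[!is.na(pool)]
  q <- rep(NA_real_, n_sets)
  obs <- nes[!undef & !is.na(nes)]
  for (i in seq_len(n_sets)) {
    if (undef[i] || is.na(nes[i])) next
    if (nes[i] > 0) {
      denom_null <- sum(pool > 0)
      num_null <- if (denom_null > 0) sum(pool >= nes[i]) / denom_null else 0
      frac_obs <- sum(obs >= nes[i]) / max(sum(obs > 0), 1L)
    } else if (nes[i] < 0) {
      denom_null <- sum(pool < 0)
      num_null <- if (denom_null > 0) sum(pool <= nes[i]) / denom_null else 0
      frac_obs <- sum(obs <= nes[i]) / max(sum(obs < 0), 1L)
    } else { q[i] <- 1; next }
    q[i] <- min(1, max(0, num_null / max(frac_obs, .Machine$double.eps)))
  }
  data.frame(set_id = names(gene_sets), size = as.integer(sizes), es = es,
             nes = nes, p_nominal = p_nom, q_fdr = q, leading_edge = le,
             undefined = undef, stringsAsFactors = FALSE)
}
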