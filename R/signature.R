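#' Consensus peaks shared by every input peak set
#'
#' Each input set is first merged (overlapping intervals collapsed); a
#' consensus interval is then a maximal region simultaneously covered by at
#' least one interval from EVERY input set (n-way intersection of the
#' merged sets). Order of arguments does not matter.
#'
#' @param peak_sets list of >= 2 [interval_set()] objects.
#' @return An [interval_set()] of consensus intervals.
#' @export
consensus_peaks <- function(peak_sets) {
  if (!is.list(peak_sets) || length(peak_sets) < 2)
    stop("consensus_peaks: need >= 2 peak sets")
  merged <- lapply(peak_sets, function(x) {
    stopifnot(is_interval_set(x))
    if (nrow(x) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(as_granges(x), ignore.strand = TRUE)
  })
  cons <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), merged)
  cons <- GenomicRanges::reduce(cons)
  if (length(cons) == 0) return(interval_set())
  granges_to_intervals(cons)
}

#' Map peaks to occupied genes
#'
#' Each peak is assigned to its nearest gene (midpoint to TSS, ties by gene
#' id) when the absolute distance is within `max_assign_distance`; the
#' occupied gene set is the union over peaks.
#'
#' @param peaks an [interval_set()].
#' @param genes gene annotation ([gene_annotation()]).
#' @param max_assign_distance maximum |midpoint - TSS| in bp (default
#'   25000).
#' @return Sorted character vector of occupied gene ids.
#' @export
peaks_to_genes <- function(peaks, genes, max_assign_distance = 25000) {
  stopifnot(is_interval_set(peaks))
  if (nrow(genes) == 0) stop("peaks_to_genes: empty gene annotation")
  if (nrow(peaks) == 0) return(character())
  ng <- nearest_genes(peaks, genes)
  keep <- !is.na(ng$gene_id) & abs(ng$distance) <= max_assign_distance
  sort(unique(ng$gene_id[keep]), method = "radix")
}

#' Build a TF-activity signature
#'
#' The signature is the intersection of TF-occupied genes (from consensus
#' ChIP peaks) with genes downregulated upon TF knockdown: `log2fc <
#' -fc_min` and `q <= q_max` in a knockdown-versus-control contrast
#' (knockdown as group 1, so downregulation is negative).
#'
#' @param occupied character vector of occupied gene ids.
#' @param de knockdown-vs-control table from [differential_expression()].
#' @param fc_min minimum |log2fc| decrease (default 0: any decrease).
#' @param q_max BH FDR ceiling for downregulation (default 0.05).
#' @return A list of class `signature_spec`: `occupied_genes`,
#'   `down_genes`, `signature` (sorted intersection).
#' @export
build_signature <- function(occupied, de, fc_min = 0, q_max = 0.05) {
  down <- de$gene_id[!is.na(de$q_value) & de$log2fc < -fc_min &
                       de$q_value <= q_max]
  sig <- sort(intersect(occupied, down), method = "radix")
  if (length(sig) == 0)
    warning("build_signature: empty signature (occupied and downregulated sets do not intersect)")
  structure(list(occupied_genes = sort(unique(occupied), method = "radix"),
                 down_genes = sort(unique(down), method = "radix"),
                 signature = sig),
            class = "signature_spec")
}

#' @export
print.signature_spec <- function(x, ...) {
  cat(sprintf("signature_spec: %d occupied, %d downregulated, %d in signature\n",
              length(x$occupied_genes), length(x$down_genes),
              length(x$signature)))
  invisible(x)
}

#' Score samples by mean signature z-score
#'
#' Expression is log2(x + 1)-transformed, each signature gene is z-scored
#' across samples (zero-variance genes get z = 0), and each sample's score
#' is the mean z over signature genes. When two group labels are supplied a
#' Welch t comparison of scores between the groups is reported.
#'
#' @param expr expression matrix, genes x samples.
#' @param signature character vector of signature gene ids; genes missing
#'   from the matrix are dropped with a warning.
#' @param groups optional named group labels per sample (exactly two
#'   distinct labels for the comparison).
#' @return A list with `scores` (`data.frame`: `sample_id`, `score`,
#'   `group`) and, when groups are given, `comparison` (`group1`, `group2`,
#'   `mean_diff`, `p_value`).
#' @export
score_samples <- function(expr, signature, groups = NULL) {
  stopifnot(is.matrix(expr))
  present <- signature %in% rownames(expr)
  if (!any(present)) stop("score_samples: no signature gene present in expr")
  if (any(!present))
    warning("score_samples: dropping signature genes absent from matrix: ",
            paste(signature[!present], collapse = ", "))
  m <- log2(expr[signature[present], , drop = FALSE] + 1)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  score <- colMeans(z)
  grp <- if (is.null(groups)) rep(NA_character_, ncol(expr))
  else unname(groups[colnames(expr)])
  out <- list(scores = data.frame(sample_id = colnames(expr), score = score,
                                  group = grp, stringsAsFactors = FALSE,
                                  row.names = NULL))
  if (!is.null(groups)) {
    labs <- sort(unique(grp[!is.na(grp)]), method = "radix")
    if (length(labs) == 2) {
      w <- welch_rows(matrix(score, 1, dimnames = list("s", names(score))),
                      which(grp == labs[1] & !is.na(grp)),
                      which(grp == labs[2] & !is.na(grp)))
      out$comparison <- data.frame(group1 = labs[1], group2 = labs[2],
                                   mean_diff = w$delta[1],
                                   p_value = w$p[1],
                                   stringsAsFactors = FALSE)
    }
  }
  out
}

#' Expression-stratified pathway screen
#'
#' Samples are ranked by the stratifier gene's expression; the top and
#' bottom `floor(fraction * n)` samples (ties broken by sample id) form the
#' high and low groups. Differential expression (high vs low) provides the
#' ranked list, and every pathway set is tested by preranked GSEA -- a
#' volcano-ready (NES, q) table. Pathways tracking the stratifier
#' positively get NES > 0; anticorrelated programs get NES < 0.
#'
#' @param expr expression matrix, genes x samples (typically tumor samples
#'   only).
#' @param stratifier_gene gene id used to stratify samples.
#' @param pathways named list of pathway gene sets (GMT-style).
#' @param fraction tail fraction in (0, 0.5] (default 0.30, i.e. top/bottom
#'   30%).
#' @param n_perm,weight_exponent,seed passed to [gsea_prerank()].
#' @return A list with `groups` (`data.frame`: `sample_id`, `group` in
#'   high/low/NA), `de` (high-vs-low table) and `gsea` (the screen table).
#' @export
stratified_pathway_screen <- function(expr, stratifier_gene, pathways,
                                      fraction = 0.30, n_perm = 1000,
                                      weight_exponent = 1, seed = 1L) {
  stopifnot(is.matrix(expr))
  if (!stratifier_gene %in% rownames(expr))
    stop("stratified_pathway_screen: stratifier gene not in matrix")
  if (fraction <= 0 || fraction > 0.5)
    stop("stratified_pathway_screen: fraction must be in (0, 0.5]")
  n <- ncol(expr)
  n_g <- floor(fraction * n)
  if (n_g < 2)
    stop("stratified_pathway_screen: floor(fraction * n) must be >= 2")
  v <- expr[stratifier_gene, ]
  o <- order(-v, colnames(expr), method = "radix")
  grp <- rep(NA_character_, n)
  names(grp) <- colnames(expr)
  grp[o[seq_len(n_g)]] <- "high"
  grp[o[(n - n_g + 1):n]] <- "low"
  de <- differential_expression(expr[, !is.na(grp), drop = FALSE],
                                grp[!is.na(grp)],
                                group1 = "high", group2 = "low")
  gs <- gsea_prerank(de_ranking(de), pathways, n_perm = n_perm,
                     weight_exponent = weight_exponent, seed = seed)
  list(groups = data.frame(sample_id = colnames(expr), group = unname(grp),
                           stringsAsFactors = FALSE),
       de = de, gsea = gs)
}
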