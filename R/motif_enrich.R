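#' One-sided Fisher exact p-value for a 2x2 table (enrichment direction)
#'
#' `p = P(X >= a)` for `X ~ Hypergeom` with the table's margins -- the exact
#' alternative = "greater" Fisher test on the table
#' `rbind(c(a, b), c(c, d))`. Vectorized over table cells.
#'
#' @param a,b,c_,d table cells: hypo-with-hit, hypo-without, background-with,
#'   background-without.
#' @return Numeric vector of p-values.
#' @export
fisher_p_greater <- function(a, b, c_, d) {
  stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}

#' Per-TF motif enrichment in hypoDMRs versus background regions
#'
#' For each TF, builds the 2x2 table of regions (hypoDMR vs background) by
#' motif-hit presence/absence and tests enrichment with the one-sided Fisher
#' exact test (alternative: greater), computed as the hypergeometric tail.
#' The odds ratio is the sample odds ratio with a Haldane-Anscombe 0.5
#' correction applied to all cells when any cell is zero. q-values are BH
#' across TFs.
#'
#' @param hits data.frame of motif hits from [scan_regions()] (columns
#'   `tf_id`, `region_id`; other columns ignored).
#' @param hypo_ids character vector of hypoDMR region ids.
#' @param background_ids character vector of background (non-DMR) region
#'   ids; must be disjoint from `hypo_ids` and non-empty.
#' @param tf_ids TFs to report (default: all TFs present in `hits`).
#' @return A `data.frame` with one row per TF: `tf_id`, `n_hypo_with_hit`,
#'   `n_hypo`, `n_bg_with_hit`, `n_bg`, `odds_ratio`, `p_value`, `q_value`,
#'   sorted by (q, p, tf_id).
#' @export
motif_enrichment <- function(hits, hypo_ids, background_ids,
                             tf_ids = sort(unique(hits$tf_id))) {
  if (length(background_ids) == 0)
    stop("motif_enrichment: empty background; supply non-DMR regions")
  if (length(hypo_ids) == 0)
    stop("motif_enrichment: empty hypoDMR set")
  if (length(intersect(hypo_ids, background_ids)) > 0)
    stop("motif_enrichment: hypo and background region sets must be disjoint")
  n_hypo <- length(hypo_ids)
  n_bg <- length(background_ids)
  rows <- lapply(tf_ids, function(tf) {
    hr <- unique(hits$region_id[hits$tf_id == tf])
    a <- sum(hypo_ids %in% hr)        # hypo with hit
    c_ <- sum(background_ids %in% hr) # background with hit
    b <- n_hypo - a
    d <- n_bg - c_
    or <- if (any(c(a, b, c_, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    p <- fisher_p_greater(a, b, c_, d)
    data.frame(tf_id = tf, n_hypo_with_hit = a, n_hypo = n_hypo,
               n_bg_with_hit = c_, n_bg = n_bg, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf_id = character(), n_hypo_with_hit = integer(),
                      n_hypo = integer(), n_bg_with_hit = integer(),
                      n_bg = integer(), odds_ratio = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  o <- order(out$q_value, out$p_value, out$tf_id, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter and order candidate TFs
#'
#' Retains TFs with enrichment `q <= q_max` and tumor-group mean expression
#' `> expr_min`, orders them by ascending q then descending odds ratio
#' (ties by TF id), and truncates to the top `top_k` (defaults follow the
#' common practice of keeping the top 30 TFs at q < 0.05 with mean tumor
#' expression above 5).
#'
#' @param enrichment data.frame from [motif_enrichment()].
#' @param expr expression matrix (genes x samples) containing one row per
#'   TF id; TFs missing from the matrix are flagged and dropped.
#' @param groups named group labels per sample (`"tumor"` / `"normal"`).
#' @param q_max enrichment FDR ceiling (default 0.05).
#' @param expr_min minimum tumor-group mean expression (default 5).
#' @param top_k maximum number of candidates kept (default 30).
#' @return The filtered, ordered `data.frame` with an added
#'   `mean_expression` column (tumor-group mean).
#' @export
select_candidates <- function(enrichment, expr, groups,
                              q_max = 0.05, expr_min = 5, top_k = 30) {
  stopifnot(is.matrix(expr))
  groups <- groups[colnames(expr)]
  tum <- which(groups == "tumor")
  if (length(tum) == 0) stop("select_candidates: no tumor samples in expr")
  present <- enrichment$tf_id %in% rownames(expr)
  if (any(!present))
    warning("select_candidates: TFs missing from expression matrix: ",
            paste(enrichment$tf_id[!present], collapse = ", "))
  out <- enrichment[present, , drop = FALSE]
  out$mean_expression <-
    rowMeans(expr[out$tf_id, tum, drop = FALSE], na.rm = TRUE)
  out <- out[out$q_value <= q_max & out$mean_expression > expr_min, ,
             drop = FALSE]
  o <- order(out$q_value, -out$odds_ratio, out$tf_id, method = "radix")
  out <- out[o, , drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}
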