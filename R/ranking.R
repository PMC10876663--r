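#' Assemble the TF prioritization report
#'
#' One row per candidate TF: motif-enrichment statistics, inferred target
#' set size, preranked-GSEA NES and FDR of the target set in the
#' tumor-versus-normal ranking, and the TF's own expression fold change.
#' TFs with `q_fdr <= nes_q_max` and `tf_log2fc > 0` are eligible and
#' ranked by descending NES, then descending TF fold change, then TF id;
#' `combined_rank` is 1..n over eligible TFs and `NA` otherwise. The full
#' table is returned regardless so users can re-rank.
#'
#' @param candidates data.frame from [select_candidates()].
#' @param target_sets named list of `target_set` objects (one per candidate;
#'   TFs with empty target sets are reported with `NA` GSEA fields).
#' @param gsea data.frame from [gsea_prerank()] keyed by `set_id` = TF id.
#' @param de differential-expression table from
#'   [differential_expression()] (tumor vs normal), providing `tf_log2fc`.
#' @param nes_q_max GSEA FDR gate for eligibility (default 0.25, GSEA's
#'   conventional exploratory threshold).
#' @return A `data.frame` (`tf_report`) sorted eligible-first by
#'   `combined_rank`, with columns `tf_id`, `odds_ratio`, `enrich_q`,
#'   `n_targets`, `es`, `nes`, `gsea_q`, `tf_log2fc`, `tf_fc`,
#'   `combined_rank`.
#' @export
rank_tfs <- function(candidates, target_sets, gsea, de, nes_q_max = 0.25) {
  cols <- c("tf_id", "odds_ratio", "enrich_q", "n_targets", "es", "nes",
            "gsea_q", "tf_log2fc", "tf_fc", "combined_rank")
  if (nrow(candidates) == 0) {
    out <- data.frame(tf_id = character(), odds_ratio = numeric(),
                      enrich_q = numeric(), n_targets = integer(),
                      es = numeric(), nes = numeric(), gsea_q = numeric(),
                      tf_log2fc = numeric(), tf_fc = numeric(),
                      combined_rank = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  de_fc <- stats::setNames(de$log2fc, de$gene_id)
  n_targets <- vapply(candidates$tf_id, function(tf) {
    ts <- target_sets[[tf]]
    if (is.null(ts)) 0L else length(ts$gene_ids)
  }, 0L)
  gi <- match(candidates$tf_id, gsea$set_id)
  out <- data.frame(
    tf_id = candidates$tf_id,
    odds_ratio = candidates$odds_ratio,
    enrich_q = candidates$q_value,
    n_targets = n_targets,
    es = gsea$es[gi],
    nes = gsea$nes[gi],
    gsea_q = gsea$q_fdr[gi],
    tf_log2fc = unname(de_fc[candidates$tf_id]),
    stringsAsFactors = FALSE)
  out$tf_fc <- 2^out$tf_log2fc
  eligible <- !is.na(out$nes) & !is.na(out$gsea_q) &
    out$gsea_q <= nes_q_max & !is.na(out$tf_log2fc) & out$tf_log2fc > 0
  out$combined_rank <- NA_integer_
  if (any(eligible)) {
    e <- which(eligible)
    o <- e[order(-out$nes[e], -out$tf_log2fc[e], out$tf_id[e],
                 method = "radix")]
    out$combined_rank[o] <- seq_along(o)
  }
  o <- order(out$combined_rank, out$enrich_q, out$tf_id, method = "radix",
             na.last = TRUE)
  out <- out[o, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}
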