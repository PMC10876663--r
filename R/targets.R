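#' Infer a TF's target genes from motif-bearing, accessible hypoDMRs
#'
#' A hypoDMR qualifies for a TF when it carries at least one motif hit for
#' that TF AND overlaps at least one open-chromatin (ATAC) peak by
#' `min_overlap_bp`. Each qualifying hypoDMR contributes its nearest gene
#' (midpoint-to-TSS); the target set is the deduplicated union. The filter
#' is conjunctive, so an empty ATAC set yields an empty target set with a
#' warning rather than an error.
#'
#' @param tf TF id to look up in `hits`.
#' @param hypo an [interval_set()] of hypoDMRs with region ids in `name`.
#' @param hits motif-hit `data.frame` from [scan_regions()] (`tf_id`,
#'   `region_id`).
#' @param atac an [interval_set()] of open-chromatin peaks.
#' @param genes gene annotation ([gene_annotation()]).
#' @param min_overlap_bp minimum hypoDMR/ATAC overlap in bp (default 1).
#' @param max_link_distance maximum |midpoint - TSS| distance in bp for a
#'   hypoDMR to be linked to its nearest gene (default `Inf`, no cap).
#' @return A list of class `target_set`: `tf_id`, `gene_ids` (sorted unique
#'   character vector) and `provenance`, a `data.frame` with one row per
#'   qualifying hypoDMR (`region_id`, `gene_id`, `distance`,
#'   `n_motif_hits`, `n_atac_peaks`).
#' @export
infer_targets <- function(tf, hypo, hits, atac, genes,
                          min_overlap_bp = 1L, max_link_distance = Inf) {
  stopifnot(is_interval_set(hypo), is_interval_set(atac))
  if (nrow(genes) == 0) stop("infer_targets: empty gene annotation")
  prov0 <- data.frame(region_id = character(), gene_id = character(),
                      distance = integer(), n_motif_hits = integer(),
                      n_atac_peaks = integer(), stringsAsFactors = FALSE)
  empty <- structure(list(tf_id = tf, gene_ids = character(),
                          provenance = prov0), class = "target_set")
  if (nrow(hypo) == 0) return(empty)
  tf_hits <- hits[hits$tf_id == tf, , drop = FALSE]
  hit_counts <- table(tf_hits$region_id)
  if (nrow(atac) == 0) {
    warning("infer_targets: empty ATAC set; conjunctive filter yields no targets")
    return(empty)
  }
  ov <- intersect_intervals(hypo, atac, min_overlap_bp = min_overlap_bp)
  atac_counts <- table(hypo$name[ov$a_idx])
  qual <- hypo$name %in% names(hit_counts) & hypo$name %in% names(atac_counts)
  if (!any(qual)) return(empty)
  qh <- hypo[qual, , drop = FALSE]
  class(qh) <- c("interval_set", "data.frame")
  ng <- nearest_genes(qh, genes)
  keep <- !is.na(ng$gene_id) & abs(ng$distance) <= max_link_distance
  prov <- data.frame(region_id = qh$name[keep], gene_id = ng$gene_id[keep],
                     distance = ng$distance[keep],
                     n_motif_hits = as.integer(hit_counts[qh$name[keep]]),
                     n_atac_peaks = as.integer(atac_counts[qh$name[keep]]),
                     stringsAsFactors = FALSE)
  rownames(prov) <- NULL
  structure(list(tf_id = tf,
                 gene_ids = sort(unique(prov$gene_id), method = "radix"),
                 provenance = prov),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set for %s: %d gene(s) from %d qualifying hypoDMR(s)\n",
              x$tf_id, length(x$gene_ids), nrow(x$provenance)))
  invisible(x)
}
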