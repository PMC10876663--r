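#' Pipeline configuration
#'
#' All stage parameters with their defaults, validated on construction.
#' Unknown keys are rejected. The thresholds mirror the analysis defaults:
#' candidate TFs kept at enrichment q < 0.05 with mean tumor expression
#' above 5 (top 30), samples stratified at the top/bottom 30%.
#'
#' @param ... overrides of the defaults: `delta_min` (0.2), `q_max` (0.05),
#'   `threshold_frac` (0.8), `expr_min` (5), `top_k` (30),
#'   `min_overlap_bp` (1), `max_link_distance` (Inf), `weight_exponent`
#'   (1), `n_perm` (1000), `nes_q_max` (0.25), `fraction` (0.30),
#'   `max_assign_distance` (25000), `sig_fc_min` (0), `sig_q_max` (0.05),
#'   `seed` (1).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(delta_min = 0.2, q_max = 0.05, threshold_frac = 0.8,
              expr_min = 5, top_k = 30, min_overlap_bp = 1L,
              max_link_distance = Inf, weight_exponent = 1,
              n_perm = 1000L, nes_q_max = 0.25, fraction = 0.30,
              max_assign_distance = 25000, sig_fc_min = 0,
              sig_q_max = 0.05, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$delta_min > 0, cfg$q_max > 0, cfg$q_max <= 1,
            cfg$threshold_frac > 0, cfg$threshold_frac <= 1,
            cfg$top_k >= 1, cfg$min_overlap_bp >= 1,
            cfg$n_perm >= 100, cfg$fraction > 0, cfg$fraction <= 0.5)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline config as flat key = value text
#'
#' @param path file path (`key = value` per line; `#` comments allowed).
#' @return `read_pipeline_config()`: a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2))
    stop("read_pipeline_config: expected 'key = value' lines")
  vals <- lapply(kv, function(x) {
    v <- utils::type.convert(x[2], as.is = TRUE)
    if (identical(x[2], "Inf")) v <- Inf
    v
  })
  names(vals) <- vapply(kv, `[[`, "", 1L)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE), "")),
             path)
  invisible(path)
}

#' Run the full TF-prioritization pipeline
#'
#' Executes the stages in dependency order on a fixture bundle (an input
#' directory readable by [read_bundle()], or an in-memory bundle from
#' [simulate_dataset()]): hypoDMR calling, motif scanning, per-TF motif
#' enrichment against the tested non-hypo background, tumor-vs-normal
#' differential expression, candidate selection, target inference,
#' preranked GSEA of each candidate's target set, and TF ranking. When ChIP
#' peak sets plus knockdown expression are present the signature stage runs
#' (consensus peaks, occupied genes, signature, sample scoring); when
#' pathway sets are present and a top TF exists, the expression-stratified
#' pathway screen runs on the tumor samples. Given identical inputs,
#' config and seed, all outputs are byte-identical across runs.
#'
#' @param input a directory path or a bundle list.
#' @param out_dir optional output directory; when given, stage outputs are
#'   written under `dmr/`, `enrichment/`, `targets/`, `gsea/`,
#'   `signature/`, `screen/`, plus `tf_report.tsv`, `resolved_config.txt`
#'   and `run.log`. Must be empty unless `force = TRUE`.
#' @param config a [pipeline_config()].
#' @param force overwrite a non-empty `out_dir`.
#' @return A list of stage results: `dmr`, `hypo_ids`, `background_ids`,
#'   `hits`, `enrichment`, `de`, `candidates`, `target_sets`, `gsea`,
#'   `tf_report`, and (when inputs allow) `signature`, `scores`, `screen`.
#' @export
run_pipeline <- function(input, out_dir = NULL, config = pipeline_config(),
                         force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- if (is.character(input)) read_bundle(input) else input
  log_lines <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    invisible(msg)
  }
  note("hypoTF pipeline, package version %s",
       as.character(utils::packageVersion("hypoTF")))
  note("parameters: %s",
       paste(sprintf("%s=%s", names(config),
                     vapply(config, function(v) format(v), "")),
             collapse = " "))

  ## stage: hypoDMR calling ------------------------------------------------
  dmr <- call_hypodmrs(bundle$beta, bundle$beta_groups,
                       delta_min = config$delta_min, q_max = config$q_max)
  hypo_ids <- dmr$region_id[dmr$is_hypo]
  background_ids <- dmr$region_id[dmr$tested & !dmr$is_hypo]
  note("call-dmrs: %d regions, %d hypoDMRs, %d background",
       nrow(dmr), length(hypo_ids), length(background_ids))

  ## stage: motif scan + enrichment ---------------------------------------
  hits <- scan_regions(bundle$region_seqs, bundle$pwms,
                       threshold_frac = config$threshold_frac)
  note("scan-motifs: %d hits over %d motifs", nrow(hits), length(bundle$pwms))
  res <- list(dmr = dmr, hypo_ids = hypo_ids,
              background_ids = background_ids, hits = hits)
  empty_report <- rank_tfs(
    candidates = data.frame(tf_id = character(), odds_ratio = numeric(),
                            q_value = numeric(), stringsAsFactors = FALSE)[0, ],
    target_sets = list(),
    gsea = data.frame(set_id = character(), es = numeric(), nes = numeric(),
                      q_fdr = numeric(), stringsAsFactors = FALSE),
    de = data.frame(gene_id = character(), log2fc = numeric(),
                    stringsAsFactors = FALSE))
  if (length(hypo_ids) == 0) {
    note("enrich-motifs: no hypoDMRs; emitting empty candidate list")
    res$enrichment <- NULL
    res$candidates <- NULL
    res$tf_report <- empty_report
    finish_pipeline(res, bundle, config, out_dir, force, log_lines)
    return(res)
  }
  enr <- motif_enrichment(hits, hypo_ids, background_ids,
                          tf_ids = sort(names(bundle$pwms), method = "radix"))
  note("enrich-motifs: %d TFs tested", nrow(enr))

  ## stage: differential expression + candidates --------------------------
  de <- differential_expression(bundle$expr, bundle$expr_groups)
  cand <- select_candidates(enr, bundle$expr, bundle$expr_groups,
                            q_max = config$q_max, expr_min = config$expr_min,
                            top_k = config$top_k)
  note("select-candidates: %d candidate TFs", nrow(cand))
  res$enrichment <- enr
  res$de <- de
  res$candidates <- cand
  if (nrow(cand) == 0) {
    res$tf_report <- empty_report
    finish_pipeline(res, bundle, config, out_dir, force, log_lines)
    return(res)
  }

  ## stage: target inference + GSEA + ranking ------------------------------
  hypo_set <- bundle$regions[bundle$regions$name %in% hypo_ids, , drop = FALSE]
  class(hypo_set) <- c("interval_set", "data.frame")
  target_sets <- lapply(cand$tf_id, function(tf)
    infer_targets(tf, hypo_set, hits, bundle$atac, bundle$genes,
                  min_overlap_bp = config$min_overlap_bp,
                  max_link_distance = config$max_link_distance))
  names(target_sets) <- cand$tf_id
  sets <- lapply(target_sets, `[[`, "gene_ids")
  nonempty <- lengths(sets) > 0
  note("infer-targets: %d/%d candidates with non-empty target sets",
       sum(nonempty), length(sets))
  ranked <- de_ranking(de)
  gs <- if (any(nonempty))
    gsea_prerank(ranked, sets[nonempty], n_perm = config$n_perm,
                 weight_exponent = config$weight_exponent,
                 seed = config$seed)
  else data.frame(set_id = character(), size = integer(), es = numeric(),
                  nes = numeric(), p_nominal = numeric(), q_fdr = numeric(),
                  leading_edge = character(), undefined = logical(),
                  stringsAsFactors = FALSE)
  report <- rank_tfs(cand, target_sets, gs, de, nes_q_max = config$nes_q_max)
  note("rank-tfs: top TF %s",
       if (any(!is.na(report$combined_rank)))
         report$tf_id[which(report$combined_rank == 1)] else "<none>")
  res$target_sets <- target_sets
  res$gsea <- gs
  res$tf_report <- report

  ## stage: signature (needs ChIP + knockdown inputs) ----------------------
  if (!is.null(bundle$chip_sets) && length(bundle$chip_sets) >= 2 &&
      !is.null(bundle$kd_expr)) {
    cons <- consensus_peaks(bundle$chip_sets)
    occupied <- peaks_to_genes(cons, bundle$genes,
                               max_assign_distance = config$max_assign_distance)
    kd_de <- differential_expression(bundle$kd_expr, bundle$kd_groups,
                                     group1 = "knockdown", group2 = "control")
    sig <- build_signature(occupied, kd_de, fc_min = config$sig_fc_min,
                           q_max = config$sig_q_max)
    res$consensus <- cons
    res$kd_de <- kd_de
    res$signature <- sig
    note("build-signature: %d consensus peaks, %d occupied, %d signature genes",
         nrow(cons), length(occupied), length(sig$signature))
    if (length(sig$signature) > 0) {
      res$scores <- score_samples(bundle$expr, sig$signature,
                                  bundle$expr_groups)
      note("score-signature: %d samples scored", nrow(res$scores$scores))
    }
  }

  ## stage: stratified pathway screen (tumor samples) ----------------------
  top_tf <- if (any(!is.na(report$combined_rank)))
    report$tf_id[which(report$combined_rank == 1)] else NULL
  if (!is.null(bundle$pathways) && !is.null(top_tf) &&
      top_tf %in% rownames(bundle$expr)) {
    tum <- names(bundle$expr_groups)[bundle$expr_groups == "tumor"]
    scr <- stratified_pathway_screen(
      bundle$expr[, tum, drop = FALSE], top_tf, bundle$pathways,
      fraction = config$fraction, n_perm = config$n_perm,
      weight_exponent = config$weight_exponent, seed = config$seed)
    res$screen <- scr
    note("stratify-screen: stratifier %s, %d pathway sets", top_tf,
         nrow(scr$gsea))
  }
  finish_pipeline(res, bundle, config, out_dir, force, log_lines)
  res
}

finish_pipeline <- function(res, bundle, config, out_dir, force, log_lines) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("run_pipeline: out_dir is not empty (use force = TRUE)")
  sub <- function(d) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
    file.path(out_dir, d)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(res$dmr, file.path(sub("dmr"), "dmr_table.tsv"))
  hypo_set <- bundle$regions[bundle$regions$name %in% res$hypo_ids, ,
                             drop = FALSE]
  class(hypo_set) <- c("interval_set", "data.frame")
  write_bed(hypo_set, file.path(sub("dmr"), "hypodmrs.bed"))
  if (!is.null(res$hits))
    write_tsv_table(res$hits, file.path(sub("enrichment"), "motif_hits.tsv"))
  if (!is.null(res$enrichment))
    write_tsv_table(res$enrichment,
                    file.path(sub("enrichment"), "tf_enrichment.tsv"))
  if (!is.null(res$de))
    write_tsv_table(res$de, file.path(sub("gsea"), "differential_expression.tsv"))
  if (!is.null(res$target_sets) && length(res$target_sets)) {
    sets <- lapply(res$target_sets, `[[`, "gene_ids")
    keep <- lengths(sets) > 0
    if (any(keep))
      write_gmt(sets[keep], file.path(sub("targets"), "target_sets.gmt"))
    prov <- do.call(rbind, lapply(res$target_sets, function(ts)
      if (nrow(ts$provenance))
        cbind(data.frame(tf_id = ts$tf_id, stringsAsFactors = FALSE),
              ts$provenance)))
    if (!is.null(prov))
      write_tsv_table(prov, file.path(sub("targets"), "provenance.tsv"))
  }
  if (!is.null(res$gsea))
    write_tsv_table(res$gsea, file.path(sub("gsea"), "target_gsea.tsv"))
  write_tsv_table(res$tf_report, file.path(out_dir, "tf_report.tsv"))
  if (!is.null(res$signature)) {
    d <- sub("signature")
    write_bed(res$consensus, file.path(d, "consensus_peaks.bed"))
    if (length(res$signature$signature) > 0)
      write_gmt(list(signature = res$signature$signature),
                file.path(d, "signature.gmt"))
    writeLines(res$signature$occupied_genes, file.path(d, "occupied_genes.txt"))
    write_tsv_table(res$kd_de, file.path(d, "knockdown_de.tsv"))
    if (!is.null(res$scores)) {
      write_tsv_table(res$scores$scores, file.path(d, "sample_scores.tsv"))
      if (!is.null(res$scores$comparison))
        write_tsv_table(res$scores$comparison,
                        file.path(d, "score_comparison.tsv"))
    }
  }
  if (!is.null(res$screen)) {
    d <- sub("screen")
    write_tsv_table(res$screen$groups, file.path(d, "strata.tsv"))
    write_tsv_table(res$screen$de, file.path(d, "stratified_de.tsv"))
    write_tsv_table(res$screen$gsea, file.path(d, "pathway_screen.tsv"))
  }
  write_pipeline_config(config, file.path(out_dir, "resolved_config.txt"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
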