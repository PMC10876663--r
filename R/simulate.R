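#' Simulation configuration with planted ground truth
#'
#' Defines the default study conditions for the synthetic benchmark: paired
#' tumor/normal beta values with planted hypomethylated regions, motif
#' instances planted inside a subset of the true hypoDMRs, ATAC and ChIP
#' peak sets with controlled overlap, and tumor/normal expression with a
#' planted TF regulon and a planted anticorrelated immune-like program.
#'
#' The motif-bearing and ATAC-overlapping subsets of the true hypoDMRs are
#' drawn nested from a single shuffled order, so the set of fully
#' qualifying hypoDMRs (motif AND open chromatin) has deterministic size
#' `min(planted_motif_fraction, atac_overlap_fraction) * n_hypodmr_true`,
#' capped at `regulon_size`. The planted regulon is the set of nearest
#' genes of those qualifying regions. The active TF is up-shifted in tumors
#' by `regulon_log2fc` plus a per-tumor-sample activity term
#' (`tf_activity_sd`); immune-program genes are shifted opposite in sign to
#' that activity, planting the anticorrelation the stratified screen is
#' meant to detect.
#'
#' @param seed integer RNG seed; the same seed reproduces every fixture
#'   byte-identically.
#' @param n_chrom,chrom_length_bp genome geometry.
#' @param n_genes,n_regions,region_width_bp counts and region width (bp).
#' @param n_hypodmr_true planted hypoDMR count.
#' @param n_tumor,n_normal sample counts per group.
#' @param beta_noise_sd beta-value noise sd; `hypo_delta` planted beta drop.
#' @param n_tfs number of TF motifs (1 active + decoys);
#'   `active_tf_ids` the planted TF(s); `motif_length` motif width.
#' @param planted_motif_fraction fraction of true hypoDMRs carrying the
#'   active TF's consensus; `atac_overlap_fraction` fraction overlapping an
#'   ATAC peak; `atac_background_fraction` ATAC rate among other regions.
#' @param regulon_size cap on qualifying hypoDMRs wired to the active TF.
#' @param regulon_log2fc planted tumor up-shift of regulon genes and the TF.
#' @param tf_activity_sd sd of the per-tumor-sample TF activity (log2).
#' @param immune_program_size,immune_anticorr_log2fc anticorrelated program.
#' @param expr_noise_sd log2 expression noise sd (patient samples).
#' @param n_chip_lines ChIP-seq "cell line" peak sets sharing the regulon
#'   loci; `n_chip_extra` line-specific extra peaks per line.
#' @param n_kd knockdown/control replicates per arm; `kd_log2fc` planted
#'   knockdown downshift; `kd_noise_sd` replicate noise (log2).
#' @param n_pathway_sets,pathway_set_size hallmark-like pathway collection
#'   (first set is the planted immune program).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length_bp = 1e6,
                       n_genes = 2000L, n_regions = 500L,
                       region_width_bp = 200L,
                       n_hypodmr_true = 20L,
                       n_tumor = 10L, n_normal = 10L,
                       beta_noise_sd = 0.05, hypo_delta = 0.4,
                       n_tfs = 20L, active_tf_ids = "TF01",
                       motif_length = 8L,
                       planted_motif_fraction = 0.9,
                       atac_overlap_fraction = 0.9,
                       atac_background_fraction = 0.3,
                       regulon_size = 30L, regulon_log2fc = 1.0,
                       tf_activity_sd = 0.75,
                       immune_program_size = 30L,
                       immune_anticorr_log2fc = 1.0,
                       expr_noise_sd = 0.5,
                       n_chip_lines = 3L, n_chip_extra = 20L,
                       n_kd = 6L, kd_log2fc = 1.5, kd_noise_sd = 0.2,
                       n_pathway_sets = 10L, pathway_set_size = 30L) {
  cfg <- as.list(environment())
  counts <- c("n_chrom", "n_genes", "n_regions", "n_hypodmr_true", "n_tumor",
              "n_normal", "n_tfs", "motif_length", "regulon_size",
              "immune_program_size", "n_chip_lines", "n_kd",
              "n_pathway_sets", "pathway_set_size")
  for (f in counts)
    if (cfg[[f]] < 1) stop("sim_config: ", f, " must be >= 1")
  for (f in c("planted_motif_fraction", "atac_overlap_fraction",
              "atac_background_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: ", f, " must be in [0, 1]")
  if (hypo_delta <= 0 || hypo_delta > 1)
    stop("sim_config: hypo_delta must be in (0, 1]")
  if (n_hypodmr_true > n_regions)
    stop("sim_config: n_hypodmr_true exceeds n_regions")
  if (!all(active_tf_ids %in% sprintf("TF%02d", seq_len(n_tfs))))
    stop("sim_config: active_tf_ids must be among TF01..TF<n_tfs>")
  per_chrom <- ceiling(n_regions / n_chrom)
  if (per_chrom * (region_width_bp + 100) > chrom_length_bp)
    stop("sim_config: infeasible geometry -- regions exceed chromosome length")
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), "")
}

#' Generate the coupled synthetic fixture bundle
#'
#' Produces every input the pipeline consumes, with the planted ground
#' truth recorded in a machine-readable manifest. With the same
#' configuration (including seed) all outputs are byte-identical across
#' runs. See [sim_config()] for the planted structure.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, fixture files are written
#'   there (`genes.bed`, `regions.bed`, `regions.fa`, `beta.tsv`,
#'   `beta_groups.tsv`, `expr.tsv`, `expr_groups.tsv`, `motifs.meme`,
#'   `atac.bed`, `chip_line<i>.bed`, `kd_expr.tsv`, `kd_groups.tsv`,
#'   `pathways.gmt`, `truth.json`).
#' @return Invisibly when writing, otherwise visibly: a list with elements
#'   `genes`, `regions`, `region_seqs`, `beta`, `beta_groups`, `expr`,
#'   `expr_groups`, `kd_expr`, `kd_groups`, `pwms`, `atac`, `chip_sets`,
#'   `pathways`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed))

  ## genome geometry -------------------------------------------------------
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  gene_chrom <- rep(chroms, length.out = cfg$n_genes)
  gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))
  gene_tss <- integer(cfg$n_genes)
  for (ch in chroms) {
    idx <- which(gene_chrom == ch)
    gene_tss[idx] <- sort(sample.int(cfg$chrom_length_bp - 1000L, length(idx)))
  }
  gene_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_start <- ifelse(gene_strand == "+", gene_tss, pmax(gene_tss - 499L, 0L))
  gene_end <- gene_start + 500L
  genes <- gene_annotation(gene_id, gene_chrom, gene_start, gene_end,
                           gene_strand)

  region_chrom <- rep(chroms, length.out = cfg$n_regions)
  region_id <- sprintf("r%04d", seq_len(cfg$n_regions))
  region_start <- integer(cfg$n_regions)
  w <- cfg$region_width_bp
  for (ch in chroms) {
    idx <- which(region_chrom == ch)
    spacing <- cfg$chrom_length_bp %/% length(idx)
    jitter <- sample.int(max(spacing - w, 1L), length(idx), replace = TRUE) - 1L
    region_start[idx] <- (seq_along(idx) - 1L) * spacing + jitter
  }
  regions <- interval_set(region_chrom, region_start, region_start + w,
                          name = region_id)
  # normalization sorts; keep the id -> interval map by name lookup
  rmap <- match(region_id, regions$name)

  ## planted truth sets ----------------------------------------------------
  true_ids <- sort(sample(region_id, cfg$n_hypodmr_true), method = "radix")
  shuffled <- sample(true_ids)
  n_motif <- round(cfg$planted_motif_fraction * cfg$n_hypodmr_true)
  n_atac <- round(cfg$atac_overlap_fraction * cfg$n_hypodmr_true)
  motif_ids <- shuffled[seq_len(n_motif)]
  atac_true_ids <- shuffled[seq_len(n_atac)]
  qual_ids <- shuffled[seq_len(min(n_motif, n_atac, cfg$regulon_size))]

  ## beta values -----------------------------------------------------------
  samples_t <- sprintf("T%02d", seq_len(cfg$n_tumor))
  samples_n <- sprintf("N%02d", seq_len(cfg$n_normal))
  beta_groups <- stats::setNames(
    c(rep("tumor", cfg$n_tumor), rep("normal", cfg$n_normal)),
    c(samples_t, samples_n))
  is_true <- region_id %in% true_ids
  base_beta <- stats::runif(cfg$n_regions, 0.3, 0.9)
  base_beta[is_true] <- stats::runif(sum(is_true), 0.55, 0.9)
  mu <- matrix(base_beta, cfg$n_regions, cfg$n_tumor + cfg$n_normal)
  mu[is_true, seq_len(cfg$n_tumor)] <-
    mu[is_true, seq_len(cfg$n_tumor)] - cfg$hypo_delta
  beta <- mu + matrix(stats::rnorm(length(mu), 0, cfg$beta_noise_sd),
                      nrow(mu), ncol(mu))
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(region_id, names(beta_groups))

  ## motifs and region sequences ------------------------------------------
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  consensi <- rand_seq(cfg$n_tfs, cfg$motif_length)
  pwms <- lapply(seq_len(cfg$n_tfs), function(i) {
    m <- matrix(0.03, 4, cfg$motif_length, dimnames = list(BASES, NULL))
    cons <- strsplit(consensi[i], "")[[1]]
    m[cbind(match(cons, BASES), seq_len(cfg$motif_length))] <- 0.91
    pwm(tf_ids[i], m)
  })
  names(pwms) <- tf_ids
  active <- cfg$active_tf_ids[1]
  seqs <- stats::setNames(rand_seq(cfg$n_regions, w), region_id)
  for (rid in motif_ids) {
    off <- sample.int(w - cfg$motif_length + 1L, 1L)
    inst <- consensi[match(active, tf_ids)]
    if (stats::runif(1) < 0.5) inst <- revcomp(inst)
    s <- seqs[[rid]]
    substr(s, off, off + cfg$motif_length - 1L) <- inst
    seqs[[rid]] <- s
  }

  ## ATAC peaks ------------------------------------------------------------
  other_ids <- setdiff(region_id, true_ids)
  atac_bg_ids <- sort(sample(other_ids,
                             round(cfg$atac_background_fraction *
                                     length(other_ids))), method = "radix")
  atac_src <- c(atac_true_ids, atac_bg_ids)
  ai <- rmap[match(atac_src, region_id)]
  jit <- sample.int(41L, length(ai), replace = TRUE) - 21L
  atac <- interval_set(regions$chrom[ai],
                       pmax(regions$start[ai] + jit, 0L),
                       regions$end[ai] + jit,
                       name = sprintf("atac%04d", seq_along(ai)))

  ## regulon = nearest genes of qualifying true hypoDMRs -------------------
  qi <- rmap[match(sort(qual_ids, method = "radix"), region_id)]
  qregions <- regions[qi, , drop = FALSE]
  class(qregions) <- c("interval_set", "data.frame")
  ng <- nearest_genes(qregions, genes)
  regulon <- sort(unique(ng$gene_id[!is.na(ng$gene_id)]), method = "radix")

  ## immune-like program ---------------------------------------------------
  immune <- sort(sample(setdiff(gene_id, regulon), cfg$immune_program_size),
                 method = "radix")

  ## expression (patient cohort) ------------------------------------------
  all_expr_ids <- c(gene_id, tf_ids)
  base_log2 <- c(stats::runif(cfg$n_genes, 3, 7),
                 stats::runif(cfg$n_tfs, 4, 6))
  names(base_log2) <- all_expr_ids
  n_samp <- cfg$n_tumor + cfg$n_normal
  shift <- matrix(0, length(all_expr_ids), n_samp,
                  dimnames = list(all_expr_ids, names(beta_groups)))
  activity <- stats::rnorm(cfg$n_tumor, 0, 1)
  tum <- seq_len(cfg$n_tumor)
  shift[regulon, tum] <- shift[regulon, tum] + cfg$regulon_log2fc
  shift[active, tum] <- cfg$regulon_log2fc + cfg$tf_activity_sd * activity
  shift[immune, tum] <- shift[immune, tum] +
    rep(-cfg$immune_anticorr_log2fc * activity, each = length(immune))
  expr <- 2^(base_log2 + shift +
               matrix(stats::rnorm(length(shift), 0, cfg$expr_noise_sd),
                      nrow(shift), ncol(shift)))
  dimnames(expr) <- dimnames(shift)
  expr_groups <- beta_groups

  ## ChIP peak sets (shared at regulon loci + line-specific extras) --------
  chip_sets <- vector("list", cfg$n_chip_lines)
  names(chip_sets) <- sprintf("line%d", seq_len(cfg$n_chip_lines))
  for (l in seq_len(cfg$n_chip_lines)) {
    jit <- sample.int(21L, length(qi), replace = TRUE) - 11L
    extra <- sample(setdiff(seq_len(nrow(regions)), qi),
                    min(cfg$n_chip_extra, nrow(regions) - length(qi)))
    chip_sets[[l]] <- interval_set(
      c(regions$chrom[qi], regions$chrom[extra]),
      c(pmax(regions$start[qi] + jit, 0L), regions$start[extra]),
      c(regions$end[qi] + jit, regions$end[extra]),
      name = sprintf("%s_p%03d", names(chip_sets)[l],
                     seq_len(length(qi) + length(extra))))
  }

  ## knockdown-vs-control expression (cell-line replicates) ----------------
  kd_samples <- c(sprintf("KD%02d", seq_len(cfg$n_kd)),
                  sprintf("CT%02d", seq_len(cfg$n_kd)))
  kd_groups <- stats::setNames(rep(c("knockdown", "control"), each = cfg$n_kd),
                               kd_samples)
  kd_shift <- matrix(0, length(all_expr_ids), 2 * cfg$n_kd,
                     dimnames = list(all_expr_ids, kd_samples))
  kd_cols <- seq_len(cfg$n_kd)
  kd_shift[c(regulon, active), kd_cols] <- -cfg$kd_log2fc
  kd_expr <- 2^(base_log2 + cfg$regulon_log2fc *
                  (all_expr_ids %in% c(regulon, active)) + kd_shift +
                  matrix(stats::rnorm(length(kd_shift), 0, cfg$kd_noise_sd),
                         nrow(kd_shift), ncol(kd_shift)))
  dimnames(kd_expr) <- dimnames(kd_shift)

  ## hallmark-like pathway sets (first = planted immune program) -----------
  pathways <- list(IMMUNE_PROGRAM = immune)
  decoy_pool <- setdiff(gene_id, immune)
  for (i in seq_len(cfg$n_pathway_sets - 1L))
    pathways[[sprintf("PATHWAY_%02d", i + 1L)]] <-
      sort(sample(decoy_pool, cfg$pathway_set_size), method = "radix")

  truth <- list(true_hypodmr_ids = true_ids,
                active_tf_ids = cfg$active_tf_ids,
                motif_hypodmr_ids = sort(motif_ids, method = "radix"),
                atac_hypodmr_ids = sort(atac_true_ids, method = "radix"),
                qualifying_hypodmr_ids = sort(qual_ids, method = "radix"),
                regulon = stats::setNames(list(regulon), active),
                immune_program_genes = immune,
                signature_genes = regulon,
                beta_groups = as.list(beta_groups),
                expr_groups = as.list(expr_groups),
                kd_groups = as.list(kd_groups))

  bundle <- list(genes = genes, regions = regions, region_seqs = seqs,
                 beta = beta, beta_groups = beta_groups,
                 expr = expr, expr_groups = expr_groups,
                 kd_expr = kd_expr, kd_groups = kd_groups,
                 pwms = pwms, atac = atac, chip_sets = chip_sets,
                 pathways = pathways, truth = truth, config = cfg)
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

gene_annotation_to_bed <- function(genes) {
  interval_set(genes$chrom, genes$body_start, genes$body_end,
               name = genes$gene_id, strand = genes$strand)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_bed(gene_annotation_to_bed(bundle$genes), p("genes.bed"))
  write_bed(bundle$regions, p("regions.bed"))
  write_region_fasta(bundle$region_seqs, p("regions.fa"))
  write_tsv_matrix(bundle$beta, p("beta.tsv"))
  write_groups(bundle$beta_groups, p("beta_groups.tsv"))
  write_tsv_matrix(bundle$expr, p("expr.tsv"))
  write_groups(bundle$expr_groups, p("expr_groups.tsv"))
  write_tsv_matrix(bundle$kd_expr, p("kd_expr.tsv"))
  write_groups(bundle$kd_groups, p("kd_groups.tsv"))
  write_meme(bundle$pwms, p("motifs.meme"))
  write_bed(bundle$atac, p("atac.bed"))
  for (l in names(bundle$chip_sets))
    write_bed(bundle$chip_sets[[l]], p(sprintf("chip_%s.bed", l)))
  write_gmt(bundle$pathways, p("pathways.gmt"))
  jsonlite::write_json(bundle$truth, p("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Read a fixture bundle written by [simulate_dataset()]
#'
#' @param dir directory containing the fixture files.
#' @return A bundle list with the same in-memory components (minus `config`;
#'   `truth` present only when `truth.json` exists).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- c("genes.bed", "regions.bed", "regions.fa", "beta.tsv",
            "beta_groups.tsv", "expr.tsv", "expr_groups.tsv", "motifs.meme",
            "atac.bed")
  miss <- need[!file.exists(vapply(need, p, ""))]
  if (length(miss))
    stop("read_bundle: missing input files: ", paste(miss, collapse = ", "))
  bundle <- list(
    genes = read_gene_bed(p("genes.bed")),
    regions = read_bed(p("regions.bed")),
    region_seqs = read_region_fasta(p("regions.fa")),
    beta = read_tsv_matrix(p("beta.tsv")),
    beta_groups = read_groups(p("beta_groups.tsv")),
    expr = read_tsv_matrix(p("expr.tsv")),
    expr_groups = read_groups(p("expr_groups.tsv")),
    pwms = read_meme(p("motifs.meme")),
    atac = read_bed(p("atac.bed")))
  chip <- sort(list.files(dir, pattern = "^chip_.*\\.bed$"), method = "radix")
  if (length(chip))
    bundle$chip_sets <- stats::setNames(
      lapply(chip, function(f) read_bed(p(f))),
      sub("^chip_(.*)\\.bed$", "\\1", chip))
  if (file.exists(p("kd_expr.tsv"))) {
    bundle$kd_expr <- read_tsv_matrix(p("kd_expr.tsv"))
    bundle$kd_groups <- read_groups(p("kd_groups.tsv"))
  }
  if (file.exists(p("pathways.gmt")))
    bundle$pathways <- read_gmt(p("pathways.gmt"))
  if (file.exists(p("truth.json")))
    bundle$truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  bundle
}
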