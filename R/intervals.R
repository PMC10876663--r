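#' Construct a normalized interval set
#'
#' An interval set is the package's currency for genomic regions (DMRs, ATAC
#' peaks, ChIP peaks, motif-bearing regions). Coordinates are BED-style:
#' 0-based, half-open `[start, end)`. Construction normalizes: intervals are
#' sorted by (chrom, start, end, name) in C locale and exact duplicate
#' (chrom, start, end, name) records are dropped.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start (>= 0).
#' @param end integer vector, 0-based exclusive end (> start).
#' @param name optional character vector of labels (`NA` for unnamed).
#' @param strand optional character vector, each one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` of class `interval_set` with columns
#'   `chrom`, `start`, `end`, `name`, `strand`, sorted and deduplicated.
#' @examples
#' interval_set(c("chr1", "chr1"), c(10, 40), c(20, 90), name = c("a", "b"))
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), name = NULL, strand = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- rep(NA_character_, n)
  if (is.null(strand)) strand <- rep(".", n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   name = as.character(name),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  normalize_interval_set(df)
}

validate_intervals <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("interval_set: chrom must be non-empty")
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval_set: non-integer coordinates")
  if (any(df$start < 0))
    stop("interval_set: start must be >= 0")
  if (any(df$end <= df$start))
    stop("interval_set: end must be > start (half-open intervals)")
  bad <- !df$strand %in% c("+", "-", ".")
  if (any(bad))
    stop("interval_set: strand must be one of '+', '-', '.'")
  invisible(df)
}

normalize_interval_set <- function(df) {
  key <- paste(df$chrom, df$start, df$end, df$name, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  o <- order(df$chrom, df$start, df$end, df$name, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

is_interval_set <- function(x) inherits(x, "interval_set")

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set with %d interval(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

# interval_set <-> GRanges (internal; shifts to 1-based closed and back)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand))
}

granges_to_intervals <- function(gr, name = NULL) {
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  interval_set(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               name = name,
               strand = st)
}

#' Read a BED3/BED6 file into an interval set
#'
#' Coordinates are taken verbatim as 0-based half-open. Column 4 maps to
#' `name` (`"."` becomes `NA`), column 6 to `strand`; column 5 (score) is
#' ignored. Lines starting with `#`, `track` or `browser`, and blank lines,
#' are skipped.
#'
#' @param path path to a BED file with >= 3 tab-separated columns.
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("read_bed: file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#|^track\\b|^browser\\b|^\\s*$", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(interval_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop("read_bed: fewer than 3 columns at line ", lineno[which(ncols < 3)[1]])
  chrom <- vapply(parts, `[[`, "", 1L)
  s_raw <- vapply(parts, `[[`, "", 2L)
  e_raw <- vapply(parts, `[[`, "", 3L)
  start <- suppressWarnings(as.integer(s_raw))
  end <- suppressWarnings(as.integer(e_raw))
  bad <- is.na(start) | is.na(end) | s_raw != as.character(start) |
    e_raw != as.character(end)
  if (any(bad))
    stop("read_bed: non-integer coordinates at line ", lineno[which(bad)[1]])
  bad <- end <= start
  if (any(bad))
    stop("read_bed: end <= start at line ", lineno[which(bad)[1]])
  name <- ifelse(ncols >= 4, vapply(parts, function(p) p[min(4L, length(p))], ""),
                 NA_character_)
  name[name == "."] <- NA_character_
  strand <- ifelse(ncols >= 6, vapply(parts, function(p) p[min(6L, length(p))], ""),
                   ".")
  if (any(!strand %in% c("+", "-", ".")))
    stop("read_bed: invalid strand at line ",
         lineno[which(!strand %in% c("+", "-", "."))[1]])
  interval_set(chrom, start, end, name, strand)
}

#' Write an interval set as BED6
#'
#' Emits six tab-separated columns (chrom, start, end, name, score, strand);
#' unnamed intervals get `"."`, score is always `"."`. `read_bed()` composed
#' with `write_bed()` is the identity on normalized sets.
#'
#' @param x an [interval_set()].
#' @param path output file path.
#' @export
write_bed <- function(x, path) {
  stopifnot(is_interval_set(x))
  nm <- ifelse(is.na(x$name), ".", x$name)
  lines <- sprintf("%s\t%d\t%d\t%s\t.\t%s", x$chrom, x$start, x$end, nm, x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Intersect two interval sets
#'
#' Reports, for each interval of `a`, the intervals of `b` overlapping it by
#' at least `min_overlap_bp` base pairs. Overlap on half-open coordinates is
#' `min(end_a, end_b) - max(start_a, start_b)`; abutting intervals do not
#' overlap.
#'
#' @param a,b [interval_set()] objects.
#' @param min_overlap_bp minimum overlap in bp (integer >= 1).
#' @return A `data.frame` with columns `a_idx`, `b_idx` (row indices into the
#'   normalized sets), `a_name`, `b_name`, `overlap_bp`, ordered by
#'   (`a_idx`, `b_idx`).
#' @export
intersect_intervals <- function(a, b, min_overlap_bp = 1L) {
  stopifnot(is_interval_set(a), is_interval_set(b))
  min_overlap_bp <- as.integer(min_overlap_bp)
  if (is.na(min_overlap_bp) || min_overlap_bp < 1L)
    stop("intersect_intervals: min_overlap_bp must be an integer >= 1")
  empty <- data.frame(a_idx = integer(), b_idx = integer(),
                      a_name = character(), b_name = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  ga <- as_granges(a)
  gb <- as_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap_bp,
                                      ignore.strand = TRUE)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  o <- order(ai, bi)
  data.frame(a_idx = ai[o], b_idx = bi[o],
             a_name = a$name[ai][o], b_name = b$name[bi][o],
             overlap_bp = as.integer(ov[o]), stringsAsFactors = FALSE)
}

#' Merge overlapping intervals within one set
#'
#' @param x an [interval_set()].
#' @return An [interval_set()] of maximal merged intervals (names dropped).
#' @export
merge_intervals <- function(x) {
  stopifnot(is_interval_set(x))
  if (nrow(x) == 0) return(interval_set())
  gr <- GenomicRanges::reduce(as_granges(x), ignore.strand = TRUE)
  granges_to_intervals(gr)
}

#' Read a gene annotation from BED6
#'
#' The only annotation dialect the package requires: BED6 with the gene id in
#' the name column. The transcription start site is derived from strand:
#' `start` for `+` genes, `end - 1` for `-` genes.
#'
#' @param path path to a BED6 file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `body_start`, `body_end`.
#' @export
read_gene_bed <- function(path) {
  x <- read_bed(path)
  if (nrow(x) > 0 && (any(is.na(x$name)) || any(!x$strand %in% c("+", "-"))))
    stop("read_gene_bed: gene annotation needs a name (gene id) and +/- strand")
  gene_annotation(gene_id = x$name, chrom = x$chrom, start = x$start,
                  end = x$end, strand = x$strand)
}

#' Build a gene annotation table
#'
#' @param gene_id character vector of unique gene ids.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open gene body extent.
#' @param strand `"+"` or `"-"`; determines the TSS end of the body.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `body_start`, `body_end`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stop("gene_annotation: duplicate gene ids")
  if (any(!strand %in% c("+", "-"))) stop("gene_annotation: strand must be +/-")
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("gene_annotation: end must be > start")
  tss <- ifelse(strand == "+", start, end - 1L)
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   tss = as.integer(tss), strand = as.character(strand),
                   body_start = start, body_end = end, stringsAsFactors = FALSE)
  o <- order(df$chrom, df$tss, df$gene_id, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Nearest gene(s) by TSS for genomic regions
#'
#' Distance is measured from the region midpoint, `floor((start + end) / 2)`,
#' to the gene TSS; the signed distance is `tss - midpoint` (0 when the
#' midpoint coincides with the TSS). Ties on absolute distance are broken by
#' the lexicographically smaller gene id (C locale). Region strand is
#' ignored. A region on a chromosome with no annotated gene gets `NA` gene
#' and distance (distinguishable from distance 0).
#'
#' @param regions an [interval_set()].
#' @param genes a gene annotation from [gene_annotation()] / [read_gene_bed()].
#' @return A `data.frame` with one row per region: `region_name`, `gene_id`,
#'   `distance` (signed bp, `tss - midpoint`).
#' @export
nearest_genes <- function(regions, genes) {
  stopifnot(is_interval_set(regions))
  if (nrow(genes) == 0) stop("nearest_genes: empty gene annotation")
  mid <- (regions$start + regions$end) %/% 2L
  out_gene <- rep(NA_character_, nrow(regions))
  out_dist <- rep(NA_integer_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ri <- which(regions$chrom == ch)
    if (nrow(g) == 0) next
    # genes sorted by (tss, gene_id); run starts give the lexicographically
    # smallest id at each distinct tss
    run_start <- which(!duplicated(g$tss))
    run_of <- rep(seq_along(run_start), diff(c(run_start, nrow(g) + 1L)))
    tss_u <- g$tss[run_start]
    m <- mid[ri]
    i <- findInterval(m, tss_u)            # last tss <= midpoint (0 if none)
    left_ok <- i >= 1L
    right_ok <- i < length(tss_u)
    d_left <- ifelse(left_ok, m - tss_u[pmax(i, 1L)], Inf)
    d_right <- ifelse(right_ok, tss_u[pmin(i + 1L, length(tss_u))] - m, Inf)
    pick_left <- d_left < d_right
    tie <- d_left == d_right & is.finite(d_left)
    gl <- g$gene_id[run_start[pmax(i, 1L)]]
    gr <- g$gene_id[run_start[pmin(i + 1L, length(tss_u))]]
    gene <- ifelse(pick_left, gl, gr)
    if (any(tie)) gene[tie] <- pmin(gl[tie], gr[tie])
    dist <- ifelse(pick_left | (tie & gene == gl), -d_left, d_right)
    out_gene[ri] <- gene
    out_dist[ri] <- as.integer(dist)
  }
  data.frame(region_name = regions$name, gene_id = out_gene,
             distance = out_dist, stringsAsFactors = FALSE)
}

#' @rdname nearest_genes
#' @param region a single-row [interval_set()].
#' @return `nearest_gene()`: a list with `gene_id` and `distance`, or both
#'   `NA` when the chromosome has no gene.
#' @export
nearest_gene <- function(region, genes) {
  stopifnot(is_interval_set(region), nrow(region) == 1L)
  r <- nearest_genes(region, genes)
  list(gene_id = r$gene_id[1], distance = r$distance[1])
}
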