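#' Read a GMT gene-set file
#'
#' One set per line: `set_id <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("read_gmt: each line needs set_id, description and >= 1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("read_gmt: duplicate set ids")
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description column (recycled; default `"na"`).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a RNK ranking file (gene, score)
#'
#' @param path two-column tab-separated file, no header.
#' @return A [ranked_genes()] object (sorted by descending score).
#' @export
read_rnk <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 2) stop("read_rnk: expected two tab-separated columns")
  ranked_genes(gene_id = as.character(x[[1]]), score = as.numeric(x[[2]]))
}

#' Write a ranking as RNK
#' @param r a [ranked_genes()] object.
#' @param path output path.
#' @export
write_rnk <- function(r, path) {
  stopifnot(inherits(r, "ranked_genes"))
  writeLines(sprintf("%s\t%s", r$gene_id, format(r$score, scientific = FALSE,
                                                 trim = TRUE)), path)
  invisible(path)
}

#' Read position weight matrices from MEME-minimal text
#'
#' Parses the minimal MEME motif format: a `MOTIF <id>` line followed by a
#' `letter-probability matrix:` header and one line of four probabilities
#' (A C G T order) per motif position. Background frequencies from a
#' `Background letter frequencies` block are applied to every motif; default
#' uniform.
#'
#' @param path path to a MEME-minimal file.
#' @param pseudocount probability pseudocount added per cell before
#'   renormalization (default 1e-4).
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudocount = 1e-4) {
  if (!file.exists(path)) stop("read_meme: file not found: ", path)
  lines <- trimws(readLines(path))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    toks <- strsplit(lines[bgi[1] + 1], "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop("read_meme: no MOTIF entries found")
  pwms <- list()
  for (s in starts) {
    id <- strsplit(lines[s], "\\s+")[[1]][2]
    h <- s + which(grepl("^letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    if (is.na(h)) stop("read_meme: motif ", id, " lacks a probability matrix")
    rows <- list()
    i <- h + 1
    while (i <= length(lines) && grepl("^[-0-9.eE+ \t]+$", lines[i]) &&
           nzchar(lines[i])) {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1
    }
    if (length(rows) == 0) stop("read_meme: empty matrix for motif ", id)
    if (any(lengths(rows) != 4))
      stop("read_meme: motif ", id, " rows must have 4 probabilities (A C G T)")
    mat <- t(matrix(unlist(rows), nrow = 4))  # positions x 4
    pwms[[id]] <- pwm(id, mat, background = bg, pseudocount = pseudocount)
  }
  pwms
}

#' Write PWMs as MEME-minimal text
#' @param pwms named list of [pwm()] objects.
#' @param path output path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  bg <- pwms[[1]]$background
  writeLines(c("Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$tf_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(p$mat)), con)
    for (j in seq_len(ncol(p$mat)))
      writeLines(sprintf("%.6f %.6f %.6f %.6f", p$mat[1, j], p$mat[2, j],
                         p$mat[3, j], p$mat[4, j]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write a numeric matrix as TSV (rows x samples)
#'
#' First column holds row ids (header `id`), remaining columns one sample
#' each.
#'
#' @param path file path.
#' @return `read_tsv_matrix()`: numeric matrix with rownames and colnames.
#' @export
read_tsv_matrix <- function(path) {
  x <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(x[[1]])
  m
}

#' @rdname read_tsv_matrix
#' @param m numeric matrix with rownames and colnames.
#' @param digits significant digits written (default 10; fixed so that
#'   identical matrices yield byte-identical files).
#' @export
write_tsv_matrix <- function(m, path, digits = 10) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(v)
    paste(formatC(v, digits = digits, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write sample group labels
#'
#' Two tab-separated columns `sample`, `group` with header.
#' @param path file path.
#' @return `read_groups()`: named character vector (names = sample ids).
#' @export
read_groups <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(as.character(x$group), as.character(x$sample))
}

#' @rdname read_groups
#' @param groups named character vector of group labels.
#' @export
write_groups <- function(groups, path) {
  writeLines(c("sample\tgroup",
               sprintf("%s\t%s", names(groups), groups)), path)
  invisible(path)
}

#' Read / write region sequences as FASTA
#'
#' Sequences are keyed by region id.
#' @param path file path.
#' @return `read_region_fasta()`: named character vector of DNA sequences.
#' @export
read_region_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_region_fasta
#' @param seqs named character vector of sequences over A/C/G/T/N.
#' @export
write_region_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# shared TSV table writer: fixed numeric formatting for reproducible bytes
write_tsv_table <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
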