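BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' Per-position nucleotide probabilities defining a binding motif, stored as
#' a 4 x L matrix (rows A, C, G, T). A pseudocount is added to every cell and
#' columns are renormalized so each position sums to 1. Log-odds scores are
#' taken in bits against the background model.
#'
#' @param tf_id motif / transcription-factor identifier.
#' @param mat numeric matrix of base probabilities, either L x 4
#'   (positions x A,C,G,T) or 4 x L.
#' @param background length-4 base probabilities (A, C, G, T); default
#'   uniform.
#' @param pseudocount probability added per cell before renormalization.
#' @return An object of class `pwm` with elements `tf_id`, `mat` (4 x L,
#'   rownames A/C/G/T), `background`, `pseudocount`, `log_odds` (bits) and
#'   `max_score` (sum of per-position maxima).
#' @export
pwm <- function(tf_id, mat, background = rep(0.25, 4), pseudocount = 1e-4) {
  mat <- as.matrix(mat)
  if (ncol(mat) == 4 && nrow(mat) != 4) mat <- t(mat)
  if (nrow(mat) != 4) stop("pwm: matrix must have 4 base rows/columns")
  if (any(mat < 0)) stop("pwm: negative probabilities")
  if (length(background) != 4 || any(background <= 0))
    stop("pwm: background must be 4 positive probabilities")
  background <- background / sum(background)
  mat <- mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- BASES
  lo <- log2(mat / background)
  structure(list(tf_id = as.character(tf_id), mat = mat,
                 background = stats::setNames(background, BASES),
                 pseudocount = pseudocount,
                 log_odds = lo,
                 max_score = sum(apply(lo, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d bp, consensus %s, max log-odds %.2f bits\n",
              x$tf_id, ncol(x$mat), pwm_consensus(x), x$max_score))
  invisible(x)
}

#' Consensus sequence of a PWM (per-position most probable base)
#' @param p a [pwm()].
#' @return Character string over A/C/G/T.
#' @export
pwm_consensus <- function(p) {
  paste(BASES[apply(p$mat, 2, which.max)], collapse = "")
}

#' Reverse-complement a DNA string (A/C/G/T/N)
#' @param s character vector of sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# encode sequence to base indices (1..4, NA for N/other)
encode_seq <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)
}

# log-odds score of every window of length L on an encoded sequence;
# windows containing N score NA
window_scores <- function(enc, lo) {
  L <- ncol(lo)
  W <- length(enc) - L + 1L
  if (W < 1L) return(numeric(0))
  sc <- numeric(W)
  for (j in seq_len(L)) {
    b <- enc[j:(j + W - 1L)]
    v <- rep(NA_real_, W)
    ok <- !is.na(b)
    v[ok] <- lo[cbind(b[ok], j)]
    sc <- sc + v
  }
  sc
}

#' Scan a sequence for PWM hits on both strands
#'
#' Every window of motif length is scored by summed per-position log-odds
#' (bits); windows containing `N` are skipped. A window is a hit when its
#' score reaches `threshold_frac` times the maximum attainable score (the sum
#' of per-position maxima). The reverse strand is scanned as the
#' reverse-complement motif against the forward sequence; reported offsets
#' are always 0-based positions of the window start on the forward sequence.
#'
#' @param sequence DNA string over A/C/G/T/N, at least motif length long.
#' @param p a [pwm()].
#' @param threshold_frac fraction of the maximum log-odds in (0, 1]
#'   (default 0.8).
#' @return A `data.frame` with columns `offset` (0-based), `strand`
#'   (`"+"`/`"-"`) and `score` (bits), ordered by offset then strand.
#' @export
scan_pwm <- function(sequence, p, threshold_frac = 0.8) {
  stopifnot(inherits(p, "pwm"))
  if (!is.numeric(threshold_frac) || length(threshold_frac) != 1 ||
      threshold_frac <= 0 || threshold_frac > 1)
    stop("scan_pwm: threshold_frac must be in (0, 1]")
  enc <- encode_seq(sequence)
  bad <- is.na(enc) & !strsplit(toupper(sequence), "")[[1]] %in% c("N")
  if (any(bad)) stop("scan_pwm: sequence must be over A/C/G/T/N")
  L <- ncol(p$mat)
  if (length(enc) < L) stop("scan_pwm: sequence shorter than motif")
  thr <- threshold_frac * p$max_score
  # minus-strand motif: reverse-complemented log-odds matrix
  lo_rc <- p$log_odds[4:1, ncol(p$log_odds):1, drop = FALSE]
  fwd <- window_scores(enc, p$log_odds)
  rev <- window_scores(enc, lo_rc)
  hit_f <- which(!is.na(fwd) & fwd >= thr)
  hit_r <- which(!is.na(rev) & rev >= thr)
  out <- data.frame(
    offset = c(hit_f, hit_r) - 1L,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    score = c(fwd[hit_f], rev[hit_r]),
    stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan many region sequences against many PWMs
#'
#' @param seqs named character vector of region sequences (names are region
#'   ids).
#' @param pwms named list of [pwm()] objects.
#' @inheritParams scan_pwm
#' @return A `data.frame` of motif hits: `tf_id`, `region_id`, `offset`,
#'   `strand`, `score`.
#' @export
scan_regions <- function(seqs, pwms, threshold_frac = 0.8) {
  stopifnot(length(names(seqs)) == length(seqs))
  if (!is.numeric(threshold_frac) || threshold_frac <= 0 || threshold_frac > 1)
    stop("scan_regions: threshold_frac must be in (0, 1]")
  enc_all <- lapply(seqs, encode_seq)  # encode once, reuse across motifs
  res <- vector("list", length(pwms) * length(seqs))
  k <- 0L
  for (p in pwms) {
    thr <- threshold_frac * p$max_score
    lo_rc <- p$log_odds[4:1, ncol(p$log_odds):1, drop = FALSE]
    for (i in seq_along(seqs)) {
      fwd <- window_scores(enc_all[[i]], p$log_odds)
      rev <- window_scores(enc_all[[i]], lo_rc)
      hit_f <- which(!is.na(fwd) & fwd >= thr)
      hit_r <- which(!is.na(rev) & rev >= thr)
      if (length(hit_f) + length(hit_r) > 0) {
        k <- k + 1L
        res[[k]] <- data.frame(
          tf_id = p$tf_id, region_id = names(seqs)[i],
          offset = c(hit_f, hit_r) - 1L,
          strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
          score = c(fwd[hit_f], rev[hit_r]), stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(tf_id = character(), region_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}
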