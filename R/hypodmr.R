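#' Call tumor-specific hypomethylated regions (hypoDMRs)
#'
#' Per region, a Welch two-sample t-test compares beta values between the
#' tumor and normal groups; p-values are Benjamini-Hochberg adjusted across
#' all tested regions. A region is called hypomethylated when
#' `delta = mean(tumor) - mean(normal) <= -delta_min` and `q <= q_max`.
#' Regions where either group has fewer than two non-missing betas are
#' flagged untested and never called. Regions where both groups are constant
#' get p = 1 when the group means agree and p = 0 when they are perfectly
#' separated.
#'
#' @param beta numeric matrix of beta values in \[0, 1\], regions x samples,
#'   with region ids as rownames and sample ids as colnames.
#' @param groups named character vector mapping each sample id to `"tumor"`
#'   or `"normal"`.
#' @param delta_min minimum absolute beta drop to call hypo (default 0.2).
#' @param q_max BH FDR ceiling (default 0.05).
#' @return A `data.frame` sorted by (q, delta) with columns `region_id`,
#'   `delta`, `mean_tumor`, `mean_normal`, `p_value`, `q_value`, `is_hypo`,
#'   `tested`.
#' @export
call_hypodmrs <- function(beta, groups, delta_min = 0.2, q_max = 0.05) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("call_hypodmrs: beta values must lie in [0, 1]")
  groups <- groups[colnames(beta)]
  if (any(is.na(groups)))
    stop("call_hypodmrs: every sample needs a group label")
  it <- which(groups == "tumor")
  ino <- which(groups == "normal")
  if (length(it) == 0 || length(ino) == 0)
    stop("call_hypodmrs: both tumor and normal groups must be non-empty")
  w <- welch_rows(beta, it, ino)
  q <- rep(NA_real_, nrow(beta))
  q[w$usable] <- stats::p.adjust(w$p[w$usable], method = "BH")
  is_hypo <- !is.na(q) & w$delta <= -delta_min & q <= q_max
  out <- data.frame(region_id = rownames(beta),
                    delta = w$delta,
                    mean_tumor = w$mean1, mean_normal = w$mean2,
                    p_value = w$p, q_value = q,
                    is_hypo = is_hypo, tested = w$usable,
                    stringsAsFactors = FALSE)
  o <- order(out$q_value, out$delta, out$region_id, method = "radix",
             na.last = TRUE)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
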