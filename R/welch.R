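# Row-wise Welch two-sample t-test, vectorized over a matrix.
# Returns delta = mean(x1) - mean(x2) per row, two-sided p.
# Degenerate rows (both group variances 0): p = 1 if delta == 0, else 0
# (perfect separation). Rows with < 2 usable values in either group get
# NA delta/p (the caller decides how to flag them).
welch_rows <- function(m, idx1, idx2) {
  m1 <- m[, idx1, drop = FALSE]
  m2 <- m[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(m1))
  n2 <- rowSums(!is.na(m2))
  mu1 <- rowMeans(m1, na.rm = TRUE)
  mu2 <- rowMeans(m2, na.rm = TRUE)
  v1 <- rowSums((m1 - mu1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((m2 - mu2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  delta <- mu1 - mu2
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- rep(NA_real_, nrow(m))
  usable <- n1 >= 2 & n2 >= 2
  degen <- usable & se2 == 0
  ok <- usable & se2 > 0
  t <- delta[ok] / sqrt(se2[ok])
  p[ok] <- 2 * stats::pt(abs(t), df[ok], lower.tail = FALSE)
  p[degen] <- ifelse(delta[degen] == 0, 1, 0)
  delta[!usable] <- NA_real_
  list(delta = delta, p = p, n1 = n1, n2 = n2,
       mean1 = mu1, mean2 = mu2, usable = usable)
}
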