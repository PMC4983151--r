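#' Otsu's histogram threshold
#'
#' Bins the values into `n_bins` equal-width bins spanning `[min, max]` and
#' returns the bin edge maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Used to derive the tracking anisotropy cutoff
#' (the tracker's default threshold is 0.6 times this value).
#'
#' @param values non-negative numeric vector with at least 2 distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold, a single bin-edge value.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || length(unique(values)) < 2L)
    stop("otsu_threshold needs at least 2 distinct finite values")
  lo <- min(values); hi <- max(values)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(counts)
  total <- w0[n_bins]
  sum0 <- cumsum(counts * mids)
  mu0 <- sum0 / w0
  w1 <- total - w0
  mu1 <- (sum0[n_bins] - sum0) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  # candidate thresholds are the interior edges; edge i+1 splits bins 1..i | i+1..
  best <- which.max(between[seq_len(n_bins - 1L)])
  edges[best + 1L]
}
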