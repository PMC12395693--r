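# independent oracle: exhaustive search maximising the triangle-rule
# distance, computed via the cross-product area formula
triangle_oracle <- function(img) {
  lo <- min(img); hi <- max(img); w <- (hi - lo) / 256
  bin <- pmin(floor((img - lo) / w), 255)
  cts <- tabulate(as.integer(bin) + 1L, nbins = 256)
  nzb <- which(cts > 0) - 1L
  peak <- which.max(cts) - 1L
  b <- if ((max(nzb) - peak) >= (peak - min(nzb))) max(nzb) else min(nzb)
  p1 <- c(peak, cts[peak + 1]); p2 <- c(b, 0)
  cand <- if (b > peak) peak:b else b:peak
  dist <- vapply(cand, function(x) {
    v <- p2 - p1; u <- c(x, cts[x + 1]) - p1
    abs(v[1] * u[2] - v[2] * u[1]) / sqrt(sum(v^2))
  }, numeric(1))
  t <- min(cand[dist == max(dist)])
  lo + (t + 1) * w
}
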