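# Independent oracle for the 2-channel metamer fit: coarse-to-fine grid
# search over the nonnegative weight plane, minimizing the same stacked
# (residual + curvature) objective as the package's solver.
grid_search_2ch <- function(target_vals, basis, smoothness) {
  B <- basis$B
  D2 <- illumdisc:::.second_diff_operator(nrow(B))
  obj <- function(w) {
    fit <- as.numeric(B %*% w)
    sum((fit - target_vals)^2) + smoothness * sum((D2 %*% fit)^2)
  }
  lo <- c(0, 0); hi <- c(2, 2)
  for (pass in 1:6) {
    g1 <- seq(lo[1], hi[1], length.out = 21)
    g2 <- seq(lo[2], hi[2], length.out = 21)
    vals <- outer(g1, g2, Vectorize(function(a, b) obj(c(a, b))))
    k <- arrayInd(which.min(vals), dim(vals))
    best <- c(g1[k[1]], g2[k[2]])
    span <- c(g1[2] - g1[1], g2[2] - g2[1])
    lo <- pmax(best - span, 0)
    hi <- best + span
  }
  best
}
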