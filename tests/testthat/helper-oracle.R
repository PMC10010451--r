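# Brute-force oracles, independent of the active-set solver path.

# Exhaustive two-stage grid search for
#   min ||y - Xw - b||^2 + lambda ||w||^2,  w >= 0, b free,
# with b profiled out at each grid point. Enumerates a coarse grid over
# [0, wmax]^p, then a fine grid around the coarse optimum.
grid_nnls_oracle <- function(y, X, lambda = 0, wmax = 3,
                             coarse = 0.05, fine = 0.002) {
  p <- ncol(X)
  eval_grid <- function(grids) {
    W <- as.matrix(expand.grid(grids))
    R <- y - X %*% t(W)                    # pairs x m residuals (pre-intercept)
    Rc <- sweep(R, 2, colMeans(R))         # profile out the intercept
    obj <- colSums(Rc^2) + lambda * rowSums(W^2)
    W[which.min(obj), ]
  }
  w1 <- eval_grid(rep(list(seq(0, wmax, by = coarse)), p))
  grids <- lapply(w1, function(wk) {
    g <- seq(max(0, wk - 1.5 * coarse), wk + 1.5 * coarse, by = fine)
    g
  })
  unname(eval_grid(grids))
}

# objective of the nonnegative ridge problem (for monotonicity checks)
nnridge_objective <- function(y, X, w, b, lambda) {
  sum((y - X %*% w - b)^2) + lambda * sum(w^2)
}
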