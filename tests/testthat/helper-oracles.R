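# Shared oracles and fixture builders for the test suite. Oracles are kept
# deliberately independent of the package internals they check: plain loops
# and direct arithmetic, no calls into the code paths under test.

# brute-force minimizer of the unary + total-variation field-map energy by
# full enumeration over all label assignments (tiny instances only)
enum_field_opt <- function(D, grid, lambda, pairs) {
  V <- nrow(D)
  L <- ncol(D)
  step <- if (L > 1) grid[2] - grid[1] else 1
  idx <- rep(1L, V)
  best <- Inf
  best_idx <- idx
  repeat {
    e <- 0
    for (v in seq_len(V)) e <- e + D[v, idx[v]]
    if (nrow(pairs)) {
      for (p in seq_len(nrow(pairs))) {
        e <- e + lambda * step * abs(idx[pairs[p, 1]] - idx[pairs[p, 2]])
      }
    }
    if (e < best) { best <- e; best_idx <- idx }
    j <- 1L
    while (j <= V) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= L) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > V) break
  }
  list(energy = best, labels = best_idx)
}

# brute-force minimizer of a binary pairwise energy by enumeration
enum_binary_opt <- function(theta0, theta1, pairs, A, B, C, D) {
  V <- length(theta0)
  best <- Inf; best_x <- rep(0L, V)
  for (code in 0:(2^V - 1)) {
    x <- as.integer(intToBits(code)[seq_len(V)])
    e <- sum(ifelse(x == 1L, theta1, theta0))
    if (nrow(pairs)) {
      for (p in seq_len(nrow(pairs))) {
        xv <- x[pairs[p, 1]]; xw <- x[pairs[p, 2]]
        e <- e + if (xv == 0 && xw == 0) A[p] else
          if (xv == 0 && xw == 1) B[p] else
          if (xv == 1 && xw == 0) C[p] else D[p]
      }
    }
    if (e < best) { best <- e; best_x <- x }
  }
  list(energy = best, x = best_x)
}

# random field-map-like optimization instance: a smooth random truth field
# quantized to L labels, per-voxel unary costs with a valley at the truth
# and a displaced secondary (swap-like) valley, plus noise
make_fws_instance <- function(seed, nx = 8, ny = 8, L = 7) {
  set.seed(seed)
  u <- outer(seq(-1, 1, length.out = nx), rep(1, ny)) * runif(1, -2, 2) +
    outer(rep(1, nx), seq(-1, 1, length.out = ny)) * runif(1, -2, 2) +
    matrix(rnorm(nx * ny, 0, 0.4), nx, ny)
  truth <- round((u - min(u)) / (max(u) - min(u)) * (L - 1)) + 1
  D <- matrix(0, nx * ny, L)
  for (v in seq_len(nx * ny)) {
    t0 <- truth[v]
    valley <- (seq_len(L) - t0)^2 * runif(1, 0.5, 1.5)
    t1 <- (t0 + L %/% 2 - 1) %% L + 1
    swap <- (seq_len(L) - t1)^2 * runif(1, 0.5, 1.5) + runif(1, 0.1, 1)
    D[v, ] <- pmin(valley, swap) + rnorm(L, 0, 0.15)^2
  }
  D
}

# central finite-difference Jacobian of gre_signal w.r.t. the 6 parameters
fd_jacobian <- function(params, model, protocol, h = 1e-6) {
  p0 <- unlist(params)[c("rho_w", "phi_w", "rho_f", "phi_f", "delta_f",
                         "r2s")]
  sapply(seq_along(p0), function(k) {
    pp <- p0; pp[k] <- pp[k] + h
    pm <- p0; pm[k] <- pm[k] - h
    sp <- do.call(voxel_params, as.list(pp))
    sm <- do.call(voxel_params, as.list(pm))
    (gre_signal(sp, model, protocol) - gre_signal(sm, model, protocol)) /
      (2 * h)
  })
}

# PDFF slope along the readout (first) axis within a mask, in percentage
# points across the field of view
readout_gradient_pp <- function(pdff, mask) {
  nx <- nrow(pdff)
  prof <- sapply(seq_len(nx), function(i) {
    m <- mask[i, ]
    if (any(m)) mean(pdff[i, m]) else NA_real_
  })
  ok <- !is.na(prof)
  unname(stats::coef(stats::lm(prof[ok] ~ seq_len(nx)[ok]))[2]) * nx * 100
}

# count of fat-water-swapped voxels relative to truth over a mask
count_swaps <- function(pdff, truth, mask) {
  sum((abs(pdff - (1 - truth)) < abs(pdff - truth)) & mask)
}
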