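# VARPRO inner solves: for fixed off-resonance and R2*, the complex water
# and fat amplitudes enter the signal model linearly and are obtained by a
# two-column complex least-squares fit; the projection residual is the
# objective that the field-map search minimizes.

# Fast two-column complex least squares of y on A = [env, cn*env].
# Returns water/fat amplitudes and the residual norm. Near-collinear columns
# (echo times aliasing fat against water) fall back to a pseudo-inverse
# both-amplitudes solution and are flagged.
varpro_solve <- function(y, te, cn, delta_f, r2s) {
  env <- exp((1i * 2 * pi * delta_f - r2s) * te)
  a1 <- env
  a2 <- cn * env
  g11 <- sum(Mod(a1)^2)
  g22 <- sum(Mod(a2)^2)
  g12 <- sum(Conj(a1) * a2)
  b1 <- sum(Conj(a1) * y)
  b2 <- sum(Conj(a2) * y)
  det <- g11 * g22 - Mod(g12)^2
  rank_deficient <- det <= 1e-12 * g11 * g22
  if (!rank_deficient) {
    w <- (g22 * b1 - g12 * b2) / det
    f <- (g11 * b2 - Conj(g12) * b1) / det
  } else {
    # pseudo-inverse via SVD of the 2-column design
    A <- cbind(a1, a2)
    sv <- svd(A)
    keep <- sv$d > 1e-10 * max(sv$d)
    x <- sv$v[, keep, drop = FALSE] %*%
      ((Conj(t(sv$u[, keep, drop = FALSE])) %*% y) / sv$d[keep])
    w <- x[1]; f <- x[2]
  }
  r <- y - (w * a1 + f * a2)
  list(water = w, fat = f, residual = sqrt(sum(Mod(r)^2)),
       rank_deficient = rank_deficient)
}

#' VARPRO water/fat amplitude solve at fixed off-resonance and R2*
#'
#' Linear least-squares fit of the complex water and fat amplitudes given a
#' candidate field-map frequency and R2*. At the true (noiseless) parameters
#' the residual is zero and the amplitudes equal the truth. Echo-time
#' configurations that make the water and fat columns collinear are solved by
#' pseudo-inverse and flagged `rank_deficient`.
#'
#' @param signal Complex echo vector (>= 3 echoes).
#' @param te_list Echo times in seconds.
#' @param fat_model A [fat_model()].
#' @param b0 Field strength (T).
#' @param delta_f Candidate off-resonance (Hz).
#' @param r2s Candidate R2* (Hz).
#' @return List with complex `water`, `fat`, the `residual` norm, and
#'   `rank_deficient`.
#' @export
varpro_decompose <- function(signal, te_list, fat_model, b0, delta_f, r2s) {
  stopifnot(length(signal) >= 3, length(signal) == length(te_list))
  cn <- fat_phasor(fat_model, b0, te_list)
  varpro_solve(signal, te_list, cn, delta_f, r2s)
}

#' Fat-water separation configuration
#'
#' Defaults follow the graph-cut separation setup used throughout the
#' package: 50 iterations, an R2* search grid of 101 values from 0 to 400 Hz
#' and an off-resonance grid of 401 values from -300 to 300 Hz.
#'
#' @param n_iterations Graph-cut iterations (binary jump moves; default 50).
#' @param r2s_grid R2* candidates in Hz (strictly increasing).
#' @param offres_grid Off-resonance candidates in Hz (strictly increasing,
#'   uniformly spaced).
#' @param regularization_weight Field-map smoothness weight `lambda`
#'   (unary units per Hz); `NULL` selects a default proportional to the mean
#'   unary curvature at the per-voxel residual minimum.
#' @param neighborhood 4 or 8 connectivity for the smoothness term.
#' @param fat_model A [fat_model()].
#' @param mask_quantile,mask_fraction Background threshold: voxels whose
#'   first-echo magnitude is below `mask_fraction` times the
#'   `mask_quantile` quantile of first-echo magnitudes are masked out
#'   (defaults: 5% of the 99th percentile).
#' @param move_steps Jump-move step sizes in grid units; the fat-water
#'   beat-frequency step is appended automatically.
#' @param center_bias Relative strength of a weak quadratic preference for
#'   off-resonances near the grid center, added to the unary term as
#'   `center_bias * median(signal energy) * (f / f_max)^2`. The fat-water
#'   swap ambiguity makes the residual landscape (near-)degenerate between
#'   a field branch and a swapped branch of identical smoothness; spatial
#'   regularization enforces a coherent branch per region but cannot choose
#'   between globally equivalent branches, so the algorithm — like complex
#'   FWS implementations generally — assumes the true field map is centered.
#'   The default `1e-2` is a few times the noise floor of the residual,
#'   i.e. a tie-breaker, not a constraint on genuine off-center fields.
#' @return Object of class `fws_config`.
#' @export
fws_config <- function(n_iterations = 50,
                       r2s_grid = seq(0, 400, length.out = 101),
                       offres_grid = seq(-300, 300, length.out = 401),
                       regularization_weight = NULL,
                       neighborhood = 4,
                       fat_model = pdffmap::fat_model("invivo"),
                       mask_quantile = 0.99, mask_fraction = 0.05,
                       move_steps = c(1, 2, 5, 10),
                       center_bias = 1e-2) {
  stopifnot(n_iterations >= 1, all(diff(r2s_grid) > 0),
            all(diff(offres_grid) > 0), neighborhood %in% c(4, 8),
            is.null(regularization_weight) || regularization_weight >= 0,
            center_bias >= 0)
  structure(list(n_iterations = n_iterations, r2s_grid = r2s_grid,
                 offres_grid = offres_grid,
                 regularization_weight = regularization_weight,
                 neighborhood = neighborhood, fat_model = fat_model,
                 mask_quantile = mask_quantile,
                 mask_fraction = mask_fraction,
                 move_steps = move_steps,
                 center_bias = center_bias),
            class = "fws_config")
}

# Orthonormal bases of the two-column designs for every (offres, r2s) grid
# combination, vectorized Gram-Schmidt. Returns per-offres stacked basis
# matrices (n_echoes x 2 n_r2s); a zero second column marks rank-deficient
# designs (projection falls back to rank 1).
varpro_bases <- function(te, cn, offres_grid, r2s_grid) {
  ne <- length(te)
  G <- expand.grid(r2s = r2s_grid, df = offres_grid)  # r2s fastest
  ex <- exp(outer(te, 1i * 2 * pi * G$df - G$r2s))    # ne x (nr*nl)
  a2 <- ex * cn
  n1 <- sqrt(colSums(Mod(ex)^2))
  q1 <- ex / rep(n1, each = ne)
  pr <- colSums(Conj(q1) * a2)
  v <- a2 - q1 * rep(pr, each = ne)
  n2 <- sqrt(colSums(Mod(v)^2))
  bad <- n2 <= 1e-8 * sqrt(colSums(Mod(a2)^2))
  n2[bad] <- 1
  q2 <- v / rep(n2, each = ne)
  q2[, bad] <- 0
  nr <- length(r2s_grid)
  lapply(seq_along(offres_grid), function(l) {
    cols <- (l - 1) * nr + seq_len(nr)
    qq <- matrix(0i, ne, 2 * nr)
    qq[, 2 * seq_len(nr) - 1] <- q1[, cols]
    qq[, 2 * seq_len(nr)] <- q2[, cols]
    qq
  })
}

#' Residual lattice over the off-resonance grid
#'
#' For every voxel and every off-resonance candidate, minimizes the VARPRO
#' residual over the R2* grid. This is the unary ("data") term of the
#' graph-cut field-map estimation.
#'
#' @param series An [echo_series()].
#' @param config An [fws_config()].
#' @param voxels Optional integer indices (into the flattened spatial grid)
#'   restricting the computation; default all voxels.
#' @return List with `residual` (voxels x off-resonance matrix of residual
#'   norms, minimized over R2*), `r2s_index` (integer matrix of argmin R2*
#'   indices), `voxels`, and the grids.
#' @export
residual_lattice <- function(series, config, voxels = NULL) {
  stopifnot(inherits(series, "echo_series"), inherits(config, "fws_config"))
  d <- dim(series$data)
  ne <- d[length(d)]
  nvox_total <- prod(d[-length(d)])
  if (is.null(voxels)) voxels <- seq_len(nvox_total)
  Y <- t(matrix(series$data, nvox_total, ne)[voxels, , drop = FALSE])
  te <- series$protocol$te
  cn <- fat_phasor(config$fat_model, series$protocol$b0, te)
  bases <- varpro_bases(te, cn, config$offres_grid, config$r2s_grid)
  nv <- length(voxels)
  nl <- length(config$offres_grid)
  nr <- length(config$r2s_grid)
  y2 <- colSums(Mod(Y)^2)
  res <- matrix(0, nv, nl)
  idx <- matrix(1L, nv, nl)
  odd <- 2 * seq_len(nr) - 1
  for (l in seq_len(nl)) {
    Pv <- Mod(crossprod(Conj(bases[[l]]), Y))^2      # 2nr x nv
    proj <- Pv[odd, , drop = FALSE] + Pv[odd + 1, , drop = FALSE]
    best <- max.col(t(proj), ties.method = "first")  # per-voxel argmax
    idx[, l] <- best
    res[, l] <- sqrt(pmax(y2 - proj[cbind(best, seq_len(nv))], 0))
  }
  list(residual = res, r2s_index = idx, voxels = voxels,
       offres_grid = config$offres_grid, r2s_grid = config$r2s_grid)
}
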