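# Full complex-data fat-water separation: residual lattice -> graph-cut
# field map -> final per-voxel VARPRO amplitude solve, plus the mixed
# magnitude/complex refinement for first-echo phase errors.

new_fws_result <- function(water, fat, field_map, r2s_map, energy_trace,
                           mask, config, lambda) {
  structure(list(water = water, fat = fat,
                 water_mag = Mod(water), fat_mag = Mod(fat),
                 field_map = field_map, r2s_map = r2s_map,
                 energy_trace = energy_trace, mask = mask,
                 config = config, lambda = lambda),
            class = "fws_result")
}

#' @export
print.fws_result <- function(x, ...) {
  cat(sprintf("<fws_result %d x %d: %d voxels in mask, lambda = %.3g>\n",
              nrow(x$water_mag), ncol(x$water_mag), sum(x$mask), x$lambda))
  invisible(x)
}

#' Complex-data fat-water separation with graph-cut field map
#'
#' Pipeline: background masking (first-echo magnitude threshold), VARPRO
#' residual lattice over the off-resonance/R2* grids, graph-cut field-map
#' estimation with a total-variation smoothness prior, and a final per-voxel
#' amplitude solve at the selected (off-resonance, R2*). Masked voxels
#' report zeros.
#'
#' @param series An [echo_series()].
#' @param config An [fws_config()].
#' @param mask Optional logical matrix overriding the magnitude-threshold
#'   background mask.
#' @return An `fws_result` with complex `water`/`fat` maps, their
#'   magnitudes, `field_map` (Hz), `r2s_map` (Hz), the graph-cut
#'   `energy_trace`, and the `mask`.
#' @export
separate <- function(series, config = fws_config(), mask = NULL) {
  stopifnot(inherits(series, "echo_series"), inherits(config, "fws_config"))
  d <- dim(series$data)
  nx <- d[1]; ny <- d[2]
  mag1 <- Mod(series$data[, , 1])
  if (is.null(mask)) {
    thr <- config$mask_fraction *
      stats::quantile(mag1, config$mask_quantile, names = FALSE)
    mask <- mag1 > thr
  }
  zero <- matrix(0, nx, ny)
  if (!any(mask)) {
    return(new_fws_result(zero + 0i, zero + 0i, zero, zero, numeric(0),
                          mask, config, 0))
  }
  vox <- which(mask)
  lat <- residual_lattice(series, config, voxels = vox)
  unary <- lat$residual^2
  if (config$center_bias > 0) {
    ne <- dim(series$data)[3]
    y2 <- rowSums(Mod(matrix(series$data, nx * ny, ne)[vox, ,
                                                       drop = FALSE])^2)
    fmax <- max(abs(config$offres_grid))
    unary <- unary + config$center_bias * stats::median(y2) *
      outer(rep(1, length(vox)), (config$offres_grid / fmax)^2)
  }
  gc <- fieldmap_graphcut(unary, config$offres_grid,
                          regularization_weight = config$regularization_weight,
                          neighborhood = config$neighborhood,
                          n_iterations = config$n_iterations,
                          dims = c(nx, ny), mask = mask,
                          move_steps = config$move_steps,
                          beat_hz = 1 / beat_period(config$fat_model,
                                                    series$protocol$b0),
                          alias_hz = 1 / mean(diff(series$protocol$te)))
  r2s_idx <- lat$r2s_index[cbind(seq_along(vox), gc$labels)]
  te <- series$protocol$te
  cn <- fat_phasor(config$fat_model, series$protocol$b0, te)
  Y <- t(matrix(series$data, nx * ny, length(te))[vox, , drop = FALSE])
  water <- zero + 0i; fat <- zero + 0i
  field <- zero; r2s_map <- zero
  # group voxels sharing the same (offres, r2s) grid point: one basis solve
  key <- paste(gc$labels, r2s_idx)
  for (grp in split(seq_along(vox), key)) {
    l <- gc$labels[grp[1]]; j <- r2s_idx[grp[1]]
    env <- exp((1i * 2 * pi * config$offres_grid[l] -
                config$r2s_grid[j]) * te)
    A <- cbind(env, cn * env)
    G <- Conj(t(A)) %*% A
    x <- solve(G, Conj(t(A)) %*% Y[, grp, drop = FALSE])
    water[vox[grp]] <- x[1, ]
    fat[vox[grp]] <- x[2, ]
    field[vox[grp]] <- config$offres_grid[l]
    r2s_map[vox[grp]] <- config$r2s_grid[j]
  }
  new_fws_result(water, fat, field, r2s_map, gc$energy_trace, mask, config,
                 gc$lambda)
}

#' Mixed magnitude/complex fitting refinement
#'
#' Voxelwise nonlinear least squares of the six-parameter signal model in
#' which echo 1 contributes only its magnitude (one real residual) while all
#' later echoes contribute full complex residuals (two each). This discards
#' the phase of the first echo, the component most affected by eddy-current
#' phase errors, while keeping the chemical-shift information of the
#' remaining echoes. Each voxel is initialized at the graph-cut solution;
#' voxels that fail to converge fall back to their initial values and are
#' flagged.
#'
#' @param series The [echo_series()] that produced `init`.
#' @param init An `fws_result` from [separate()].
#' @param fat_model A [fat_model()] (defaults to the one in `init$config`).
#' @return An `fws_result` with refined maps and an added logical
#'   `refit_failed` matrix.
#' @export
mixed_fit_refine <- function(series, init, fat_model = NULL) {
  stopifnot(inherits(series, "echo_series"), inherits(init, "fws_result"))
  if (is.null(fat_model)) fat_model <- init$config$fat_model
  te <- series$protocol$te
  ne <- length(te)
  stopifnot(ne >= 3)
  cn <- fat_phasor(fat_model, series$protocol$b0, te)
  d <- dim(series$data)
  vox <- which(init$mask)
  Y <- t(matrix(series$data, d[1] * d[2], ne)[vox, , drop = FALSE])
  out <- init
  out$refit_failed <- matrix(FALSE, d[1], d[2])
  model_sig <- function(p) {
    (p[1] * exp(1i * p[2]) + p[3] * exp(1i * p[4]) * cn) *
      exp((1i * 2 * pi * p[5] - max(p[6], 0)) * te)
  }
  for (i in seq_along(vox)) {
    v <- vox[i]
    y <- Y[, i]
    p0 <- c(init$water_mag[v], Arg(init$water[v]),
            init$fat_mag[v], Arg(init$fat[v]),
            init$field_map[v], init$r2s_map[v])
    resid_fn <- function(p) {
      m <- model_sig(p)
      c(Mod(m[1]) - Mod(y[1]),
        Re(m[-1] - y[-1]), Im(m[-1] - y[-1]))
    }
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 60))),
      error = function(e) NULL)
    ok <- !is.null(fit) && is.finite(fit$deviance) &&
      fit$deviance <= sum(resid_fn(p0)^2) + 1e-12
    if (ok) {
      p <- fit$par
      # fold negative magnitudes into the phase
      if (p[1] < 0) { p[1] <- -p[1]; p[2] <- p[2] + pi }
      if (p[3] < 0) { p[3] <- -p[3]; p[4] <- p[4] + pi }
      out$water[v] <- p[1] * exp(1i * p[2])
      out$fat[v] <- p[3] * exp(1i * p[4])
      out$field_map[v] <- p[5]
      out$r2s_map[v] <- max(p[6], 0)
    } else {
      out$refit_failed[v] <- TRUE
    }
  }
  out$water_mag <- Mod(out$water)
  out$fat_mag <- Mod(out$fat)
  out
}
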