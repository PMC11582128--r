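# Effective number of signal averages (NSA*) via Cramer-Rao lower bounds.
#
# NSA*(p_k) = sigma^2(p_k) / sigma^2(p_k_hat): the numerator is the minimum
# variance attainable when p_k is the ONLY unknown model parameter, referred
# to a single acquired echo (N / I_kk, i.e. the single-unknown CRLB of the
# average per-echo information); the denominator is the CRLB variance with
# the full unknown set (the k-th diagonal of the pseudo-inverse of the
# Fisher matrix). Both scale identically with noise and overall signal
# level, so NSA* depends only on the echo times, the fat model, PDFF,
# off-resonance and R2*. Perfectly independent echoes give NSA* = N (the
# estimate is as precise as averaging N images); echo spacings that repeat
# the fat-water phase relation give redundant information, a diverging
# bound, and NSA* = 0.

# relative eigenvalue cutoff for pseudo-inversion of degenerate Fisher
# matrices (PDFF exactly 0 or 1 makes one phase unidentifiable)
.pinv_tol <- 1e-10

#' Analytic Jacobian of the GRE signal w.r.t. the six voxel parameters
#'
#' Entry (n, k) is the complex partial derivative of echo `n` with respect to
#' parameter `k`, in the order `rho_w, phi_w, rho_f, phi_f, delta_f, r2s`.
#'
#' @inheritParams gre_signal
#' @return Complex matrix, `n_echoes x 6`, with column names.
#' @export
signal_jacobian <- function(params, model, protocol) {
  te <- protocol$te
  cn <- fat_phasor(model, protocol$b0, te)
  ew <- exp(1i * params$phi_w)
  ef <- exp(1i * params$phi_f)
  env <- exp((1i * 2 * pi * params$delta_f - params$r2s) * te)
  s <- (params$rho_w * ew + params$rho_f * ef * cn) * env
  J <- cbind(rho_w   = ew * env,
             phi_w   = 1i * params$rho_w * ew * env,
             rho_f   = ef * cn * env,
             phi_f   = 1i * params$rho_f * ef * cn * env,
             delta_f = 1i * 2 * pi * te * s,
             r2s     = -te * s)
  J
}

#' Fisher information matrix for complex Gaussian noise
#'
#' For i.i.d. circular complex Gaussian noise,
#' `I_jk = (2 / noise_sd^2) sum_n Re(conj(ds_n/dp_j) ds_n/dp_k)`,
#' where `noise_sd` is the total complex noise standard deviation (real and
#' imaginary channels each carry variance `noise_sd^2 / 2`). NSA* is a
#' variance ratio, so this scale convention cancels there.
#'
#' @inheritParams gre_signal
#' @param noise_sd Complex noise standard deviation (> 0); per-channel SD
#'   times `sqrt(2)`.
#' @return Symmetric positive semidefinite 6 x 6 matrix.
#' @export
fisher_matrix <- function(params, model, protocol, noise_sd = 1) {
  stopifnot(noise_sd > 0)
  J <- signal_jacobian(params, model, protocol)
  I <- (2 / noise_sd^2) * Re(crossprod(Conj(J), J))
  (I + t(I)) / 2  # symmetrize roundoff
}

# NSA* for every parameter in `unknown` (indices into 1:6) given a Fisher
# matrix computed at unit noise. Returns a length-6 vector, NA outside the
# unknown set. Degenerate directions (information in the null space) give 0.
nsa_from_fisher <- function(I, unknown = 1:6, n_echoes) {
  Iu <- I[unknown, unknown, drop = FALSE]
  eg <- eigen(Iu, symmetric = TRUE)
  d <- eg$values
  keep <- d > .pinv_tol * max(d, 0)
  out <- rep(NA_real_, 6)
  for (j in seq_along(unknown)) {
    k <- unknown[j]
    ikk <- I[k, k]
    if (ikk <= 0) { out[k] <- 0; next }
    vk <- eg$vectors[j, ]
    if (any(!keep & abs(vk) > 1e-6)) { out[k] <- 0; next }  # variance diverges
    denom <- sum(vk[keep]^2 / d[keep])     # (pseudo-inverse)_kk
    out[k] <- min(max(n_echoes / (ikk * denom), 0), n_echoes)
  }
  names(out) <- param_names
  out
}

#' NSA* of one model parameter
#'
#' @inheritParams gre_signal
#' @param param Parameter name or index (order `rho_w, phi_w, rho_f, phi_f,
#'   delta_f, r2s`).
#' @param include_r2s Logical; if `FALSE`, R2* is treated as known and
#'   excluded from the unknown set (the classical setting in which the
#'   maximum NSA* equals the number of echoes).
#' @return Dimensionless scalar in `[0, n_echoes]`; degenerate cases
#'   (no single-parameter information, or a diverging full-model bound)
#'   return 0.
#' @export
nsa_star <- function(params, model, protocol, param, include_r2s = TRUE) {
  if (is.character(param)) param <- match(param, param_names)
  stopifnot(param %in% 1:6)
  I <- fisher_matrix(params, model, protocol, noise_sd = 1)
  unknown <- if (include_r2s) 1:6 else 1:5
  if (!param %in% unknown) stop("param is excluded from the unknown set")
  nsa_from_fisher(I, unknown, n_echoes = length(protocol$te))[param]
}

#' Scan NSA* over a (TE1, dTE) grid
#'
#' Fills a 4-D grid of NSA* values over first echo time, echo spacing, PDFF
#' and the six model parameters. The default grid reproduces the protocol-
#' optimization setting: TE1 and dTE from 0.5 to 5 ms in 0.05 ms steps
#' (91 x 91 combinations), six echoes, a single fat peak at -3.3 ppm,
#' R2* = 50 Hz, and total magnitude `rho_w + rho_f = 1` so grids are
#' comparable across PDFF.
#'
#' @param model A [fat_model()]; default single peak at -3.3 ppm.
#' @param b0 Field strength (T).
#' @param te1_range,dte_range Ranges in seconds (default 0.5-5 ms).
#' @param step Grid step in seconds (default 0.05 ms).
#' @param pdff_values PDFF fractions to evaluate (default 0, 5, 25, 50, 75,
#'   100%).
#' @param r2s True R2* in Hz (default 50).
#' @param n_echoes Number of equidistant echoes (default 6).
#' @param include_r2s Include R2* in the unknown parameter set (default
#'   `TRUE`, the full six-parameter fit); if `FALSE` the R2* slice of the
#'   grid is `NA`.
#' @param delta_f True off-resonance (Hz, default 0).
#' @return Object of class `nsa_grid`: list with `te1`, `dte`, `pdff`,
#'   `param`, the 4-D array `nsa` (te1 x dte x pdff x param) and `settings`.
#' @export
nsa_grid_scan <- function(model = single_peak_model(), b0,
                          te1_range = c(0.5e-3, 5e-3),
                          dte_range = c(0.5e-3, 5e-3),
                          step = 0.05e-3,
                          pdff_values = c(0, 0.05, 0.25, 0.5, 0.75, 1),
                          r2s = 50, n_echoes = 6, include_r2s = TRUE,
                          delta_f = 0) {
  stopifnot(all(te1_range > 0), all(dte_range > 0), step > 0,
            all(pdff_values >= 0), all(pdff_values <= 1))
  te1_values <- seq(te1_range[1], te1_range[2], by = step)
  dte_values <- seq(dte_range[1], dte_range[2], by = step)
  nyq <- nyquist_dte(dominant_shift(model), b0)
  if (min(dte_values) > nyq) {
    warning(sprintf(paste("entire dTE range is above the Nyquist spacing",
                          "%.3g ms; fat-water phase oscillation is",
                          "undersampled everywhere"), nyq * 1e3))
  }
  unknown <- if (include_r2s) 1:6 else 1:5
  nsa <- array(NA_real_,
               dim = c(length(te1_values), length(dte_values),
                       length(pdff_values), 6),
               dimnames = list(NULL, NULL, NULL, param_names))
  for (i in seq_along(te1_values)) {
    for (j in seq_along(dte_values)) {
      te <- te1_values[i] + dte_values[j] * (seq_len(n_echoes) - 1)
      cn <- fat_phasor(model, b0, te)
      env <- exp((1i * 2 * pi * delta_f - r2s) * te)
      for (q in seq_along(pdff_values)) {
        rw <- 1 - pdff_values[q]
        rf <- pdff_values[q]
        s <- (rw + rf * cn) * env
        J <- cbind(env, 1i * rw * env, cn * env, 1i * rf * cn * env,
                   1i * 2 * pi * te * s, -te * s)
        I <- 2 * Re(crossprod(Conj(J), J))
        nsa[i, j, q, ] <- nsa_from_fisher((I + t(I)) / 2, unknown, n_echoes)
      }
    }
  }
  structure(list(te1 = te1_values, dte = dte_values, pdff = pdff_values,
                 param = param_names, nsa = nsa,
                 settings = list(model = model, b0 = b0, r2s = r2s,
                                 n_echoes = n_echoes,
                                 include_r2s = include_r2s,
                                 delta_f = delta_f, step = step)),
            class = "nsa_grid")
}

#' @export
print.nsa_grid <- function(x, ...) {
  cat(sprintf(
    "<nsa_grid: %d x %d (TE1 x dTE) at B0 = %g T, %d PDFF value(s)>\n",
    length(x$te1), length(x$dte), x$settings$b0, length(x$pdff)))
  invisible(x)
}

# NSA* at a single protocol (helper used by reports/tests)
nsa_at <- function(protocol, pdff, model = single_peak_model(), r2s = 50,
                   include_r2s = TRUE) {
  p <- voxel_params(rho_w = 1 - pdff, rho_f = pdff, r2s = r2s)
  I <- fisher_matrix(p, model, protocol, noise_sd = 1)
  nsa_from_fisher(I, if (include_r2s) 1:6 else 1:5, length(protocol$te))
}

#' Maximum-likelihood fit of the six-parameter voxel model
#'
#' Grid-initialized local least squares: a VARPRO sweep of candidate
#' off-resonances (restricted to a window around `delta_f_init` to stay in
#' the correct basin of the fat-water ambiguity) and coarse R2* values picks
#' the starting point; a Levenberg-Marquardt refinement of all six real
#' parameters against the stacked real/imaginary residuals returns the ML
#' estimate (least squares is ML under Gaussian noise).
#'
#' @param signal Complex echo vector.
#' @param model A [fat_model()].
#' @param protocol An [acquisition_protocol()].
#' @param delta_f_init Center of the off-resonance search window (Hz).
#' @param window Half-width of the search window in Hz (default: 45% of the
#'   fat-water beat frequency, which keeps the search inside one basin).
#' @param r2s_init Coarse R2* candidates (Hz).
#' @return Named numeric vector of the six parameter estimates.
#' @export
ml_fit_voxel <- function(signal, model, protocol, delta_f_init = 0,
                         window = NULL,
                         r2s_init = c(0, 25, 50, 100, 200)) {
  te <- protocol$te
  cn <- fat_phasor(model, protocol$b0, te)
  if (is.null(window)) window <- 0.45 / beat_period(model, protocol$b0)
  df_grid <- delta_f_init + seq(-window, window, length.out = 31)
  best <- NULL; best_res <- Inf
  for (df in df_grid) for (r2 in r2s_init) {
    dec <- varpro_solve(signal, te, cn, df, r2)
    if (dec$residual < best_res) {
      best_res <- dec$residual
      best <- c(Mod(dec$water), Arg(dec$water), Mod(dec$fat), Arg(dec$fat),
                df, r2)
    }
  }
  resid_fn <- function(p) {
    pr <- voxel_params(max(p[1], 0), p[2], max(p[3], 0), p[4], p[5],
                       max(p[6], 0))
    m <- gre_signal(pr, model, protocol)
    c(Re(m - signal), Im(m - signal))
  }
  fit <- minpack.lm::nls.lm(par = best, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ptol = 1e-10, ftol = 1e-10))
  est <- fit$par
  est[c(1, 3, 6)] <- pmax(est[c(1, 3, 6)], 0)
  names(est) <- param_names
  est
}

#' Monte-Carlo check of the CRLB variance
#'
#' Draws repeated complex-Gaussian noise realizations of a voxel signal,
#' refits the six-parameter model by [ml_fit_voxel()], and compares the
#' empirical estimator variances with the CRLB (diagonal of the inverse
#' Fisher matrix). At high SNR the ML estimator attains the bound, so the
#' ratios should be close to 1.
#'
#' @inheritParams gre_signal
#' @param noise_sd Noise SD per real/imaginary channel (as in
#'   [simulate_acquisition()]; the CRLB uses the matching complex SD
#'   `noise_sd * sqrt(2)`).
#' @param n_draws Number of noise realizations (>= 100 recommended).
#' @param seed RNG seed.
#' @param params_check Parameter names to report (default all six).
#' @return Data frame with columns `param`, `empirical_var`, `crlb_var`,
#'   `ratio`.
#' @export
crlb_mc_check <- function(params, model, protocol, noise_sd, n_draws = 2000,
                          seed = 1, params_check = param_names) {
  s0 <- gre_signal(params, model, protocol)
  n <- length(s0)
  I <- fisher_matrix(params, model, protocol, noise_sd * sqrt(2))
  crlb <- diag(solve(I))
  set.seed(seed)
  est <- matrix(NA_real_, n_draws, 6)
  for (d in seq_len(n_draws)) {
    y <- s0 + complex(real = stats::rnorm(n, sd = noise_sd),
                      imaginary = stats::rnorm(n, sd = noise_sd))
    est[d, ] <- ml_fit_voxel(y, model, protocol,
                             delta_f_init = params$delta_f)
  }
  # phases: wrap estimates into the truth-centered interval before taking
  # variances (irrelevant at high SNR, protects against stray wraps)
  truth <- unlist(params)[param_names]
  for (k in c(2, 4)) {
    est[, k] <- truth[k] + atan2(sin(est[, k] - truth[k]),
                                 cos(est[, k] - truth[k]))
  }
  idx <- match(params_check, param_names)
  data.frame(param = param_names[idx],
             empirical_var = apply(est[, idx, drop = FALSE], 2, stats::var),
             crlb_var = crlb[idx],
             ratio = apply(est[, idx, drop = FALSE], 2, stats::var) /
               crlb[idx])
}
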