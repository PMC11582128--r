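# Simulated multi-echo acquisitions of digital phantoms.

#' Construct an echo series
#'
#' Container for a complex multi-echo image stack: a complex array with the
#' echo index as the last dimension, the acquisition protocol, the noise
#' level, and provenance (generator settings and seed, when simulated).
#'
#' @param data Complex array, spatial dims x echoes.
#' @param protocol An [acquisition_protocol()]; echo count must match the
#'   last dimension of `data`.
#' @param noise_sd Per-channel complex noise SD (a.u.).
#' @param provenance Free-form list recording how the series was made.
#' @return Object of class `echo_series`.
#' @export
echo_series <- function(data, protocol, noise_sd = 0, provenance = list()) {
  stopifnot(is.complex(data) || is.numeric(data),
            inherits(protocol, "acq_protocol"))
  d <- dim(data)
  if (d[length(d)] != length(protocol$te)) {
    stop("echo count of data does not match protocol")
  }
  structure(list(data = data + 0i, protocol = protocol,
                 noise_sd = noise_sd, provenance = provenance),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_series: %s voxels x %d echoes, B0 = %g T>\n",
              paste(d[-length(d)], collapse = " x "), d[length(d)],
              x$protocol$b0))
  invisible(x)
}

n_echoes <- function(series) dim(series$data)[length(dim(series$data))]

#' Per-channel noise SD for a target SNR
#'
#' SNR is defined throughout the package as signal magnitude divided by the
#' total complex noise standard deviation; the real and imaginary channels
#' then each carry SD `1 / (snr sqrt(2))` (for unit signal magnitude).
#'
#' @param snr Target signal-to-noise ratio (> 0).
#' @param magnitude Signal magnitude the SNR refers to (default 1).
#' @return Per-channel noise SD for [simulate_acquisition()].
#' @export
snr_noise_sd <- function(snr, magnitude = 1) {
  stopifnot(snr > 0)
  magnitude / (snr * sqrt(2))
}

# spatial matrix of one echo
echo_image <- function(series, n) series$data[, , n]

#' Simulate a multi-echo GRE acquisition of a digital phantom
#'
#' Applies the forward signal model voxelwise using the phantom's truth maps
#' (water magnitude `rho (1 - pdff)`, fat magnitude `rho pdff`, common
#' initial phase `phi0`, off-resonance `b0`, relaxation `r2s`) and adds
#' i.i.d. circular complex Gaussian noise. Deterministic given `seed`.
#'
#' @param phantom A `digital_phantom`.
#' @param model A [fat_model()].
#' @param protocol An [acquisition_protocol()].
#' @param noise_sd Noise SD per real/imaginary channel (>= 0); for a target
#'   SNR (signal magnitude over total complex noise SD) use
#'   [snr_noise_sd()].
#' @param seed RNG seed (recorded in provenance; `NULL` leaves the RNG
#'   state alone).
#' @return An [echo_series()] of dimension `nx x ny x n_echoes`.
#' @export
simulate_acquisition <- function(phantom, model, protocol, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(inherits(phantom, "digital_phantom"), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  te <- protocol$te
  cn <- fat_phasor(model, protocol$b0, te)
  W <- phantom$rho * (1 - phantom$pdff) * exp(1i * phantom$phi0)
  F <- phantom$rho * phantom$pdff * exp(1i * phantom$phi0)
  nx <- phantom$shape[1]; ny <- phantom$shape[2]
  data <- array(0i, dim = c(nx, ny, length(te)))
  for (n in seq_along(te)) {
    s <- (W + F * cn[n]) *
      exp((1i * 2 * pi * phantom$b0 - phantom$r2s) * te[n])
    if (noise_sd > 0) {
      s <- s + complex(real = stats::rnorm(nx * ny, sd = noise_sd),
                       imaginary = stats::rnorm(nx * ny, sd = noise_sd))
    }
    data[, , n] <- s
  }
  echo_series(data, protocol, noise_sd,
              provenance = list(generator = "simulate_acquisition",
                                seed = seed, noise_sd = noise_sd,
                                fat_model = model$name))
}

#' Impose eddy-current-like phase ramps along the readout direction
#'
#' Multiplies echo images by a spatially linear phase
#' `phi(x) = first_echo_phase + readout_gradient (x - center)` along the
#' protocol's readout axis. In `"first-echo-only"` mode only echo 1 is
#' perturbed (the error targeted by the mixed magnitude/complex fit); in
#' `"all-echoes-linear"` mode every echo receives the ramp, attenuated by
#' `exp(-(TE_n - TE_1)/decay_tau)` to emulate eddy currents decaying over
#' the echo train.
#'
#' @param series An [echo_series()].
#' @param first_echo_phase Spatially constant phase offset (rad) at echo 1.
#' @param readout_gradient Phase slope (rad per voxel) along the readout
#'   axis at echo 1.
#' @param mode `"first-echo-only"` or `"all-echoes-linear"`.
#' @param decay_tau Decay time constant (s) of the ramp amplitude across
#'   echoes in `"all-echoes-linear"` mode (default 2 ms).
#' @return The perturbed `echo_series`.
#' @export
apply_eddy_phase <- function(series, first_echo_phase = 0,
                             readout_gradient = 0,
                             mode = c("first-echo-only", "all-echoes-linear"),
                             decay_tau = 2e-3) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)
  nx <- d[1]; ny <- d[2]
  # readout axis "x" is the first array dimension, "y" the second
  along_x <- series$protocol$readout_axis == "x"
  nr <- if (along_x) nx else ny
  ramp1d <- first_echo_phase + readout_gradient * (seq_len(nr) - (nr + 1) / 2)
  ramp <- if (along_x) matrix(ramp1d, nx, ny) else
    matrix(ramp1d, nx, ny, byrow = TRUE)
  te <- series$protocol$te
  scale <- switch(mode,
    "first-echo-only" = c(1, rep(0, length(te) - 1)),
    "all-echoes-linear" = exp(-(te - te[1]) / decay_tau))
  for (n in seq_along(te)) {
    if (scale[n] != 0) {
      series$data[, , n] <- series$data[, , n] * exp(1i * ramp * scale[n])
    }
  }
  series$provenance$eddy <- list(mode = mode,
                                 first_echo_phase = first_echo_phase,
                                 readout_gradient = readout_gradient,
                                 decay_tau = decay_tau)
  series
}
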