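# Multi-peak chemical-shift signal model for spoiled multi-echo GRE.
#
# Conventions (used consistently everywhere in the package):
#   * gyromagnetic ratio gamma/2pi = 42.577 MHz/T, nominal fields 3.0 / 7.0 T;
#   * a positive off-resonance delta_f (Hz) ADVANCES phase with echo time,
#     s ~ exp(+i 2 pi delta_f TE); demodulation applies the conjugate factor;
#   * fat peak shifts are carried in ppm (negative = lower frequency than
#     water) and converted to Hz per field strength, so one fat model serves
#     both 3 T and 7 T.

.gamma_hz_per_t <- 42.577e6

#' Convert a chemical shift in ppm to a frequency offset in Hz
#'
#' @param shift_ppm Chemical shift relative to water (ppm); negative values
#'   are below the water resonance (the dominant methylene fat peak is near
#'   -3.3 ppm).
#' @param b0 Main field strength in Tesla (> 0).
#' @return Frequency offset in Hz, same sign as `shift_ppm`. Vectorized.
#' @examples
#' ppm_to_hz(-3.3, 3)   # about -421.6 Hz
#' @export
ppm_to_hz <- function(shift_ppm, b0) {
  stopifnot(all(b0 > 0))
  shift_ppm * 1e-6 * .gamma_hz_per_t * b0
}

#' Fat spectrum models
#'
#' Named multi-peak fat spectra: peak positions in ppm relative to water and
#' normalized relative amplitudes. Two models are shipped (read from the
#' packaged table `extdata/fat_models.csv`): `"phantom"`, a 9-peak spectrum of
#' a peanut-oil/agarose emulsion, and `"invivo"`, an 8-peak spectrum of
#' subcutaneous adipose tissue, both measured at 7 T by STEAM spectroscopy.
#' A single-peak model is available through [single_peak_model()].
#'
#' @param name `"phantom"` or `"invivo"`.
#' @return An object of class `fat_model`: a list with elements `name`,
#'   `shift_ppm` (distinct ppm shifts) and `rel_amp` (amplitudes, normalized
#'   to sum to 1).
#' @examples
#' fm <- fat_model("invivo")
#' sum(fm$rel_amp)  # 1
#' @export
fat_model <- function(name = c("phantom", "invivo")) {
  name <- match.arg(name)
  path <- system.file("extdata", "fat_models.csv", package = "pdffmap",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$model == name, ]
  new_fat_model(name, tab$shift_ppm, tab$rel_amp)
}

#' @rdname fat_model
#' @param shift_ppm,rel_amp Peak positions (ppm, distinct) and amplitudes for
#'   a custom model; amplitudes are renormalized to sum to 1.
#' @export
new_fat_model <- function(name, shift_ppm, rel_amp) {
  stopifnot(length(shift_ppm) == length(rel_amp),
            length(shift_ppm) >= 1,
            !anyDuplicated(shift_ppm),
            all(rel_amp > 0))
  structure(list(name = name,
                 shift_ppm = as.numeric(shift_ppm),
                 rel_amp = as.numeric(rel_amp) / sum(rel_amp)),
            class = "fat_model")
}

#' @rdname fat_model
#' @export
single_peak_model <- function(shift_ppm = -3.3) {
  new_fat_model(sprintf("single-peak %.2f ppm", shift_ppm), shift_ppm, 1)
}

#' @export
print.fat_model <- function(x, ...) {
  cat(sprintf("<fat_model '%s': %d peak(s)>\n", x$name, length(x$shift_ppm)))
  print(data.frame(shift_ppm = x$shift_ppm, rel_amp = x$rel_amp))
  invisible(x)
}

# ppm of the highest-amplitude peak (used for in-phase checks, Nyquist dTE)
dominant_shift <- function(model) {
  model$shift_ppm[which.max(model$rel_amp)]
}

#' Multi-echo GRE acquisition protocol
#'
#' @param b0 Field strength in Tesla.
#' @param te1 First echo time in seconds (used with `dte`/`n_echoes` for
#'   equidistant echoes), or give `te_list` directly.
#' @param dte Echo spacing in seconds.
#' @param n_echoes Number of echoes (default 6).
#' @param te_list Explicit echo times in seconds (strictly increasing, > 0).
#' @param readout_axis,phase_encode_axis Image-axis labels (must differ);
#'   phase ramps from eddy currents run along the readout axis.
#' @return Object of class `acq_protocol` with elements `b0`, `te`
#'   (seconds), `readout_axis`, `phase_encode_axis`.
#' @examples
#' p <- acquisition_protocol(7, te1 = 1.9e-3, dte = 2.3e-3)
#' p$te * 1e3  # echo times in ms
#' @export
acquisition_protocol <- function(b0, te1 = NULL, dte = NULL, n_echoes = 6,
                                 te_list = NULL,
                                 readout_axis = "x", phase_encode_axis = "y") {
  stopifnot(b0 > 0, readout_axis != phase_encode_axis)
  if (is.null(te_list)) {
    stopifnot(!is.null(te1), !is.null(dte), te1 > 0, dte > 0, n_echoes >= 1)
    te_list <- te1 + dte * (seq_len(n_echoes) - 1)
  }
  stopifnot(all(te_list > 0), all(diff(te_list) > 0))
  structure(list(b0 = b0, te = as.numeric(te_list),
                 readout_axis = readout_axis,
                 phase_encode_axis = phase_encode_axis),
            class = "acq_protocol")
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf("<acq_protocol: B0 = %g T, %d echoes, TE = %s ms>\n",
              x$b0, length(x$te),
              paste(sprintf("%.3g", x$te * 1e3), collapse = ", ")))
  invisible(x)
}

#' Named acquisition protocol presets
#'
#' Six-echo monopolar 3D GRE protocols used for fat-water separation at 3 T
#' and 7 T. TE1 is 2.2 ms at 3 T and 1.9 ms at 7 T (2.2 ms for the shifted
#' variant); the echo spacing is 3.2 / 2.24 ms (high / low NSA*) at 3 T and
#' 2.3 / 2.0 ms at 7 T. The `"7T-shifted"` preset keeps the high-NSA* spacing
#' but delays TE1 by 0.3 ms to reduce first-echo eddy-current phase errors.
#'
#' @param name One of `"3T-lowNSA"`, `"3T-highNSA"`, `"7T-lowNSA"`,
#'   `"7T-highNSA"`, `"7T-shifted"`.
#' @param ... Passed on to [acquisition_protocol()] (e.g. axis labels).
#' @return An `acq_protocol`.
#' @export
protocol_preset <- function(name = c("3T-lowNSA", "3T-highNSA", "7T-lowNSA",
                                     "7T-highNSA", "7T-shifted"), ...) {
  name <- match.arg(name)
  par <- switch(name,
    "3T-lowNSA"  = list(b0 = 3, te1 = 2.2e-3, dte = 2.24e-3),
    "3T-highNSA" = list(b0 = 3, te1 = 2.2e-3, dte = 3.2e-3),
    "7T-lowNSA"  = list(b0 = 7, te1 = 1.9e-3, dte = 2.0e-3),
    "7T-highNSA" = list(b0 = 7, te1 = 1.9e-3, dte = 2.3e-3),
    "7T-shifted" = list(b0 = 7, te1 = 2.2e-3, dte = 2.3e-3))
  acquisition_protocol(par$b0, te1 = par$te1, dte = par$dte, n_echoes = 6, ...)
}

#' Single-voxel signal parameters
#'
#' The six-parameter voxel model: water and fat magnitudes and phases,
#' off-resonance frequency and effective transverse relaxation rate R2*.
#' Water and fat phases are independent (a shared-phase five-parameter
#' variant is selected in the estimation routines, not here).
#'
#' @param rho_w,rho_f Water / fat magnitudes (a.u., >= 0).
#' @param phi_w,phi_f Water / fat phases (rad).
#' @param delta_f Off-resonance (field-map) frequency in Hz.
#' @param r2s R2* relaxation rate in Hz (>= 0).
#' @return Object of class `voxel_params`.
#' @export
voxel_params <- function(rho_w, phi_w = 0, rho_f = 0, phi_f = 0,
                         delta_f = 0, r2s = 0) {
  stopifnot(rho_w >= 0, rho_f >= 0, r2s >= 0)
  structure(list(rho_w = rho_w, phi_w = phi_w, rho_f = rho_f, phi_f = phi_f,
                 delta_f = delta_f, r2s = r2s),
            class = "voxel_params")
}

param_names <- c("rho_w", "phi_w", "rho_f", "phi_f", "delta_f", "r2s")

#' Complex fat phasor at given echo time(s)
#'
#' Sum of the fat model's peaks, `sum_p a_p exp(i 2 pi f_p(b0) te)`, the
#' dimensionless complex weight that multiplies the fat magnitude in the GRE
#' signal model. Its magnitude is at most 1, with equality at te = 0.
#'
#' @param model A [fat_model()].
#' @param b0 Field strength (T).
#' @param te Echo time(s) in seconds (>= 0). Vectorized.
#' @return Complex vector, one phasor per echo time.
#' @export
fat_phasor <- function(model, b0, te) {
  stopifnot(inherits(model, "fat_model"), all(te >= 0))
  f_hz <- ppm_to_hz(model$shift_ppm, b0)
  as.vector(exp(1i * 2 * pi * outer(te, f_hz)) %*% model$rel_amp)
}

#' Forward multi-echo GRE signal for one voxel
#'
#' `s_n = (rho_w e^{i phi_w} + rho_f e^{i phi_f} c_n) e^{i 2 pi delta_f TE_n}
#' e^{-r2s TE_n}` with `c_n` the [fat_phasor()] at echo `n`.
#'
#' @param params A [voxel_params()].
#' @param model A [fat_model()].
#' @param protocol An [acquisition_protocol()].
#' @return Complex vector of length `length(protocol$te)`.
#' @export
gre_signal <- function(params, model, protocol) {
  stopifnot(inherits(params, "voxel_params"),
            inherits(protocol, "acq_protocol"))
  te <- protocol$te
  cn <- fat_phasor(model, protocol$b0, te)
  amp <- params$rho_w * exp(1i * params$phi_w) +
    params$rho_f * exp(1i * params$phi_f) * cn
  amp * exp((1i * 2 * pi * params$delta_f - params$r2s) * te)
}

#' Nyquist echo spacing for the fat-water phase oscillation
#'
#' The echo spacing that samples the beat between water and the dominant fat
#' peak at exactly two points per cycle: `1 / (2 |f_fat(b0)|)`. Spacings above
#' this undersample the oscillation and increase the risk of fat-water swaps.
#' For the -3.3 ppm methylene peak this is about 1.2 ms at 3 T and 0.5 ms at
#' 7 T.
#'
#' @param dominant_shift_ppm Dominant fat peak shift (ppm, nonzero).
#' @param b0 Field strength (T).
#' @return Echo spacing in seconds.
#' @export
nyquist_dte <- function(dominant_shift_ppm = -3.3, b0) {
  if (any(dominant_shift_ppm == 0)) {
    stop("dominant fat shift must be nonzero")
  }
  1 / (2 * abs(ppm_to_hz(dominant_shift_ppm, b0)))
}

# fat-water beat period (s): one full phase cycle of the dominant peak
beat_period <- function(model, b0) {
  1 / abs(ppm_to_hz(dominant_shift(model), b0))
}
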