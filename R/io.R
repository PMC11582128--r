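# File interfaces: complex echo series as paired NIfTI volumes with a JSON
# sidecar, B0 maps as NIfTI, NSA* grids as CSV + JSON sidecar, FWS results
# as a directory of maps.

#' Write / read an echo series as NIfTI volumes
#'
#' The complex stack is stored as two 4-D NIfTI volumes (echo as the 4th
#' dimension) holding either real/imaginary or magnitude/phase components,
#' plus a JSON sidecar with echo times (ms), field strength, axis labels,
#' noise level and provenance.
#'
#' @param series An [echo_series()].
#' @param prefix Output path prefix; writes `<prefix>_real.nii.gz` /
#'   `<prefix>_imag.nii.gz` (or `_mag`/`_phase`) and `<prefix>.json`.
#' @param representation `"real-imag"` (default) or `"mag-phase"`.
#' @return `prefix`, invisibly.
#' @export
write_echo_series <- function(series, prefix,
                              representation = c("real-imag", "mag-phase")) {
  representation <- match.arg(representation)
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)
  arr <- array(series$data, dim = c(d[1], d[2], 1, d[3]))  # x, y, z, echo
  if (representation == "real-imag") {
    RNifti::writeNifti(Re(arr), paste0(prefix, "_real.nii.gz"))
    RNifti::writeNifti(Im(arr), paste0(prefix, "_imag.nii.gz"))
  } else {
    RNifti::writeNifti(Mod(arr), paste0(prefix, "_mag.nii.gz"))
    RNifti::writeNifti(Arg(arr), paste0(prefix, "_phase.nii.gz"))
  }
  side <- list(te_ms = series$protocol$te * 1e3,
               b0 = series$protocol$b0,
               readout_axis = series$protocol$readout_axis,
               phase_encode_axis = series$protocol$phase_encode_axis,
               noise_sd = series$noise_sd,
               representation = representation,
               provenance = series$provenance)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_echo_series
#' @export
read_echo_series <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rep <- side$representation
  if (identical(rep, "real-imag")) {
    re <- as.array(RNifti::readNifti(paste0(prefix, "_real.nii.gz")))
    im <- as.array(RNifti::readNifti(paste0(prefix, "_imag.nii.gz")))
    data <- re + 1i * im
  } else {
    mg <- as.array(RNifti::readNifti(paste0(prefix, "_mag.nii.gz")))
    ph <- as.array(RNifti::readNifti(paste0(prefix, "_phase.nii.gz")))
    data <- mg * exp(1i * ph)
  }
  d <- dim(data)
  data <- array(data, dim = c(d[1], d[2], d[4]))  # drop singleton z
  proto <- acquisition_protocol(side$b0, te_list = side$te_ms / 1e3,
                                readout_axis = side$readout_axis,
                                phase_encode_axis = side$phase_encode_axis)
  prov <- side$provenance
  echo_series(data, proto, noise_sd = side$noise_sd,
              provenance = if (is.null(prov)) list() else as.list(prov))
}

#' Write / read a B0 map as NIfTI
#'
#' Field map in Hz plus a companion validity-mask volume and JSON sidecar.
#'
#' @param b0map A `b0_map`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_b0_map <- function(b0map, prefix) {
  stopifnot(inherits(b0map, "b0_map"))
  RNifti::writeNifti(b0map$delta_f, paste0(prefix, "_hz.nii.gz"))
  RNifti::writeNifti(b0map$valid_mask + 0, paste0(prefix, "_mask.nii.gz"))
  jsonlite::write_json(list(te_pair_ms = b0map$te_pair * 1e3,
                            aliasing_hz = b0map$aliasing_hz),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_b0_map
#' @export
read_b0_map <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- as.array(RNifti::readNifti(paste0(prefix, "_hz.nii.gz")))
  mk <- as.array(RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))) > 0
  df <- matrix(df, dim(df)[1])
  mk <- matrix(mk, dim(mk)[1])
  structure(list(delta_f = df, valid_mask = mk,
                 te_pair = side$te_pair_ms / 1e3,
                 aliasing_hz = side$aliasing_hz),
            class = "b0_map")
}

#' Write / read an NSA* grid
#'
#' Long-format CSV of the 4-D grid (full double precision) plus a JSON
#' sidecar holding the axes and simulation settings; the round trip is
#' lossless.
#'
#' @param grid An `nsa_grid` from [nsa_grid_scan()].
#' @param prefix Output path prefix; writes `<prefix>_grid.csv` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_nsa_grid <- function(grid, prefix) {
  stopifnot(inherits(grid, "nsa_grid"))
  idx <- expand.grid(te1 = seq_along(grid$te1), dte = seq_along(grid$dte),
                     pdff = seq_along(grid$pdff),
                     param = seq_along(grid$param))
  tab <- data.frame(te1_s = sprintf("%.17g", grid$te1[idx$te1]),
                    dte_s = sprintf("%.17g", grid$dte[idx$dte]),
                    pdff = sprintf("%.17g", grid$pdff[idx$pdff]),
                    param = grid$param[idx$param],
                    nsa = sprintf("%.17g", as.vector(grid$nsa)))
  utils::write.csv(tab, paste0(prefix, "_grid.csv"), row.names = FALSE)
  set <- grid$settings
  jsonlite::write_json(
    list(te1_s = grid$te1, dte_s = grid$dte, pdff = grid$pdff,
         param = grid$param, b0 = set$b0, r2s = set$r2s,
         n_echoes = set$n_echoes, include_r2s = set$include_r2s,
         delta_f = set$delta_f, step = set$step,
         fat_model = list(name = set$model$name,
                          shift_ppm = set$model$shift_ppm,
                          rel_amp = set$model$rel_amp)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_nsa_grid
#' @export
read_nsa_grid <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(prefix, "_grid.csv"),
                         stringsAsFactors = FALSE)
  nsa <- array(as.numeric(tab$nsa),
               dim = c(length(side$te1_s), length(side$dte_s),
                       length(side$pdff), length(side$param)),
               dimnames = list(NULL, NULL, NULL, side$param))
  model <- new_fat_model(side$fat_model$name, side$fat_model$shift_ppm,
                         side$fat_model$rel_amp)
  structure(list(te1 = side$te1_s, dte = side$dte_s, pdff = side$pdff,
                 param = side$param, nsa = nsa,
                 settings = list(model = model, b0 = side$b0,
                                 r2s = side$r2s, n_echoes = side$n_echoes,
                                 include_r2s = side$include_r2s,
                                 delta_f = side$delta_f, step = side$step)),
            class = "nsa_grid")
}

#' Write separation results as NIfTI maps
#'
#' Writes water/fat magnitude, field map, R2*, PDFF and mask volumes, the
#' graph-cut energy trace as CSV, and a JSON run log.
#'
#' @param result An `fws_result` from [separate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fws_result <- function(result, dir) {
  stopifnot(inherits(result, "fws_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wp <- function(x, nm) RNifti::writeNifti(x, file.path(dir,
                                                        paste0(nm, ".nii.gz")))
  wp(result$water_mag, "water")
  wp(result$fat_mag, "fat")
  wp(result$field_map, "fieldmap_hz")
  wp(result$r2s_map, "r2s_hz")
  wp(pdff_map(result$fat_mag, result$water_mag)$pdff, "pdff")
  wp(result$mask + 0, "mask")
  utils::write.csv(data.frame(iteration =
                                seq_along(result$energy_trace) - 1L,
                              energy = result$energy_trace),
                   file.path(dir, "energy_trace.csv"), row.names = FALSE)
  jsonlite::write_json(list(lambda = result$lambda,
                            n_iterations = result$config$n_iterations,
                            offres_grid_hz = range(result$config$offres_grid),
                            r2s_grid_hz = range(result$config$r2s_grid),
                            fat_model = result$config$fat_model$name),
                       file.path(dir, "run_log.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
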