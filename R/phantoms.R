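# Digital phantoms: known PDFF / R2* / field-map / phase truth on a voxel
# grid, with integer region labels usable as ROIs.

new_digital_phantom <- function(pdff, rho, r2s, b0, phi0, labels,
                                label_names, interface_points = NULL) {
  stopifnot(all(dim(pdff) == dim(rho)), all(dim(pdff) == dim(labels)),
            all(pdff >= 0 & pdff <= 1), all(rho >= 0))
  structure(list(shape = dim(pdff), pdff = pdff, rho = rho, r2s = r2s,
                 b0 = b0, phi0 = phi0, labels = labels,
                 label_names = label_names,
                 interface_points = interface_points),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom %d x %d: regions %s>\n",
              x$shape[1], x$shape[2],
              paste(names(x$label_names), collapse = ", ")))
  invisible(x)
}

# squared-distance grid helper; axis 1 is the readout ("x") axis
.grid_xy <- function(n) {
  x <- matrix(rep(seq_len(n), n), n, n)
  list(x = x, y = t(x))
}

#' Vial fat-fraction phantom
#'
#' Circular vials of known volume fat fraction (VFF) arranged in a ring
#' inside a circular water bath, mimicking a peanut-oil/agarose emulsion
#' phantom. The VFF of each vial is used 1:1 as the PDFF ground truth.
#'
#' @param vff Volume fat fractions of the vials (default 5, 10, 25, 50, 75,
#'   100%).
#' @param grid_size Image matrix size (square, default 96).
#' @param bath_radius,ring_radius,vial_radius Geometry as fractions of
#'   `grid_size` (schematic; vials must not overlap).
#' @param r2s Uniform true R2* in Hz (default 50).
#' @param rho Total magnitude inside the object (default 1).
#' @return A `digital_phantom` with labels `background` (0), `bath` (1) and
#'   `vial1` ... `vialK` (2, 3, ...). The truth field map and initial phase
#'   are zero; add inhomogeneity with [make_field_map()].
#' @export
make_vial_phantom <- function(vff = c(0.05, 0.10, 0.25, 0.50, 0.75, 1.00),
                              grid_size = 96, bath_radius = 0.46,
                              ring_radius = 0.28, vial_radius = 0.10,
                              r2s = 50, rho = 1) {
  stopifnot(length(vff) >= 1, all(vff >= 0), all(vff <= 1))
  n <- grid_size
  k <- length(vff)
  rv <- vial_radius * n
  r0 <- ring_radius * n
  rb <- bath_radius * n
  # overlap / containment checks at the requested geometry
  if (k > 1 && 2 * r0 * sin(pi / k) <= 2 * rv) {
    stop("vials would overlap at the requested grid size / geometry")
  }
  if (r0 + rv >= rb) stop("vials do not fit inside the water bath")
  g <- .grid_xy(n)
  cx <- (n + 1) / 2
  pdff <- matrix(0, n, n)
  labels <- matrix(0L, n, n)
  bath <- (g$x - cx)^2 + (g$y - cx)^2 <= rb^2
  labels[bath] <- 1L
  ang <- 2 * pi * (seq_len(k) - 1) / k
  for (i in seq_len(k)) {
    vx <- cx + r0 * cos(ang[i])
    vy <- cx + r0 * sin(ang[i])
    vial <- (g$x - vx)^2 + (g$y - vy)^2 <= rv^2
    labels[vial] <- i + 1L
    pdff[vial] <- vff[i]
  }
  rho_map <- matrix(0, n, n)
  rho_map[labels > 0L] <- rho
  label_names <- c(background = 0L, bath = 1L,
                   stats::setNames(seq_len(k) + 1L, paste0("vial", seq_len(k))))
  new_digital_phantom(pdff, rho_map, matrix(r2s * (labels > 0L), n, n),
                      matrix(0, n, n), matrix(0, n, n), labels, label_names)
}

#' Calf-like phantom
#'
#' Schematic transversal calf slice: low-PDFF muscle partitioned into three
#' ROI sectors (ANT, SOL, GM), a high-PDFF subcutaneous fat ring, and a tibia
#' with near-zero-signal cortical bone surrounding high-PDFF marrow. The
#' low-SNR bone region emulates tissue that gets masked during B0-map
#' computation.
#'
#' @param grid_size Image matrix size (square, default 64).
#' @param muscle_pdff,fat_ring_pdff,marrow_pdff True PDFF of muscle,
#'   subcutaneous ring and bone marrow (defaults 0.03, 0.90, 0.90).
#' @param r2s Uniform true R2* in Hz (default 50).
#' @return A `digital_phantom` with labels `background` (0), `ANT` (1),
#'   `SOL` (2), `GM` (3), `fat_ring` (4), `bone` (5), `marrow` (6).
#' @export
make_calf_phantom <- function(grid_size = 64, muscle_pdff = 0.03,
                              fat_ring_pdff = 0.90, marrow_pdff = 0.90,
                              r2s = 50) {
  stopifnot(muscle_pdff >= 0, muscle_pdff <= 1, fat_ring_pdff >= 0,
            fat_ring_pdff <= 1, marrow_pdff >= 0, marrow_pdff <= 1)
  n <- grid_size
  g <- .grid_xy(n)
  cx <- (n + 1) / 2
  a <- 0.45 * n; b <- 0.42 * n          # outer ellipse semi-axes
  ring_frac <- 0.82                     # muscle boundary as fraction of outer
  rel <- ((g$x - cx) / a)^2 + ((g$y - cx) / b)^2
  outer_el <- rel <= 1
  muscle_el <- rel <= ring_frac^2
  labels <- matrix(0L, n, n)
  labels[outer_el] <- 4L                # subcutaneous ring (overwritten inside)
  theta <- atan2(g$y - cx, g$x - cx)
  ant <- theta >= pi / 3 & theta < 2 * pi / 3         # anterior sector
  sol <- theta >= -5 * pi / 6 & theta < -pi / 6       # posterior sector
  labels[muscle_el & ant] <- 1L
  labels[muscle_el & sol] <- 2L
  labels[muscle_el & !ant & !sol] <- 3L
  # tibia: offset circle, cortical bone annulus around marrow
  tx <- cx + 0.16 * n; ty <- cx + 0.14 * n
  rt <- 0.11 * n; rm <- 0.07 * n
  d2 <- (g$x - tx)^2 + (g$y - ty)^2
  labels[d2 <= rt^2] <- 5L
  labels[d2 <= rm^2] <- 6L
  pdff <- matrix(0, n, n)
  pdff[labels %in% 1:3] <- muscle_pdff
  pdff[labels == 4L] <- fat_ring_pdff
  pdff[labels == 6L] <- marrow_pdff
  rho <- matrix(0, n, n)
  rho[labels %in% c(1:4, 6L)] <- 1
  rho[labels == 5L] <- 0.02             # cortical bone: near-zero signal
  label_names <- c(background = 0L, ANT = 1L, SOL = 2L, GM = 3L,
                   fat_ring = 4L, bone = 5L, marrow = 6L)
  # fat/bone interface points used for local field perturbations: anterior
  # rim of the fat ring and the tibia boundary
  ip <- rbind(c(cx, cx + ring_frac * b), c(tx + rt, ty))
  new_digital_phantom(pdff, rho, matrix(r2s * (labels > 0L), n, n),
                      matrix(0, n, n), matrix(0, n, n), labels, label_names,
                      interface_points = ip)
}

# 2-D dipole-like kernel: quadrupolar angular pattern decaying with distance
.dipole_kernel <- function(x, y, cx, cy, width) {
  dx <- x - cx; dy <- y - cy
  r2 <- dx^2 + dy^2
  (dx^2 - dy^2) / (r2 + width^2)^1.5 * width^1.5
}

#' Add B0 inhomogeneity to a phantom
#'
#' The truth field map is the sum of a smooth low-order 2-D polynomial term
#' and localized dipole-like perturbations centered at fat/bone interfaces
#' (falling back to the object center when the phantom records no interface
#' points). Each term is scaled so its maximum absolute value inside the
#' object equals the requested amplitude; physical inhomogeneities grow
#' linearly with B0, so callers typically scale amplitudes with field
#' strength.
#'
#' @param phantom A `digital_phantom`.
#' @param smooth_amplitude Peak |Hz| of the smooth polynomial term.
#' @param local_gradient_amplitude Peak |Hz| of the localized perturbations.
#' @return The phantom with `b0` replaced (components stored in
#'   `b0_components`).
#' @export
make_field_map <- function(phantom, smooth_amplitude = 0,
                           local_gradient_amplitude = 0) {
  n <- phantom$shape[1]
  g <- .grid_xy(n)
  u <- (g$x - (n + 1) / 2) / (n / 2)
  v <- (g$y - (n + 1) / 2) / (n / 2)
  # fixed low-order polynomial shape (normalized below)
  smooth <- 0.55 * u + 0.30 * v + 0.60 * u^2 - 0.40 * u * v - 0.25 * v^2
  m <- max(abs(smooth))
  smooth <- if (m > 0) smooth / m * smooth_amplitude else smooth * 0
  pts <- phantom$interface_points
  if (is.null(pts)) pts <- matrix((n + 1) / 2, 1, 2)
  local <- matrix(0, n, n)
  for (i in seq_len(nrow(pts))) {
    local <- local + .dipole_kernel(g$x, g$y, pts[i, 1], pts[i, 2],
                                    width = 0.06 * n)
  }
  m <- max(abs(local))
  local <- if (m > 0) local / m * local_gradient_amplitude else local * 0
  phantom$b0 <- smooth + local
  phantom$b0_components <- list(smooth = smooth, local = local)
  phantom
}
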