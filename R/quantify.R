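# PDFF quantification, ROI statistics and agreement metrics.

#' PDFF map from separated magnitude images
#'
#' Magnitude definition `PDFF = |F| / (|W| + |F|)`, which confines values to
#' 0..1 (at the cost of a positive noise bias at very low and a negative
#' bias at very high fat fractions). A signed complex-based definition
#' `Re(F / (W + F))` is available behind `signed = TRUE` for diagnostic use;
#' the magnitude form is the default because it is more robust to phase
#' errors.
#'
#' @param fat_mag,water_mag Non-negative magnitude maps on a common grid
#'   (or complex maps when `signed = TRUE`).
#' @param signed Use the signed complex definition (default `FALSE`).
#' @return List with `pdff` (fraction map; 0 where `|W| + |F| = 0`) and
#'   `undefined` (logical map flagging those zero-signal voxels).
#' @export
pdff_map <- function(fat_mag, water_mag, signed = FALSE) {
  stopifnot(all(dim(fat_mag) == dim(water_mag)))
  if (signed) {
    tot <- water_mag + fat_mag
    undef <- Mod(tot) == 0
    pdff <- matrix(0, nrow(fat_mag), ncol(fat_mag))
    pdff[!undef] <- Re(fat_mag[!undef] / tot[!undef])
  } else {
    if (is.complex(fat_mag)) fat_mag <- Mod(fat_mag)
    if (is.complex(water_mag)) water_mag <- Mod(water_mag)
    stopifnot(all(fat_mag >= 0), all(water_mag >= 0))
    tot <- water_mag + fat_mag
    undef <- tot == 0
    pdff <- matrix(0, nrow(fat_mag), ncol(fat_mag))
    pdff[!undef] <- fat_mag[!undef] / tot[!undef]
  }
  list(pdff = pdff, undefined = undef)
}

#' Region-of-interest specification
#'
#' @param name ROI label (e.g. `"ANT"`, `"vial3"`).
#' @param mask Non-empty logical matrix.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(name, mask) {
  stopifnot(is.logical(mask), any(mask))
  structure(list(name = name, mask = mask), class = "roi_spec")
}

#' ROIs from a phantom's label map
#'
#' @param phantom A `digital_phantom`.
#' @param which Names of labels to extract (default: all nonzero labels).
#' @return List of [roi_spec()]s.
#' @export
phantom_rois <- function(phantom, which = NULL) {
  ln <- phantom$label_names
  ln <- ln[ln > 0L]
  if (!is.null(which)) ln <- ln[names(ln) %in% which]
  lapply(names(ln), function(nm) {
    roi_spec(nm, phantom$labels == ln[[nm]])
  })
}

#' ROI statistics of a map
#'
#' Mean, population standard deviation and voxel count per ROI. ROIs within
#' one evaluation set must not overlap.
#'
#' @param map Numeric matrix.
#' @param rois List of [roi_spec()]s.
#' @return Data frame with columns `name`, `mean`, `sd`, `n_voxels`.
#' @export
roi_stats <- function(map, rois) {
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  cover <- Reduce(`+`, lapply(rois, function(r) r$mask + 0L))
  if (any(cover > 1L)) stop("ROIs overlap within this evaluation set")
  do.call(rbind, lapply(rois, function(r) {
    x <- map[r$mask]
    n <- length(x)
    data.frame(name = r$name, mean = mean(x),
               sd = sqrt(sum((x - mean(x))^2) / n), n_voxels = n)
  }))
}

#' Mean absolute error between reference and measured fat fractions
#'
#' `(1/K) sum_k |VFF_k - PDFF_k|`, reported in percentage points.
#'
#' @param vff Reference volume fat fractions (fractions in 0..1).
#' @param pdff Measured PDFF values (fractions), same length.
#' @return MAE in percentage points.
#' @export
mae <- function(vff, pdff) {
  stopifnot(length(vff) == length(pdff))
  mean(abs(vff - pdff)) * 100
}

#' Agreement between reference and measured fat fractions
#'
#' Ordinary least-squares regression of PDFF on VFF (coefficient of
#' determination, slope, intercept) plus the Spearman rank correlation
#' (average ranks for ties).
#'
#' @inheritParams mae
#' @return List with `r_squared`, `slope`, `intercept`, `spearman_rho`.
#' @export
agreement <- function(vff, pdff) {
  stopifnot(length(vff) == length(pdff), length(vff) >= 2)
  fit <- stats::lm(pdff ~ vff)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       spearman_rho = stats::cor(vff, pdff, method = "spearman"))
}
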