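#' Build a band grid
#'
#' Regular grid of band centers with a common full width at half maximum
#' (FWHM), emulating an imaging spectrometer's band layout.
#'
#' @param start,stop First center and upper bound (nm); `start < stop`
#'   required except for the degenerate single-band case `start == stop`.
#' @param step Center spacing in nm (> 0).
#' @param fwhm FWHM in nm (> 0), common to all bands.
#' @return Object of class `band_grid` with `centers`, `fwhm` and an `id`.
#' @examples
#' g <- band_grid(400, 2500, 10, 10)  # 211 bands
#' length(g$centers)
#' @export
band_grid <- function(start, stop, step, fwhm) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (start > stop) stop("start must be <= stop", call. = FALSE)
  centers <- seq(start, stop, by = step)
  structure(list(centers = centers,
                 fwhm = rep(fwhm, length(centers)),
                 id = sprintf("grid_%g_%g_%g_%g", start, stop, step, fwhm)),
            class = "band_grid")
}

#' Preset band grids
#'
#' Two configurable presets emulating a CHIME-like band layout: a uniform
#' 10 nm grid over 400-2500 nm and a uniform 7 nm grid over 400-2346 nm.
#' Neither claims to be the true instrument grid, which is unpublished.
#'
#' @param name `"chime10"` or `"chime7"`.
#' @return A [band_grid()].
#' @export
preset_band_grid <- function(name = c("chime10", "chime7")) {
  switch(match.arg(name),
         chime10 = band_grid(400, 2500, 10, 10),
         chime7 = band_grid(400, 2346, 7, 10))
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf("<band_grid> %d bands, %.0f-%.0f nm, FWHM %g nm\n",
              length(x$centers), min(x$centers), max(x$centers), x$fwhm[1]))
  invisible(x)
}

#' Resample spectra through Gaussian spectral response functions
#'
#' Each output band is the SRF-weighted mean of the source samples within
#' +/- 2 FWHM of the band center, with Gaussian weights
#' `exp(-4 ln 2 (lambda - c)^2 / FWHM^2)` renormalized over the truncated
#' support. Exact for constant spectra; linear in the spectrum.
#'
#' @param wavelengths Source wavelengths (nm), ascending.
#' @param spectra Vector (one spectrum) or matrix (`n x length(wavelengths)`).
#' @param grid Target [band_grid()].
#' @return Resampled vector or matrix (`n x n_bands`). Bands with no source
#'   support are `NA` with a warning.
#' @export
gaussian_resample <- function(wavelengths, spectra, grid) {
  one <- is.null(dim(spectra))
  X <- if (one) matrix(spectra, nrow = 1) else as.matrix(spectra)
  if (ncol(X) != length(wavelengths)) {
    stop("spectra columns do not match source wavelengths", call. = FALSE)
  }
  B <- length(grid$centers)
  W <- matrix(0, length(wavelengths), B)
  for (j in seq_len(B)) {
    c_j <- grid$centers[j]
    f_j <- grid$fwhm[j]
    keep <- abs(wavelengths - c_j) <= 2 * f_j
    if (any(keep)) {
      w <- exp(-4 * log(2) * (wavelengths[keep] - c_j)^2 / f_j^2)
      W[keep, j] <- w / sum(w)
    }
  }
  empty <- colSums(W) == 0
  out <- X %*% W
  if (any(empty)) {
    warning(sum(empty), " target band(s) without source support; masked as NA")
    out[, empty] <- NA_real_
  }
  if (one) drop(out) else out
}

#' Exclusion windows over the spectral axis
#'
#' Closed wavelength intervals to be removed (union semantics), typically
#' atmospheric gaseous-absorption regions where surface reflectance is
#' unreliable.
#'
#' @param windows `data.frame` with columns `min`, `max` (nm) and optionally
#'   `label`.
#' @return Object of class `exclusion_windows`.
#' @export
exclusion_windows <- function(windows) {
  windows <- as.data.frame(windows)
  if (!all(c("min", "max") %in% names(windows))) {
    stop("windows need 'min' and 'max' columns", call. = FALSE)
  }
  if (any(windows$min > windows$max)) {
    stop("window with min > max", call. = FALSE)
  }
  if (is.null(windows$label)) windows$label <- rep("excluded", nrow(windows))
  structure(windows, class = c("exclusion_windows", "data.frame"))
}

#' Default atmospheric-absorption exclusion windows
#'
#' The standard set of gaseous-absorption windows removed before model
#' training and mapping. Overlapping intervals are applied as a union.
#'
#' @return An [exclusion_windows()] object.
#' @export
default_exclusion_windows <- function() {
  exclusion_windows(data.frame(
    min = c(535, 755, 755, 810, 885, 1015, 1080, 1225, 1330, 1685, 1725,
            1780, 1990),
    max = c(550, 780, 775, 855, 970, 1050, 1165, 1285, 1490, 1700, 1750,
            1960, 2030),
    label = "atmospheric absorption"))
}

#' Remove bands inside exclusion windows
#'
#' Drops every band whose center lies inside any window and records the
#' kept-band index in the metadata so training and mapping artifacts built
#' from the same grid can be aligned exactly.
#'
#' @param x A [spectral_library()], a `synthetic_cube`, or a numeric vector
#'   of band centers.
#' @param windows An [exclusion_windows()] object.
#' @return Same class as `x`, reduced to the kept bands, with
#'   `meta$kept_index` set. For a numeric vector, the kept index vector.
#' @export
apply_exclusion_windows <- function(x, windows = default_exclusion_windows()) {
  wl <- if (is.numeric(x)) x else x$wavelengths
  keep <- rep(TRUE, length(wl))
  for (i in seq_len(nrow(windows))) {
    keep <- keep & !(wl >= windows$min[i] & wl <= windows$max[i])
  }
  if (!any(keep)) stop("all bands excluded", call. = FALSE)
  idx <- which(keep)
  if (is.numeric(x)) return(idx)
  if (inherits(x, "spectral_library")) {
    out <- spectral_library(wl[idx], x$reflectance[, idx, drop = FALSE],
                            x$traits, x$meta)
    out$meta$kept_index <- idx
    return(out)
  }
  if (inherits(x, "synthetic_cube")) {
    x$cube <- x$cube[, , idx, drop = FALSE]
    x$wavelengths <- wl[idx]
    x$meta$kept_index <- idx
    return(x)
  }
  stop("unsupported input type", call. = FALSE)
}
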