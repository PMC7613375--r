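#' Construct a spectral library
#'
#' The universal container moving between pipeline stages: a wavelength grid,
#' a reflectance matrix, and a row-aligned trait table.
#'
#' @param wavelengths Strictly increasing band centers in nm.
#' @param reflectance Numeric matrix, `n_samples x n_bands`, values in
#'   `[0, 1]` (NA allowed for masked bands).
#' @param traits `data.frame` with one row per sample (inputs and/or derived
#'   targets).
#' @param meta Named list of provenance (seed, generator version, grid id,
#'   kept-band index, ...).
#' @return Object of class `spectral_library`.
#' @export
spectral_library <- function(wavelengths, reflectance, traits,
                             meta = list()) {
  reflectance <- as.matrix(reflectance)
  if (length(wavelengths) != ncol(reflectance)) {
    stop("wavelength count does not match reflectance columns", call. = FALSE)
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (nrow(reflectance) != nrow(traits)) {
    stop("reflectance and trait table row counts differ", call. = FALSE)
  }
  finite <- reflectance[is.finite(reflectance)]
  if (length(finite) && (min(finite) < -1e-9 || max(finite) > 1 + 1e-9)) {
    stop("reflectance values outside [0, 1]", call. = FALSE)
  }
  colnames(reflectance) <- format_band_names(wavelengths)
  structure(
    list(wavelengths = as.numeric(wavelengths),
         reflectance = reflectance,
         traits = as.data.frame(traits),
         meta = meta),
    class = "spectral_library"
  )
}

format_band_names <- function(wl) paste0("B", sub("\\.?0+$", "", sprintf("%.3f", wl)))

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf(
    "<spectral_library> %d samples x %d bands (%.0f-%.0f nm), traits: %s\n",
    nrow(x$reflectance), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths),
    paste(names(x$traits), collapse = ", ")))
  invisible(x)
}

#' @export
dim.spectral_library <- function(x) dim(x$reflectance)

#' Subset a spectral library by sample rows
#' @param lib A `spectral_library`.
#' @param i Row index vector.
#' @return A `spectral_library` with the selected rows.
#' @export
lib_subset <- function(lib, i) {
  spectral_library(lib$wavelengths,
                   lib$reflectance[i, , drop = FALSE],
                   lib$traits[i, , drop = FALSE],
                   lib$meta)
}

#' Stack two spectral libraries sharing a band grid
#' @param a,b `spectral_library` objects on identical wavelength grids.
#' @return The row-concatenated `spectral_library`; trait columns are merged
#'   by name (absent columns fill with NA).
#' @export
lib_rbind <- function(a, b) {
  if (nrow(b$reflectance) == 0L) return(a)
  if (nrow(a$reflectance) == 0L) return(b)
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(abs(a$wavelengths - b$wavelengths) > 1e-9)) {
    stop("band grids differ; cannot stack libraries", call. = FALSE)
  }
  cols <- union(names(a$traits), names(b$traits))
  pad <- function(df) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df[, cols, drop = FALSE]
  }
  spectral_library(a$wavelengths,
                   rbind(a$reflectance, b$reflectance),
                   rbind(pad(a$traits), pad(b$traits)),
                   a$meta)
}

## trait targets the retrieval workflow knows about
trait_target_names <- function() c("SLA", "LAI", "CCC", "CWC", "FAPAR", "FVC")
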