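#' Write / read a spectral library as CSV with a JSON sidecar
#'
#' One row per sample; columns: `sample_id`, the trait columns by name, then
#' one reflectance column per band named by its center wavelength in nm.
#' Metadata (seed, grid id, kept-band index, ...) goes to `<path>.json`.
#' Values round-trip at full double precision.
#'
#' @param lib A [spectral_library()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_spectral_library <- function(lib, path) {
  df <- data.frame(sample_id = seq_len(nrow(lib$reflectance)),
                   lib$traits, check.names = FALSE)
  refl <- as.data.frame(lib$reflectance)
  names(refl) <- format(lib$wavelengths, trim = TRUE, digits = 15,
                        scientific = FALSE)
  df <- cbind(df, refl)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  meta <- lib$meta
  meta$wavelengths <- lib$wavelengths
  meta$trait_columns <- names(lib$traits)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spectral_library
#' @param require_traits Character vector of trait columns that must be
#'   present; a missing one is an error naming the column.
#' @return For `read_spectral_library`, the reconstructed
#'   [spectral_library()].
#' @export
read_spectral_library <- function(path, require_traits = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  is_band <- suppressWarnings(!is.na(as.numeric(names(df))))
  wl <- as.numeric(names(df)[is_band])
  traits <- df[, !is_band & names(df) != "sample_id", drop = FALSE]
  if (!is.null(require_traits)) {
    miss <- setdiff(require_traits, names(traits))
    if (length(miss)) {
      stop("library at '", path, "' lacks required trait column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  ord <- order(wl)
  R <- as.matrix(df[, is_band, drop = FALSE])[, ord, drop = FALSE]
  meta$wavelengths <- NULL
  meta$trait_columns <- NULL
  spectral_library(wl[ord], R, traits, as.list(meta))
}

## ---- ENVI cubes ---------------------------------------------------------
## Minimal ENVI format support: text .hdr + flat binary, BSQ/BIL/BIP,
## data types 4 (float32) and 5 (float64), byte order 0 (little endian).

envi_dtype <- function(code) {
  switch(as.character(code),
         "4" = list(what = "numeric", size = 4L),
         "5" = list(what = "numeric", size = 8L),
         stop("unsupported ENVI data type ", code, call. = FALSE))
}

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  get_field <- function(name, numeric = TRUE) {
    m <- regmatches(joined,
      regexpr(paste0("(?mi)^", name, "\\s*=\\s*([^\n{]+)"), joined,
              perl = TRUE))
    if (!length(m)) return(NULL)
    v <- trimws(sub(paste0("(?i)^", name, "\\s*=\\s*"), "", m, perl = TRUE))
    if (numeric) as.numeric(v) else v
  }
  wl <- NULL
  m <- regmatches(joined,
    regexpr("(?si)wavelength\\s*=\\s*\\{([^}]*)\\}", joined, perl = TRUE))
  if (length(m)) {
    body <- sub("(?si)wavelength\\s*=\\s*\\{", "", m, perl = TRUE)
    body <- sub("\\}$", "", body)
    wl <- as.numeric(strsplit(gsub("\\s", "", body), ",")[[1]])
  }
  list(samples = get_field("samples"), lines = get_field("lines"),
       bands = get_field("bands"),
       dtype = get_field("data type"),
       interleave = tolower(get_field("interleave", numeric = FALSE)),
       byte_order = get_field("byte order"),
       wavelength = wl,
       map_info = get_field("map info", numeric = FALSE))
}

#' Write / read a hyperspectral cube in ENVI format
#'
#' A text `.hdr` plus flat binary pixel data. Supported: interleaves BSQ,
#' BIL and BIP; 32- and 64-bit floats; little-endian byte order; optional
#' wavelength list and `map info` georeferencing string.
#'
#' @param cube 3-D array (`rows x cols x bands`).
#' @param path Binary data path; the header is written to `<path>.hdr`.
#' @param wavelengths Optional band centers (nm) stored in the header.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param dtype `"double"` (exact round trip) or `"float"`.
#' @param map_info Optional ENVI `map info` string for georeferencing.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, wavelengths = NULL,
                       interleave = c("bsq", "bil", "bip"),
                       dtype = c("double", "float"), map_info = NULL) {
  interleave <- match.arg(interleave)
  dtype <- match.arg(dtype)
  stopifnot(length(dim(cube)) == 3)
  d <- dim(cube)  # rows (lines), cols (samples), bands
  ## reorder to the on-disk element order; R arrays are column-major so we
  ## build an aperm() whose fastest axis is the innermost on-disk dimension
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube, c(2, 1, 3))),  # sample, line, band
    bil = as.vector(aperm(cube, c(2, 3, 1))),  # sample, band, line
    bip = as.vector(aperm(cube, c(3, 2, 1))))  # band, sample, line
  size <- if (dtype == "double") 8L else 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = size, endian = "little")
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", if (dtype == "double") 5L else 4L),
           sprintf("interleave = %s", interleave),
           "byte order = 0")
  if (!is.null(map_info)) hdr <- c(hdr, sprintf("map info = %s", map_info))
  if (!is.null(wavelengths)) {
    hdr <- c(hdr, "wavelength units = Nanometers",
             paste0("wavelength = {",
                    paste(format(wavelengths, trim = TRUE, digits = 12),
                          collapse = ", "), "}"))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_cube
#' @return For `read_cube`, a list with `cube` (rows x cols x bands array),
#'   `wavelengths` (or NULL) and `map_info` (or NULL).
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    stop("missing ENVI header: ", hdr_path, call. = FALSE)
  }
  h <- parse_envi_header(hdr_path)
  if (is.null(h$samples) || is.null(h$lines) || is.null(h$bands)) {
    stop("malformed ENVI header: need samples/lines/bands", call. = FALSE)
  }
  if (!is.null(h$wavelength) && length(h$wavelength) != h$bands) {
    stop("band-count mismatch: header declares ", h$bands, " bands but ",
         length(h$wavelength), " wavelengths", call. = FALSE)
  }
  dt <- envi_dtype(h$dtype)
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = "little")
  if (length(vals) != n) stop("cube file truncated", call. = FALSE)
  cube <- switch(h$interleave,
    bsq = aperm(array(vals, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(vals, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(vals, c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
    stop("unsupported interleave: ", h$interleave, call. = FALSE))
  list(cube = cube, wavelengths = h$wavelength, map_info = h$map_info)
}
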