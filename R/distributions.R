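#' Distribution specification for a simulator input variable
#'
#' Declares how one leaf/canopy/soil/geometry variable is drawn when building
#' a training library: uniform over a range, truncated Gaussian inside a
#' range, or fixed at a constant.
#'
#' @param name Variable name (e.g. `"Cab"`).
#' @param kind One of `"uniform"`, `"truncated-gaussian"`, `"fixed"`.
#' @param min,max Range bounds (for `"fixed"`, `min == max` is the value).
#' @param mean,sd Location and spread of the underlying Gaussian
#'   (`"truncated-gaussian"` only; `sd` must be positive).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("LAI", "uniform", 0.1, 8)
#' dist_spec("Cab", "truncated-gaussian", 0, 80, mean = 45, sd = 35)
#' @export
dist_spec <- function(name, kind = c("uniform", "truncated-gaussian", "fixed"),
                      min, max = min, mean = NULL, sd = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(min) || !is.numeric(max) || min > max) {
    stop("dist_spec '", name, "': need numeric min <= max", call. = FALSE)
  }
  if (kind == "fixed" && min != max) {
    stop("dist_spec '", name, "': fixed distribution requires min == max",
         call. = FALSE)
  }
  if (kind == "truncated-gaussian") {
    if (is.null(mean) || is.null(sd)) {
      stop("dist_spec '", name, "': truncated-gaussian needs mean and sd",
           call. = FALSE)
    }
    if (sd <= 0) {
      stop("dist_spec '", name, "': sd must be > 0", call. = FALSE)
    }
  }
  structure(
    list(name = name, kind = kind, min = min, max = max,
         mean = mean, sd = sd),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  extra <- if (x$kind == "truncated-gaussian") {
    sprintf(" (mean %g, sd %g)", x$mean, x$sd)
  } else ""
  cat(sprintf("<dist_spec> %s: %s on [%g, %g]%s\n",
              x$name, x$kind, x$min, x$max, extra))
  invisible(x)
}

#' Default input distributions of the canopy simulator
#'
#' The standard parameterization used to build the simulated training
#' database: leaf constituents (N, Cab, Cm, Cw) follow truncated Gaussians,
#' carotenoids and the canopy/geometry variables are uniform, and the soil
#' descriptors follow truncated Gaussians. Anthocyanins and senescent
#' material are fixed at zero (green canopies only).
#'
#' @return Named list of [dist_spec()] objects, one per simulator input.
#' @export
default_trait_specs <- function() {
  specs <- list(
    dist_spec("N",          "truncated-gaussian", 1.0,   2.7,  mean = 1.5,    sd = 0.5),
    dist_spec("Cab",        "truncated-gaussian", 0,     80,   mean = 45,     sd = 35),
    dist_spec("Cm",         "truncated-gaussian", 0.002, 0.02, mean = 0.0075, sd = 0.005),
    dist_spec("Cw",         "truncated-gaussian", 0.005, 0.035, mean = 0.015, sd = 0.0075),
    dist_spec("Cxc",        "uniform", 0, 20),
    dist_spec("LAI",        "uniform", 0.1, 8),
    dist_spec("LIDF",       "uniform", -1, 1),
    dist_spec("alpha_soil", "uniform", 0, 1),
    dist_spec("SZA",        "uniform", 0, 80),
    dist_spec("OZA",        "uniform", 0, 25),
    dist_spec("RAA",        "uniform", 0, 180),
    dist_spec("SMC",        "truncated-gaussian", 5,  55,  mean = 25,  sd = 12.5),
    dist_spec("B_soil",     "truncated-gaussian", 0,  0.9, mean = 0.5, sd = 0.25),
    dist_spec("BSM_lat",    "truncated-gaussian", 20, 40,  mean = 25,  sd = 12.5),
    dist_spec("BSM_lon",    "truncated-gaussian", 45, 65,  mean = 50,  sd = 10)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

## names every library must be able to provide to the canopy model
simulator_input_names <- function() {
  c("N", "Cab", "Cm", "Cw", "Cxc", "LAI", "LIDF", "alpha_soil",
    "SZA", "OZA", "RAA", "SMC", "B_soil", "BSM_lat", "BSM_lon")
}

## rejection sampler: redraw out-of-range values so the truncated density has
## no boundary atoms (clipping would pile mass at min/max)
rtruncnorm_reject <- function(n, mean, sd, min, max) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < min | out > max)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < min | out[bad] > max]
  }
  out
}

draw_spec <- function(spec, n) {
  switch(spec$kind,
    "uniform" = stats::runif(n, spec$min, spec$max),
    "fixed" = rep(spec$min, n),
    "truncated-gaussian" =
      rtruncnorm_reject(n, spec$mean, spec$sd, spec$min, spec$max)
  )
}

#' Draw simulator input samples
#'
#' Draws `n` joint realizations of the simulator input variables from their
#' declared distributions. Truncated Gaussians are realized by rejection
#' sampling inside `[min, max]`. Reproducible for a fixed seed.
#'
#' @param specs Named list of [dist_spec()]; must cover every variable in
#'   `simulator_input_names()` (extra variables are drawn too).
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A `data.frame` with one column per variable and `n` rows.
#' @examples
#' head(sample_inputs(default_trait_specs(), 5, seed = 1))
#' @export
sample_inputs <- function(specs, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, `[[`, "", "name")
  }
  missing <- setdiff(simulator_input_names(), names(specs))
  if (length(missing) > 0L) {
    stop("missing distribution spec for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(specs, draw_spec, n = n)
  as.data.frame(out, optional = FALSE)
}
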