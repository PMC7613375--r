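#' Configuration of the surrogate canopy reflectance model
#'
#' The simulator is a declared, fully parameterized surrogate for a full
#' radiative-transfer chain. It produces trait-driven, strongly collinear,
#' nonlinear canopy spectra via Beer-Lambert-style leaf absorption features,
#' gap-fraction soil/vegetation mixing and a weak geometric modulation. It
#' targets the statistical structure the retrieval method assumes, not
#' radiometric fidelity.
#'
#' Absorption templates are sums of Gaussians (center nm / width nm /
#' amplitude in cm^2 per unit constituent): chlorophyll at 430 and 660 nm,
#' carotenoids at 470 nm, water at 970/1200/1450/1940 nm, dry matter at
#' 1730/2100/2300 nm.
#'
#' @param rho0 Baseline leaf reflectance.
#' @param s0,s1 Leaf scattering intercept and slope in the structure
#'   parameter N: `s_N = s0 + s1 * (N - 1.5)`.
#' @param q Multiple-scattering gain of the canopy layer.
#' @param k_ext0,k_ext_lidf Extinction coefficient model
#'   `k_ext = k_ext0 * (1 + k_ext_lidf * LIDF)` (0.5 at spherical LIDF = 0).
#' @param templates Named list of absorption templates; each element is a
#'   `data.frame` with columns `center`, `width`, `amplitude`.
#' @param soil_r0 Range of the linear bare-soil baseline over
#'   `soil_lambda` nm.
#' @param soil_lambda Wavelengths anchoring the soil baseline.
#' @param soil_smc_gain Moisture darkening gain applied through the
#'   max-normalized water template.
#' @return List of class `simulator_config`.
#' @export
simulator_config <- function(rho0 = 0.02, s0 = 0.46, s1 = 0.05, q = 0.8,
                             k_ext0 = 0.5, k_ext_lidf = 0.3,
                             templates = default_absorption_templates(),
                             soil_r0 = c(0.10, 0.35),
                             soil_lambda = c(400, 2400),
                             soil_smc_gain = 0.7) {
  structure(list(rho0 = rho0, s0 = s0, s1 = s1, q = q,
                 k_ext0 = k_ext0, k_ext_lidf = k_ext_lidf,
                 templates = templates,
                 soil_r0 = soil_r0, soil_lambda = soil_lambda,
                 soil_smc_gain = soil_smc_gain),
            class = "simulator_config")
}

#' Default Gaussian absorption templates of the leaf surrogate
#' @return Named list (`k_ab`, `k_xc`, `k_w`, `k_m`) of data.frames with
#'   columns `center` (nm), `width` (nm), `amplitude`.
#' @export
default_absorption_templates <- function() {
  list(
    k_ab = data.frame(center = c(430, 660), width = c(30, 25),
                      amplitude = c(0.06, 0.04)),
    k_xc = data.frame(center = 470, width = 30, amplitude = 0.05),
    k_w  = data.frame(center = c(970, 1200, 1450, 1940),
                      width = c(40, 40, 60, 70),
                      amplitude = c(5, 10, 60, 90)),
    k_m  = data.frame(center = c(1730, 2100, 2300),
                      width = c(60, 80, 60),
                      amplitude = c(8, 12, 10))
  )
}

## evaluate one Gaussian-sum template on a wavelength grid
eval_template <- function(tpl, wl) {
  out <- numeric(length(wl))
  for (i in seq_len(nrow(tpl))) {
    out <- out + tpl$amplitude[i] *
      exp(-((wl - tpl$center[i])^2) / (2 * tpl$width[i]^2))
  }
  out
}

## internal fine grid the surrogate is evaluated on before any resampling
default_fine_grid <- function(step = 1) seq(400, 2500, by = step)

## ---- batch engine -------------------------------------------------------
## All public simulate_* operations are thin wrappers around this one code
## path, so a 1-pixel cube, a 1-row library and a direct call agree exactly.
## traits: data.frame with the simulator input columns; wl: wavelengths (nm).
## Returns leaf reflectance, absorptance, soil, canopy reflectance, gap
## fraction P, all as n x B matrices (P as length-n vector).
simulate_batch <- function(traits, wl, config = simulator_config()) {
  need <- simulator_input_names()
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    stop("trait table lacks simulator inputs: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(wl < 400 - 1e-9 | wl > 2500 + 1e-9)) {
    stop("wavelengths must lie within [400, 2500] nm", call. = FALSE)
  }
  bad <- c("Cab", "Cm", "Cw", "Cxc")[
    vapply(c("Cab", "Cm", "Cw", "Cxc"),
           function(v) any(traits[[v]] < 0), logical(1))]
  if (length(bad)) {
    stop("negative constituent content: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(traits$LAI < 0)) stop("LAI < 0", call. = FALSE)

  k_ab <- eval_template(config$templates$k_ab, wl)
  k_xc <- eval_template(config$templates$k_xc, wl)
  k_w  <- eval_template(config$templates$k_w,  wl)
  k_m  <- eval_template(config$templates$k_m,  wl)

  ## leaf: per-leaf absorption coefficient and single-pass absorptance
  a <- (outer(traits$Cab, k_ab) + outer(traits$Cxc, k_xc) +
        outer(traits$Cw,  k_w)  + outer(traits$Cm,  k_m)) / traits$N
  A <- 1 - exp(-a)
  s_N <- config$s0 + config$s1 * (traits$N - 1.5)
  rho_leaf <- pmin(pmax(config$rho0 + s_N * (1 - A), 0), 1)

  ## soil: scaled linear baseline darkened by moisture via the water shape
  r0 <- config$soil_r0[1] + diff(config$soil_r0) *
    (wl - config$soil_lambda[1]) / diff(config$soil_lambda)
  wbar <- k_w / max(k_w)
  soil <- (traits$alpha_soil * traits$B_soil) %o% r0 *
    (1 - config$soil_smc_gain * (traits$SMC / 100) %o% wbar)
  soil <- pmin(pmax(soil, 0), 1)

  ## canopy: gap-fraction mixing plus declared geometric modulation
  k_ext <- config$k_ext0 * (1 + config$k_ext_lidf * traits$LIDF)
  P <- exp(-k_ext * traits$LAI)
  deg <- pi / 180
  g_geo <- 1 + 0.05 * (cos(traits$OZA * deg) - 1) +
    0.02 * cos(traits$RAA * deg) * sin(traits$SZA * deg) * sin(traits$OZA * deg)
  R <- g_geo * ((1 - P) * rho_leaf * (1 + config$q * (1 - A)) + P * soil)
  R <- pmin(pmax(R, 0), 1)

  list(R = R, A = A, rho_leaf = rho_leaf, soil = soil, P = P, g_geo = g_geo)
}

as_trait_row <- function(sample) {
  if (is.data.frame(sample)) sample else as.data.frame(as.list(sample))
}

#' Simulate leaf reflectance and absorptance
#'
#' Single-pass Beer-Lambert leaf surrogate: the absorption coefficient is
#' the constituent-weighted sum of the Gaussian templates divided by the
#' structure parameter N; absorptance is `1 - exp(-a)`; reflectance is a
#' baseline plus an N-dependent scattering term on the transmitted fraction.
#'
#' @param sample Named list/one-row data.frame with at least `N`, `Cab`,
#'   `Cm`, `Cw`, `Cxc` (other simulator inputs may be present).
#' @param wavelengths Wavelength grid in nm, within `[400, 2500]`.
#' @param config A [simulator_config()].
#' @return List with `reflectance` and `absorptance` vectors.
#' @export
simulate_leaf <- function(sample, wavelengths, config = simulator_config()) {
  tr <- fill_missing_inputs(as_trait_row(sample))
  out <- simulate_batch(tr, wavelengths, config)
  list(reflectance = drop(out$rho_leaf), absorptance = drop(out$A))
}

#' Simulate canopy reflectance for one sample
#'
#' Mixes leaf and soil spectra by the nadir gap fraction
#' `P = exp(-k_ext * LAI)` with a multiple-scattering gain on the vegetated
#' part and a weak sun/view geometric modulation; output clipped to
#' `[0, 1]`.
#'
#' @inheritParams simulate_leaf
#' @param leaf Optional list as returned by [simulate_leaf()]; computed if
#'   missing.
#' @param soil Optional soil reflectance on the same grid; computed from the
#'   sample's soil variables if missing.
#' @return List with `reflectance`, `P` (gap fraction), `absorptance`.
#' @export
simulate_canopy <- function(sample, wavelengths, leaf = NULL, soil = NULL,
                            config = simulator_config()) {
  tr <- fill_missing_inputs(as_trait_row(sample))
  out <- simulate_batch(tr, wavelengths, config)
  R <- drop(out$R)
  if (!is.null(leaf) || !is.null(soil)) {
    rho_leaf <- if (is.null(leaf)) drop(out$rho_leaf) else leaf$reflectance
    A <- if (is.null(leaf)) drop(out$A) else leaf$absorptance
    rs <- if (is.null(soil)) drop(out$soil) else soil
    if (length(rs) != length(wavelengths)) {
      stop("soil spectrum not on the requested grid", call. = FALSE)
    }
    R <- pmin(pmax(drop(out$g_geo) *
      ((1 - out$P) * rho_leaf * (1 + config$q * (1 - A)) + out$P * rs), 0), 1)
  }
  list(reflectance = R, P = out$P, absorptance = drop(out$A))
}

## complete a partial sample with neutral values so single-op calls work
fill_missing_inputs <- function(tr) {
  defaults <- list(N = 1.5, Cab = 0, Cm = 0, Cw = 0, Cxc = 0, LAI = 0,
                   LIDF = 0, alpha_soil = 0.5, SZA = 30, OZA = 0, RAA = 0,
                   SMC = 25, B_soil = 0.5, BSM_lat = 25, BSM_lon = 50)
  for (v in names(defaults)) if (is.null(tr[[v]])) tr[[v]] <- defaults[[v]]
  tr
}

#' Derive retrieval targets from simulator state
#'
#' Computes the canopy-level targets from the leaf/canopy inputs, the PAR
#' absorptance and the gap fraction: `FVC = 1 - P`,
#' `FAPAR = (1 - P) * mean(A)` over 400-700 nm, `CCC = LAI * Cab * 1e-2`
#' (g/m^2), `CWC = LAI * Cw * 1e4` (g/m^2), `SLA = 1/Cm` (cm^2/g).
#'
#' @param sample Named list/one-row data.frame with `LAI`, `Cab`, `Cw`, `Cm`.
#' @param absorptance Leaf absorptance spectrum aligned with `wavelengths`.
#' @param P Gap fraction in `[0, 1]`.
#' @param wavelengths Wavelengths (nm) of `absorptance`.
#' @return Named list `SLA`, `LAI`, `CCC`, `CWC`, `FAPAR`, `FVC`.
#' @export
derive_traits <- function(sample, absorptance, P, wavelengths) {
  tr <- as_trait_row(sample)
  if (any(P < -1e-12 | P > 1 + 1e-12)) stop("P must be in [0, 1]", call. = FALSE)
  if (any(tr$Cm == 0)) stop("Cm = 0: SLA undefined", call. = FALSE)
  par_idx <- which(wavelengths >= 400 & wavelengths <= 700)
  if (length(par_idx) == 0L) stop("no PAR wavelengths (400-700 nm) present",
                                  call. = FALSE)
  A <- if (is.matrix(absorptance)) absorptance else
    matrix(absorptance, nrow = nrow(tr), byrow = TRUE,
           ncol = length(wavelengths))
  apar <- rowMeans(A[, par_idx, drop = FALSE])
  list(SLA = 1 / tr$Cm,
       LAI = tr$LAI,
       CCC = tr$LAI * tr$Cab * 1e-2,
       CWC = tr$LAI * tr$Cw * 1e4,
       FAPAR = (1 - P) * apar,
       FVC = 1 - P)
}

#' Simulate a spectral library from an explicit trait table
#'
#' Shared workhorse of [generate_library()] and
#' [generate_synthetic_cube()]: runs the surrogate on a fine internal grid,
#' resamples to the requested band grid, and attaches derived targets.
#'
#' @param traits `data.frame` of simulator inputs (one row per sample).
#' @param grid A [band_grid()]; `NULL` keeps the fine internal grid.
#' @param config A [simulator_config()].
#' @param fine_step Step (nm) of the internal simulation grid.
#' @param meta Extra metadata entries.
#' @return A [spectral_library()] whose trait table holds the inputs plus
#'   the derived targets and a `surface` label.
#' @export
simulate_from_traits <- function(traits, grid = NULL,
                                 config = simulator_config(),
                                 fine_step = 1, meta = list()) {
  wl_fine <- default_fine_grid(fine_step)
  out <- simulate_batch(traits, wl_fine, config)
  tg <- derive_traits(traits, out$A, out$P, wl_fine)
  tab <- cbind(traits, as.data.frame(tg[setdiff(names(tg), "LAI")]))
  tab$surface <- "vegetated"
  if (is.null(grid)) {
    wl <- wl_fine
    R <- out$R
  } else {
    wl <- grid$centers
    R <- gaussian_resample(wl_fine, out$R, grid)
  }
  meta$generator <- "hytrait surrogate v1"
  spectral_library(wl, R, tab, meta)
}

#' Generate a trait-labelled canopy reflectance library
#'
#' End-to-end composition: draw inputs from the distributions, run the leaf
#' and canopy surrogate on a fine grid, resample to the band grid, derive
#' targets. Deterministic for a fixed seed.
#'
#' @param specs Named list of [dist_spec()] (default [default_trait_specs()]).
#' @param n Number of samples (the standard training pool uses 2000).
#' @param grid A [band_grid()] or `NULL` for the fine 1 nm grid.
#' @param seed Integer seed.
#' @param config A [simulator_config()].
#' @param fine_step Internal simulation step in nm.
#' @return A [spectral_library()].
#' @examples
#' lib <- generate_library(n = 10, grid = band_grid(400, 2500, 50, 50), seed = 1)
#' dim(lib)
#' @export
generate_library <- function(specs = default_trait_specs(), n = 2000,
                             grid = NULL, seed = NULL,
                             config = simulator_config(), fine_step = 1) {
  traits <- sample_inputs(specs, n, seed)
  simulate_from_traits(traits, grid, config, fine_step,
                       meta = list(seed = seed, n = n))
}

## ---- non-vegetated archetypes ------------------------------------------

nonveg_archetypes <- function() c("soil_bright", "soil_dark", "water", "man_made")

## archetype templates on an arbitrary grid; smooth, in [0,1]
nonveg_template <- function(kind, wl) {
  r0 <- 0.10 + 0.25 * (wl - 400) / 2000
  wbar <- eval_template(default_absorption_templates()$k_w, wl)
  wbar <- wbar / max(wbar)
  switch(kind,
    soil_bright = pmin(1.3 * r0 * (1 - 0.15 * wbar), 1),
    soil_dark   = 0.45 * r0 * (1 - 0.30 * wbar),
    water       = 0.02 + 0.07 * exp(-pmax(wl - 550, 0) / 150),
    man_made    = rep(0.25, length(wl)),
    stop("unknown archetype: ", kind, call. = FALSE)
  )
}

#' Generate zero-labelled non-vegetated spectra
#'
#' Builds augmentation spectra of bare soils (bright/dark, smooth convex),
#' water (low, decaying beyond the red edge) and man-made surfaces (flat
#' gray) with multiplicative jitter, and sets every trait target to zero.
#' Appending them to a training set teaches the regressor to map
#' non-vegetated surfaces near zero.
#'
#' @param n Number of spectra (the standard augmentation uses 26).
#' @param grid A [band_grid()] or `NULL` for the fine grid.
#' @param seed Integer seed.
#' @param jitter SD of the per-spectrum multiplicative log-normal jitter;
#'   `0` reproduces the archetype templates exactly.
#' @param proportions Named sampling weights over the four archetypes.
#' @param fine_step Internal grid step (nm).
#' @return A [spectral_library()] with all trait targets 0 and a `surface`
#'   label per row.
#' @export
generate_nonvegetated <- function(n = 26, grid = NULL, seed = NULL,
                                  jitter = 0.1,
                                  proportions = c(soil_bright = 0.35,
                                                  soil_dark = 0.25,
                                                  water = 0.2,
                                                  man_made = 0.2),
                                  fine_step = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  kinds <- sample(names(proportions), n, replace = TRUE, prob = proportions)
  wl_fine <- default_fine_grid(fine_step)
  R <- t(vapply(seq_len(n), function(i) {
    f <- if (jitter > 0) exp(stats::rnorm(1, 0, jitter)) else 1
    pmin(pmax(nonveg_template(kinds[i], wl_fine) * f, 0), 1)
  }, numeric(length(wl_fine))))
  tab <- data.frame(matrix(NA_real_, n, length(simulator_input_names()),
                           dimnames = list(NULL, simulator_input_names())))
  for (v in trait_target_names()) tab[[v]] <- 0
  tab$surface <- kinds
  if (!is.null(grid)) {
    R <- gaussian_resample(wl_fine, R, grid)
    wl <- grid$centers
  } else wl <- wl_fine
  spectral_library(wl, R, tab, meta = list(seed = seed, kind = "nonvegetated"))
}

## ---- synthetic scenes ---------------------------------------------------

## low-frequency random surface in [0,1]: smoothed white noise, rank-mapped
smooth_field <- function(rows, cols, scale = 6) {
  pad <- 3 * scale
  z <- matrix(stats::rnorm((rows + 2 * pad) * (cols + 2 * pad)),
              rows + 2 * pad, cols + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = scale)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  z <- z[pad + seq_len(rows), pad + seq_len(cols), drop = FALSE]
  matrix(rank(z, ties.method = "first") / (rows * cols + 1), rows, cols)
}

## map a uniform field through a distribution spec's quantile function
field_to_spec <- function(u, spec) {
  switch(spec$kind,
    "uniform" = spec$min + u * (spec$max - spec$min),
    "fixed" = rep(spec$min, length(u)),
    "truncated-gaussian" = {
      pl <- stats::pnorm(spec$min, spec$mean, spec$sd)
      pu <- stats::pnorm(spec$max, spec$mean, spec$sd)
      stats::qnorm(pl + u * (pu - pl), spec$mean, spec$sd)
    })
}

#' Generate a synthetic hyperspectral scene with per-pixel truth
#'
#' Builds spatially smooth trait fields (low-frequency random surfaces
#' mapped through the input distributions), runs them through the canopy
#' surrogate, and assigns a fraction of pixels to non-vegetated archetypes
#' whose truth targets are zero. A test stand-in for a real scene.
#'
#' @param rows,cols Scene dimensions in pixels.
#' @param grid A [band_grid()] or `NULL` for the fine grid.
#' @param seed Integer seed.
#' @param specs Input distributions (see [default_trait_specs()]).
#' @param frac_nonveg Fraction of pixels drawn as non-vegetated surfaces.
#' @param smoothness Correlation length (pixels) of the trait fields.
#' @param config A [simulator_config()].
#' @param fine_step Internal grid step (nm).
#' @return List of class `synthetic_cube`: `cube` (rows x cols x bands),
#'   `wavelengths`, `truth` (list of rows x cols matrices per target),
#'   `nonveg` logical mask, `traits` flattened trait table, `meta`.
#' @export
generate_synthetic_cube <- function(rows, cols, grid = NULL, seed = NULL,
                                    specs = default_trait_specs(),
                                    frac_nonveg = 0.15, smoothness = 6,
                                    config = simulator_config(),
                                    fine_step = 1) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  npix <- rows * cols
  traits <- as.data.frame(lapply(specs, function(sp) {
    u <- if (npix == 1L) matrix(stats::runif(1), 1, 1)
         else smooth_field(rows, cols, smoothness)
    field_to_spec(as.vector(u), sp)
  }))
  names(traits) <- names(specs)

  nv_field <- if (npix == 1L) matrix(stats::runif(1), 1, 1)
              else smooth_field(rows, cols, smoothness)
  nonveg <- as.vector(nv_field) < frac_nonveg
  kinds <- sample(nonveg_archetypes(), npix, replace = TRUE)

  lib <- simulate_from_traits(traits, grid = NULL, config = config,
                              fine_step = fine_step)
  R <- lib$reflectance
  wl_fine <- lib$wavelengths
  if (any(nonveg)) {
    for (i in which(nonveg)) R[i, ] <- nonveg_template(kinds[i], wl_fine)
  }
  tab <- lib$traits
  if (any(nonveg)) {
    tab[nonveg, trait_target_names()] <- 0
    tab$surface[nonveg] <- kinds[nonveg]
  }
  if (!is.null(grid)) {
    R <- gaussian_resample(wl_fine, R, grid)
    wl <- grid$centers
  } else wl <- wl_fine

  truth <- lapply(trait_target_names(), function(v) {
    matrix(tab[[v]], rows, cols)
  })
  names(truth) <- trait_target_names()
  structure(
    list(cube = array(R, c(rows, cols, length(wl))),
         wavelengths = wl,
         truth = truth,
         nonveg = matrix(nonveg, rows, cols),
         traits = tab,
         meta = list(seed = seed, rows = rows, cols = cols)),
    class = "synthetic_cube")
}

#' @export
print.synthetic_cube <- function(x, ...) {
  cat(sprintf("<synthetic_cube> %d x %d pixels, %d bands, %.0f%% non-vegetated\n",
              x$meta$rows, x$meta$cols, length(x$wavelengths),
              100 * mean(x$nonveg)))
  invisible(x)
}
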