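#' Configuration of one retrieval strategy
#'
#' Declares how a trait-specific model is built: the target variable, the
#' spectral reduction mode (20 principal components, 20 ranked bands, or no
#' reduction), the training-set optimization (active learning against a
#' reference, or a random bypass for targets without reference data), the
#' band grid and exclusion windows, and the seed.
#'
#' @param variable One of `"SLA"`, `"LAI"`, `"CCC"`, `"CWC"`, `"FAPAR"`,
#'   `"FVC"`.
#' @param mode `"PCA"`, `"BR"` or `"ALL_BANDS"`.
#' @param n_features Number of components/bands kept (default 20).
#' @param al An [al_config()], or `NULL` to use the random bypass.
#' @param bypass_n Random-bypass sample count (default 1000; used when `al`
#'   is `NULL` or no reference is supplied — the FAPAR/FVC situation).
#' @param n_nonveg Zero-labelled augmentation spectra appended (default 26).
#' @param grid A [band_grid()] (default the 10 nm preset).
#' @param windows An [exclusion_windows()] (default
#'   [default_exclusion_windows()]).
#' @param seed Integer seed.
#' @param sbbr_rows Training rows subsampled for the band-ranking wrapper
#'   (keeps the wrapper tractable; the final model uses all rows).
#' @param sbbr_folds CV folds for SBBR.
#' @param fit_maxit Optimizer iteration cap for the final GPR fit.
#' @return List of class `strategy_config`.
#' @export
strategy_config <- function(variable, mode = c("PCA", "BR", "ALL_BANDS"),
                            n_features = 20, al = NULL, bypass_n = 1000,
                            n_nonveg = 26,
                            grid = preset_band_grid("chime10"),
                            windows = default_exclusion_windows(),
                            seed = 1, sbbr_rows = 200, sbbr_folds = 3,
                            fit_maxit = 100) {
  mode <- match.arg(mode)
  if (!variable %in% trait_target_names()) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  structure(list(variable = variable, mode = mode, n_features = n_features,
                 al = al, bypass_n = bypass_n, n_nonveg = n_nonveg,
                 grid = grid, windows = windows, seed = seed,
                 sbbr_rows = sbbr_rows, sbbr_folds = sbbr_folds,
                 fit_maxit = fit_maxit),
            class = "strategy_config")
}

#' Run one retrieval strategy end to end
#'
#' Pipeline: obtain the pool (simulated if not given) -> exclusion windows
#' -> training-set optimization (active learning against the reference, or
#' the random bypass) -> zero-labelled augmentation -> spectral reduction
#' (PCA scores, SBBR-ranked band subset, or all bands) -> GP fit ->
#' evaluation on the reference (or on a held-out pool split when no
#' reference exists).
#'
#' @param config A [strategy_config()].
#' @param pool Optional [spectral_library()] candidate pool; simulated with
#'   the default distributions (n = 2000) when `NULL`.
#' @param reference Optional [spectral_library()] with in-situ-style targets.
#' @return Object of class `trait_model`: the fitted GP plus everything
#'   needed to apply it to a cube (grid id, kept wavelengths, transform),
#'   with `stats` (a [goodness_of_fit()] on the evaluation set) and
#'   `n_train`.
#' @export
run_strategy <- function(config, pool = NULL, reference = NULL) {
  if (is.null(pool)) {
    pool <- generate_library(n = 2000, grid = config$grid, seed = config$seed)
  }
  pool <- align_to_grid(pool, config)
  if (!is.null(reference)) reference <- align_to_grid(reference, config)

  ## sampling-domain reduction
  has_ref <- !is.null(reference) &&
    config$variable %in% names(reference$traits) &&
    any(is.finite(reference$traits[[config$variable]]))
  al_result <- NULL
  if (has_ref && !is.null(config$al)) {
    al_result <- al_run(pool, reference, config$variable, config$al)
    train_lib <- al_result$library
  } else {
    train_lib <- al_random_bypass(pool, min(config$bypass_n,
                                            nrow(pool$reflectance)),
                                  seed = config$seed)
  }
  if (config$n_nonveg > 0) {
    nonveg <- generate_nonvegetated(config$n_nonveg, grid = config$grid,
                                    seed = config$seed + 1L)
    nonveg <- align_to_grid(nonveg, config)
    train_lib <- augment_zero_spectra(train_lib, nonveg)
  }

  y <- train_lib$traits[[config$variable]]
  X <- train_lib$reflectance

  ## spectral-domain reduction
  transform <- switch(config$mode,
    PCA = {
      pca <- pca_fit(X)
      n <- select_n_components(pca, n_fixed = config$n_features)
      n <- min(n, config$n_features)  # fixed-feature contract: exactly n_features
      list(kind = "pca", pca = pca, n = n)
    },
    BR = {
      rows <- seq_len(nrow(X))
      if (length(rows) > config$sbbr_rows) {
        set.seed(config$seed + 2L)
        rows <- sort(sample(rows, config$sbbr_rows))
      }
      sb <- sbbr_run(lib_subset(train_lib, rows), config$variable,
                     folds = config$sbbr_folds, seed = config$seed)
      bands <- select_best_bands(sb, config$n_features)
      list(kind = "bands", wavelengths = bands,
           index = match(bands, train_lib$wavelengths), sbbr = sb)
    },
    ALL_BANDS = list(kind = "identity"))

  F <- apply_feature_transform(transform, X)
  feature_names <- switch(transform$kind,
    pca = paste0("PC", seq_len(ncol(F))),
    bands = as.character(transform$wavelengths),
    identity = as.character(train_lib$wavelengths))

  model <- gpr_fit(F, y, restarts = 2, seed = config$seed,
                   maxit = config$fit_maxit, feature_names = feature_names)

  ## evaluation: reference if available, else a simulated held-out set
  if (has_ref) {
    eval_X <- apply_feature_transform(transform, reference$reflectance)
    eval_y <- reference$traits[[config$variable]]
  } else {
    held <- generate_library(n = 200, grid = config$grid,
                             seed = config$seed + 3L)
    held <- align_to_grid(held, config)
    eval_X <- apply_feature_transform(transform, held$reflectance)
    eval_y <- held$traits[[config$variable]]
  }
  pr <- gpr_predict(model, eval_X)
  stats <- goodness_of_fit(eval_y, pr$mean)

  structure(
    list(variable = config$variable, mode = config$mode,
         grid_id = config$grid$id, grid = config$grid,
         windows = as.data.frame(config$windows),
         kept_wavelengths = train_lib$wavelengths,
         kept_index = train_lib$meta$kept_index,
         transform = transform, gpr = model,
         al = al_result, stats = stats,
         n_train = nrow(train_lib$reflectance),
         seed = config$seed),
    class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf(paste0("<trait_model> %s (%s, %d features), trained on %d ",
                     "samples; eval NRMSE %.2f%%, R2 %.3f\n"),
              x$variable, x$mode, n_model_features(x), x$n_train,
              x$stats$NRMSE, x$stats$R2))
  invisible(x)
}

n_model_features <- function(bundle) ncol(bundle$gpr$Z)

align_to_grid <- function(lib, config) {
  if (!is.null(lib$meta$kept_index)) return(lib)  # already reduced
  apply_exclusion_windows(lib, config$windows)
}

apply_feature_transform <- function(transform, X) {
  switch(transform$kind,
    pca = pca_transform(transform$pca, X, transform$n),
    bands = X[, transform$index, drop = FALSE],
    identity = X)
}

#' Map traits over a hyperspectral cube
#'
#' Applies a trained model per pixel: the cube is aligned to the model's
#' band layout by recorded metadata (same wavelengths, or the model's
#' kept-band subset of the model's grid, or Gaussian resampling from a
#' finer grid — never nearest-wavelength guessing), the bundle's feature
#' transform is applied, and the GP posterior gives the estimate, its SD
#' and the percent coefficient of variation. Estimates are not clipped to
#' physical ranges by default so out-of-range diagnostics stay visible.
#'
#' @param bundle A [run_strategy()] model.
#' @param cube 3-D reflectance array (`rows x cols x bands`), a
#'   `synthetic_cube`, or a [read_cube()] list.
#' @param wavelengths Band centers of `cube` (taken from the object when it
#'   carries them).
#' @param clamp Optional `c(min, max)` post-hoc clamp on the estimates
#'   (default off).
#' @return Object of class `trait_map`: `estimate`, `sd`, `cv` matrices,
#'   logical `mask` of valid pixels, `variable`, `provenance`.
#' @export
map_traits <- function(bundle, cube, wavelengths = NULL, clamp = NULL) {
  if (inherits(cube, "synthetic_cube")) {
    wavelengths <- cube$wavelengths
    cube <- cube$cube
  } else if (is.list(cube) && !is.null(cube$cube)) {
    if (is.null(wavelengths)) wavelengths <- cube$wavelengths
    cube <- cube$cube
  }
  if (length(dim(cube)) != 3) stop("cube must be a 3-D array", call. = FALSE)
  if (is.null(wavelengths)) stop("cube wavelengths unknown", call. = FALSE)
  d <- dim(cube)
  X <- matrix(cube, d[1] * d[2], d[3])

  X <- align_cube_bands(X, wavelengths, bundle)

  mask <- apply(is.finite(X), 1, all)
  est <- sd_m <- cv_m <- rep(NA_real_, nrow(X))
  if (any(mask)) {
    F <- apply_feature_transform(bundle$transform, X[mask, , drop = FALSE])
    pr <- gpr_predict(bundle$gpr, F)
    est[mask] <- pr$mean
    sd_m[mask] <- pr$sd
    cv_m[mask] <- pr$cv
  } else stop("all cube pixels are masked", call. = FALSE)
  if (!is.null(clamp)) est <- pmin(pmax(est, clamp[1]), clamp[2])

  structure(
    list(estimate = matrix(est, d[1], d[2]),
         sd = matrix(sd_m, d[1], d[2]),
         cv = matrix(cv_m, d[1], d[2]),
         mask = matrix(mask, d[1], d[2]),
         variable = bundle$variable,
         provenance = list(mode = bundle$mode, grid_id = bundle$grid_id,
                           n_features = n_model_features(bundle))),
    class = "trait_map")
}

#' @export
print.trait_map <- function(x, ...) {
  cat(sprintf("<trait_map> %s (%s): %d x %d pixels, %d valid; range [%.3g, %.3g]\n",
              x$variable, x$provenance$mode, nrow(x$estimate),
              ncol(x$estimate), sum(x$mask),
              min(x$estimate, na.rm = TRUE), max(x$estimate, na.rm = TRUE)))
  invisible(x)
}

## align flattened cube bands to the bundle's kept wavelengths using
## recorded metadata; hard error on mismatch
align_cube_bands <- function(X, wavelengths, bundle) {
  target <- bundle$kept_wavelengths
  if (length(wavelengths) == length(target) &&
      all(abs(wavelengths - target) < 1e-6)) {
    return(X)
  }
  full <- bundle$grid$centers
  if (length(wavelengths) == length(full) &&
      all(abs(wavelengths - full) < 1e-6)) {
    return(X[, bundle$kept_index, drop = FALSE])
  }
  ## finer source grid: resample through the model's grid, then subset
  if (length(wavelengths) > length(full) &&
      min(wavelengths) <= min(full) && max(wavelengths) >= max(full)) {
    Xr <- gaussian_resample(wavelengths, X, bundle$grid)
    return(Xr[, bundle$kept_index, drop = FALSE])
  }
  stop("cube bands cannot be aligned to the model's recorded grid (",
       bundle$grid_id, ")", call. = FALSE)
}

## ---- model bundle serialization ----------------------------------------

#' Save / load a trained trait model as JSON
#'
#' Text serialization of everything [map_traits()] needs: hyperparameters,
#' standardization constants, training arrays, transform (PCA loadings or
#' band subset) and grid metadata. Arrays are stored at full precision.
#'
#' @param bundle A [run_strategy()] model.
#' @param path Output path (`.json`).
#' @return `path` (write) or the restored `trait_model` (load).
#' @export
save_trait_model <- function(bundle, path) {
  tr <- bundle$transform
  obj <- list(
    variable = bundle$variable, mode = bundle$mode,
    grid = list(centers = bundle$grid$centers, fwhm = bundle$grid$fwhm,
                id = bundle$grid$id),
    windows = bundle$windows,
    kept_wavelengths = bundle$kept_wavelengths,
    kept_index = bundle$kept_index,
    transform = switch(tr$kind,
      pca = list(kind = "pca", n = tr$n, center = tr$pca$center,
                 rotation = tr$pca$rotation,
                 eigenvalues = tr$pca$eigenvalues),
      bands = list(kind = "bands", wavelengths = tr$wavelengths,
                   index = tr$index),
      identity = list(kind = "identity")),
    gpr = list(Z = bundle$gpr$Z, y = bundle$gpr$y,
               y_center = bundle$gpr$y_center,
               x_center = bundle$gpr$x_center, x_scale = bundle$gpr$x_scale,
               theta = unclass(bundle$gpr$theta),
               feature_names = bundle$gpr$feature_names,
               log_evidence = bundle$gpr$log_evidence),
    stats = unclass(bundle$stats),
    n_train = bundle$n_train, seed = bundle$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_trait_model
#' @export
load_trait_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- structure(list(centers = o$grid$centers, fwhm = o$grid$fwhm,
                         id = o$grid$id), class = "band_grid")
  transform <- switch(o$transform$kind,
    pca = list(kind = "pca",
               pca = structure(list(center = o$transform$center,
                                    rotation = o$transform$rotation,
                                    eigenvalues = o$transform$eigenvalues,
                                    var_ratio = o$transform$eigenvalues /
                                      sum(o$transform$eigenvalues)),
                               class = "pca_model"),
               n = o$transform$n),
    bands = list(kind = "bands", wavelengths = o$transform$wavelengths,
                 index = o$transform$index),
    identity = list(kind = "identity"))
  theta <- gpr_hyperparams(o$gpr$theta$sigma_f2, o$gpr$theta$alpha_mix,
                           o$gpr$theta$lengthscales, o$gpr$theta$sigma_n2)
  Z <- as.matrix(o$gpr$Z)
  D <- scaled_sqdist(Z, Z, theta$lengthscales)
  K <- theta$sigma_f2 * exp(-theta$alpha_mix * log1p(D / (2 * theta$alpha_mix)))
  cj <- chol_jitter(K + diag(theta$sigma_n2, nrow(Z)), theta$sigma_f2)
  yc <- o$gpr$y - o$gpr$y_center
  gpr <- structure(
    list(Z = Z, y = o$gpr$y, y_center = o$gpr$y_center,
         x_center = o$gpr$x_center, x_scale = o$gpr$x_scale,
         theta = theta, L = cj$L,
         weights = backsolve(cj$L, backsolve(cj$L, yc, transpose = TRUE)),
         jitter = cj$jitter, log_evidence = o$gpr$log_evidence,
         feature_names = o$gpr$feature_names),
    class = "gpr_model")
  structure(
    list(variable = o$variable, mode = o$mode, grid_id = o$grid$id,
         grid = grid, windows = o$windows,
         kept_wavelengths = o$kept_wavelengths, kept_index = o$kept_index,
         transform = transform, gpr = gpr, al = NULL,
         stats = structure(o$stats, class = "fit_stats"),
         n_train = o$n_train, seed = o$seed),
    class = "trait_model")
}

#' Write a run manifest
#'
#' Records the exact invocation (arguments, seeds, package version, time)
#' as JSON next to a run's outputs so results can be traced and reproduced.
#'
#' @param path Output path.
#' @param invocation Character or list describing the call.
#' @param seed Integer seed used.
#' @param extra Named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, invocation, seed = NULL, extra = list()) {
  obj <- c(list(invocation = invocation, seed = seed,
                package = "hytrait",
                version = as.character(utils::packageVersion("hytrait")),
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
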