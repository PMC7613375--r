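#' Active-learning configuration
#'
#' Settings of the pool-based Euclidean-distance-based diversity (EBD)
#' optimization: start from a random seed set, repeatedly propose the pool
#' sample most distant from the training set, and keep it only if the
#' reference-set RMSE improves.
#'
#' @param initial_size Random seed-set size (default 200, i.e. 10% of the
#'   standard 2000-sample pool).
#' @param stop_size Stop after this many accepted samples (default 500).
#' @param compression Number of principal components used *inside* the loop
#'   for speed (default 20); the returned library keeps all bands.
#' @param seed Integer seed.
#' @param max_rejections Consecutive rejections tolerated before stopping.
#' @param refit_every Re-optimize GPR hyperparameters after this many
#'   acceptances (warm-started; kept only if the reference RMSE does not
#'   worsen). `Inf` fixes them at the initial fit.
#' @param fit_maxit Optimizer iteration cap for hyperparameter fits.
#' @return List of class `al_config`.
#' @export
al_config <- function(initial_size = 200, stop_size = 500, compression = 20,
                      seed = NULL, max_rejections = Inf, refit_every = 50,
                      fit_maxit = 60) {
  if (initial_size >= stop_size) {
    stop("initial_size must be < stop_size", call. = FALSE)
  }
  structure(list(initial_size = initial_size, stop_size = stop_size,
                 compression = compression, seed = seed,
                 max_rejections = max_rejections, refit_every = refit_every,
                 fit_maxit = fit_maxit),
            class = "al_config")
}

#' Squared Euclidean distances and diversity score of a candidate
#'
#' `d_E(u, l) = ||x_u - x_l||^2` to every training sample; the diversity
#' score is the minimum (distance to the nearest training sample).
#'
#' @param x_u Candidate feature vector.
#' @param X_train Training feature matrix.
#' @return List with `distances` (length `nrow(X_train)`) and `score`.
#' @export
ebd_distance <- function(x_u, X_train) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) == 0L) stop("empty training set", call. = FALSE)
  d <- colSums((t(X_train) - as.numeric(x_u))^2)
  list(distances = unname(d), score = min(d))
}

#' Select the most diverse pool candidate
#'
#' Argmax over the pool of the EBD diversity score (minimum squared
#' Euclidean distance to the training set); ties break to the lowest index.
#'
#' @param X_pool Pool feature matrix.
#' @param X_train Training feature matrix.
#' @return Index into `X_pool`.
#' @export
ebd_select <- function(X_pool, X_train) {
  X_pool <- as.matrix(X_pool)
  if (nrow(X_pool) == 0L) stop("empty pool", call. = FALSE)
  scores <- pool_min_sqdist(X_pool, as.matrix(X_train))
  which.max(scores)  # which.max returns the first (lowest) index on ties
}

## min over training rows of squared distances, for every pool row
pool_min_sqdist <- function(X_pool, X_train) {
  D <- outer(rowSums(X_pool^2), rowSums(X_train^2), "+") -
    2 * tcrossprod(X_pool, X_train)
  D[D < 0] <- 0
  apply(D, 1, min)
}

#' Run EBD active learning against a reference set
#'
#' Optimizes a training library drawn from `pool` for one target variable:
#' spectra are compressed to principal components fitted on the pool (the
#' reference is projected with the same transform), a random seed set is
#' drawn, and EBD-most-remote candidates are proposed one at a time. A
#' candidate is accepted iff the reference-set RMSE strictly decreases;
#' rejected candidates are permanently discarded. Stops at `stop_size`
#' accepted samples, pool exhaustion, or the rejection cap. Early
#' convergence (pool exhausted before `stop_size`) is reported, not an
#' error. The returned library preserves all original bands.
#'
#' @param pool A [spectral_library()] (the candidate pool).
#' @param reference A [spectral_library()] with targets for `variable`.
#' @param variable Target name (e.g. `"LAI"`).
#' @param config An [al_config()].
#' @return List of class `al_result`: `accepted` (pool row indices in
#'   acceptance order), `curve` (`data.frame` n/RMSE/NRMSE/R2 per accepted
#'   sample), `rejected`, `library` (accepted rows, all bands),
#'   `converged_early`.
#' @export
al_run <- function(pool, reference, variable, config = al_config()) {
  if (!variable %in% names(reference$traits) ||
      all(is.na(reference$traits[[variable]]))) {
    stop("reference lacks target variable '", variable, "'", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n_pool <- nrow(pool$reflectance)
  if (config$stop_size > n_pool) {
    stop("stop_size exceeds pool size", call. = FALSE)
  }

  ## in-loop compression: PCA fitted on the pool, reference projected with it
  ncomp <- min(config$compression, ncol(pool$reflectance), n_pool - 1)
  pca <- pca_fit(pool$reflectance)
  Xp <- pca_transform(pca, pool$reflectance, ncomp)
  Xr <- pca_transform(pca, reference$reflectance, ncomp)
  y_pool <- pool$traits[[variable]]
  y_ref <- reference$traits[[variable]]
  keep_ref <- is.finite(y_ref)
  Xr <- Xr[keep_ref, , drop = FALSE]
  y_ref <- y_ref[keep_ref]
  ref_range <- diff(range(y_ref))

  train <- sample.int(n_pool, config$initial_size)
  candidates <- setdiff(seq_len(n_pool), train)

  eval_rmse <- function(model) {
    pr <- gpr_predict(model, Xr)
    sqrt(mean((pr$mean - y_ref)^2))
  }
  fit_full <- function(idx, init = NULL) {
    ## capped optimizer budget by design: hitting maxit here is routine
    suppressWarnings(
      gpr_fit(Xp[idx, , drop = FALSE], y_pool[idx], init = init,
              restarts = if (is.null(init)) 2 else 0,
              seed = config$seed, maxit = config$fit_maxit))
  }
  ## weights-only refit: reuse hyperparameters, recompute the factorization
  fit_fixed <- function(idx, theta) {
    gpr_fit(Xp[idx, , drop = FALSE], y_pool[idx], init = theta,
            optimize = FALSE)
  }

  model <- fit_full(train)
  cur_rmse <- eval_rmse(model)
  curve <- list(al_curve_row(length(train), cur_rmse, ref_range,
                             model, Xr, y_ref))
  rejected <- integer(0)
  n_rej_streak <- 0L
  accept_since_refit <- 0L

  while (length(train) < config$stop_size && length(candidates) > 0L &&
         n_rej_streak < config$max_rejections) {
    pick <- ebd_select(Xp[candidates, , drop = FALSE],
                       Xp[train, , drop = FALSE])
    cand <- candidates[pick]
    trial <- fit_fixed(c(train, cand), model$theta)
    trial_rmse <- eval_rmse(trial)
    if (trial_rmse < cur_rmse) {
      train <- c(train, cand)
      model <- trial
      cur_rmse <- trial_rmse
      n_rej_streak <- 0L
      accept_since_refit <- accept_since_refit + 1L
      if (accept_since_refit >= config$refit_every) {
        refit <- fit_full(train, init = model$theta)
        refit_rmse <- eval_rmse(refit)
        if (refit_rmse <= cur_rmse) {  # keep only non-worsening refits
          model <- refit
          cur_rmse <- refit_rmse
        }
        accept_since_refit <- 0L
      }
      curve[[length(curve) + 1L]] <-
        al_curve_row(length(train), cur_rmse, ref_range, model, Xr, y_ref)
    } else {
      rejected <- c(rejected, cand)
      n_rej_streak <- n_rej_streak + 1L
    }
    candidates <- setdiff(candidates, cand)
  }

  structure(
    list(accepted = train,
         curve = do.call(rbind, curve),
         rejected = rejected,
         library = lib_subset(pool, train),
         variable = variable,
         converged_early = length(train) < config$stop_size),
    class = "al_result")
}

al_curve_row <- function(n, rmse, ref_range, model, Xr, y_ref) {
  pr <- gpr_predict(model, Xr)
  r2 <- suppressWarnings(stats::cor(y_ref, pr$mean)^2)
  data.frame(n = n, RMSE = rmse, NRMSE = 100 * rmse / ref_range,
             R2 = if (is.finite(r2)) r2 else NA_real_)
}

#' @export
print.al_result <- function(x, ...) {
  cat(sprintf(paste0("<al_result> %s: %d accepted, %d rejected, final ",
                     "RMSE %.4g%s\n"),
              x$variable, length(x$accepted), length(x$rejected),
              utils::tail(x$curve$RMSE, 1),
              if (x$converged_early) " (converged before stop_size)" else ""))
  invisible(x)
}

#' Random-sample bypass for variables without reference data
#'
#' For targets with no in-situ reference (FAPAR, FVC) the active-learning
#' loop cannot be scored; instead a random subset of the pool is drawn
#' (default 1000 samples).
#'
#' @param pool A [spectral_library()].
#' @param n Number of samples to draw.
#' @param seed Integer seed.
#' @return A [spectral_library()] of `n` random pool rows.
#' @export
al_random_bypass <- function(pool, n = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n > nrow(pool$reflectance)) stop("n exceeds pool size", call. = FALSE)
  lib_subset(pool, sample.int(nrow(pool$reflectance), n))
}

#' Append zero-labelled non-vegetated spectra to a training library
#'
#' Row-concatenates the training set with the non-vegetated augmentation
#' set (all trait targets zero); provenance labels are retained via the
#' `surface` column. Band grids must match.
#'
#' @param library Training [spectral_library()].
#' @param nonveg Non-vegetated [spectral_library()] (e.g.
#'   [generate_nonvegetated()]); may have zero rows (identity).
#' @return The augmented [spectral_library()].
#' @export
augment_zero_spectra <- function(library, nonveg) {
  lib_rbind(library, nonveg)
}
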