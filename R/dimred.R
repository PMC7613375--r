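#' Principal component analysis of a spectral matrix
#'
#' Eigen-analysis of the feature covariance of the mean-centered spectra
#' (computed by singular value decomposition for numerical stability).
#' Deterministic sign convention: each loading's largest-magnitude element
#' is positive. Reflectance is centered but not standardized: all bands
#' share units and the decomposition is defined on the covariance matrix.
#'
#' @param X Spectra matrix (`n x B`), `n >= 2`.
#' @return Object of class `pca_model`: `center`, `rotation` (orthonormal
#'   loadings, columns), `eigenvalues` (descending), `var_ratio`
#'   (explained-variance fractions summing to 1).
#' @export
pca_fit <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  rot <- sv$v
  ## fix signs: largest-|.| element of each loading positive
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  tot <- sum(ev)
  structure(
    list(center = center, rotation = rot, eigenvalues = ev,
         var_ratio = if (tot > 0) ev / tot else rep(0, length(ev))),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d features, %d components; PC1 ratio %.4f\n",
              nrow(x$rotation), ncol(x$rotation), x$var_ratio[1]))
  invisible(x)
}

#' Choose the number of retained components
#'
#' Smallest count whose cumulative explained-variance ratio exceeds
#' `threshold`; in fixed-feature mode (`n_fixed`), at least `n_fixed`
#' components are kept (the standard retrieval setting keeps 20).
#'
#' @param model A [pca_model][pca_fit()].
#' @param threshold Variance fraction in (0, 1); default 0.9995.
#' @param n_fixed Optional lower bound on the count (fixed-n mode).
#' @return Integer component count.
#' @export
select_n_components <- function(model, threshold = 0.9995, n_fixed = NULL) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  cum <- cumsum(model$var_ratio)
  hit <- which(cum > threshold)
  if (length(hit) == 0L) {
    warning("threshold numerically unreachable; keeping all components")
    n <- length(cum)
  } else n <- hit[1]
  if (!is.null(n_fixed)) n <- max(n, n_fixed)
  min(n, length(cum))
}

#' Project spectra onto principal components (and back)
#'
#' `pca_transform` maps centered spectra onto the first `n` loadings;
#' `pca_inverse` maps scores back to the spectral space.
#'
#' @param model A [pca_model][pca_fit()].
#' @param X Spectra (`n_samples x B`).
#' @param n Number of components (default: all).
#' @return Score matrix (`n_samples x n`).
#' @export
pca_transform <- function(model, X, n = ncol(model$rotation)) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop("band count does not match the fitted PCA", call. = FALSE)
  }
  sweep(X, 2, model$center) %*% model$rotation[, seq_len(n), drop = FALSE]
}

#' @rdname pca_transform
#' @param scores Score matrix from [pca_transform()].
#' @export
pca_inverse <- function(model, scores) {
  scores <- as.matrix(scores)
  n <- ncol(scores)
  sweep(scores %*% t(model$rotation[, seq_len(n), drop = FALSE]), 2,
        model$center, "+")
}

## ---- sequential backward band removal ----------------------------------

#' Sequential backward band removal (SBBR)
#'
#' Wrapper band selection by automatic relevance determination: under
#' k-fold cross-validation, a GP is fitted per fold on the surviving bands,
#' per-fold lengthscales are ranked, and the band with the worst (largest,
#' least relevant) consensus lengthscale rank is removed; repeat until one
#' band remains. The final ranking is the removal order reversed. Fold
#' assignment is a seeded random partition held fixed across iterations so
#' iterations stay comparable. Hyperparameters are warm-started from the
#' previous iteration (dropping the removed lengthscale) unless
#' `from_scratch`.
#'
#' @param library A [spectral_library()] with the target variable.
#' @param variable Target name.
#' @param folds Number of CV folds (default 3).
#' @param seed Integer seed (fold assignment and optimizer restarts).
#' @param from_scratch Refit hyperparameters from the default
#'   initialization at every iteration instead of warm-starting.
#' @param maxit_first,maxit_warm Optimizer iteration caps for the first /
#'   warm-started iterations.
#' @return Object of class `sbbr_result`: `table` (per-iteration
#'   `data.frame`: `n_bands`, `R2`, `SD`, `Min`, `Max`, `wavelengths`
#'   string), `ranking` (wavelengths, most relevant first), `removal_order`,
#'   `folds` assignment.
#' @export
sbbr_run <- function(library, variable, folds = 3, seed = NULL,
                     from_scratch = FALSE, maxit_first = 60,
                     maxit_warm = 20) {
  y <- library$traits[[variable]]
  if (is.null(y)) stop("library lacks target '", variable, "'", call. = FALSE)
  keep_rows <- is.finite(y)
  X <- library$reflectance[keep_rows, , drop = FALSE]
  y <- y[keep_rows]
  n <- nrow(X)
  if (n < folds) stop("need at least `folds` samples", call. = FALSE)
  wl <- library$wavelengths
  B0 <- length(wl)

  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))

  surviving <- seq_len(B0)
  removal <- integer(0)
  records <- vector("list", B0)
  warm <- vector("list", folds)  # per-fold hyperparameters

  for (iter in seq_len(B0)) {
    Bcur <- length(surviving)
    r2 <- numeric(folds)
    ranks <- matrix(0, folds, Bcur)
    sig2 <- matrix(0, folds, Bcur)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      init <- if (!from_scratch) warm[[f]] else NULL
      fit <- tryCatch(
        suppressWarnings(
          gpr_fit(X[tr, surviving, drop = FALSE], y[tr], init = init,
                  restarts = if (is.null(init)) 1 else 0, seed = seed,
                  maxit = if (is.null(init)) maxit_first else maxit_warm)),
        error = function(e) NULL)
      if (is.null(fit)) {
        fit <- suppressWarnings(
          gpr_fit(X[tr, surviving, drop = FALSE], y[tr],
                  restarts = 2, seed = seed, maxit = maxit_first))
      }
      pr <- gpr_predict(fit, X[!tr, surviving, drop = FALSE])
      cc <- suppressWarnings(stats::cor(y[!tr], pr$mean))
      r2[f] <- if (is.finite(cc)) cc^2 else 0
      s2 <- fit$theta$lengthscales^2
      sig2[f, ] <- s2
      ranks[f, ] <- rank(s2, ties.method = "first")
      warm[[f]] <- fit$theta
    }
    records[[iter]] <- data.frame(
      n_bands = Bcur, R2 = mean(r2), SD = stats::sd(r2),
      Min = min(r2), Max = max(r2),
      wavelengths = paste(wl[surviving], collapse = " "))

    if (Bcur == 1L) break
    ## consensus: drop the band with the largest mean lengthscale rank
    mean_rank <- colMeans(ranks)
    worst <- which(mean_rank == max(mean_rank))
    if (length(worst) > 1L) worst <- worst[which.max(colMeans(sig2)[worst])]
    removal <- c(removal, surviving[worst])
    surviving <- surviving[-worst]
    if (!from_scratch) {
      warm <- lapply(warm, function(th) {
        if (is.null(th)) return(NULL)
        gpr_hyperparams(th$sigma_f2, th$alpha_mix,
                        th$lengthscales[-worst], th$sigma_n2)
      })
    }
  }
  removal <- c(removal, surviving)  # last survivor removed "last"
  structure(
    list(table = do.call(rbind, records),
         ranking = wl[rev(removal)],
         removal_order = wl[removal],
         variable = variable,
         folds = fold_id),
    class = "sbbr_result")
}

#' @export
print.sbbr_result <- function(x, ...) {
  cat(sprintf("<sbbr_result> %s: %d bands ranked over %d iterations\n",
              x$variable, length(x$ranking), nrow(x$table)))
  invisible(x)
}

#' Best-band subset from an SBBR ranking
#'
#' The surviving band set at the iteration with `k` bands, i.e. the top-k
#' of the final ranking (returned in ascending wavelength order).
#'
#' @param result An [sbbr_run()] result.
#' @param k Number of bands (default 20).
#' @return Numeric wavelengths (nm).
#' @export
select_best_bands <- function(result, k = 20) {
  if (k > length(result$ranking)) {
    stop("k exceeds the number of ranked bands", call. = FALSE)
  }
  sort(result$ranking[seq_len(k)])
}
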