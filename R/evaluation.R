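#' Goodness-of-fit statistics
#'
#' RMSE in target units; RRMSE = 100 RMSE / mean(observed); NRMSE =
#' 100 RMSE / range(observed); R2 as the squared Pearson correlation
#' between observed and predicted (default), or the coefficient of
#' determination about the 1:1 line (`r2 = "cod"`).
#'
#' @param observed,predicted Equal-length numeric vectors (`n >= 2`).
#' @param r2 `"pearson"` (default) or `"cod"`.
#' @return List of class `fit_stats`: `N`, `RMSE`, `RRMSE`, `NRMSE`, `R2`.
#' @examples
#' goodness_of_fit(c(0, 2, 4), c(1, 1, 5))
#' @export
goodness_of_fit <- function(observed, predicted, r2 = c("pearson", "cod")) {
  r2 <- match.arg(r2)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  n <- length(observed)
  if (n < 2) stop("need at least 2 paired values", call. = FALSE)
  rmse <- sqrt(mean((predicted - observed)^2))
  rng <- diff(range(observed))
  mn <- mean(observed)
  if (rng == 0) {
    warning("constant observations: NRMSE and R2 undefined")
    nrmse <- NA_real_
    r2v <- NA_real_
  } else {
    nrmse <- 100 * rmse / rng
    r2v <- if (r2 == "pearson") {
      suppressWarnings(stats::cor(observed, predicted))^2
    } else {
      1 - sum((predicted - observed)^2) / sum((observed - mn)^2)
    }
  }
  structure(list(N = n, RMSE = rmse,
                 RRMSE = if (mn != 0) 100 * rmse / mn else NA_real_,
                 NRMSE = nrmse, R2 = r2v),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("<fit_stats> N = %d, RMSE = %.4g, RRMSE = %.2f%%, NRMSE = %.2f%%, R2 = %.3f\n",
              x$N, x$RMSE, x$RRMSE, x$NRMSE, x$R2))
  invisible(x)
}

#' @export
as.data.frame.fit_stats <- function(x, ...) {
  data.frame(N = x$N, RMSE = x$RMSE, RRMSE = x$RRMSE,
             NRMSE = x$NRMSE, R2 = x$R2)
}

#' Consistency between two co-registered maps
#'
#' Paired statistics over the unmasked pixels of two trait maps of the same
#' scene: R2, bias (`mean(b - a)`), RMSE, and the scatter table.
#'
#' @param map_a,map_b Numeric matrices (or vectors) on the same grid.
#' @param mask Optional logical matrix; `TRUE` pixels are compared.
#' @param r2 Passed to [goodness_of_fit()].
#' @return List: `R2`, `bias`, `RMSE`, `N`, `scatter` (`data.frame` with
#'   columns `a`, `b`).
#' @export
model_consistency <- function(map_a, map_b, mask = NULL,
                              r2 = c("pearson", "cod")) {
  a <- as.vector(map_a); b <- as.vector(map_b)
  if (length(a) != length(b)) stop("maps are not co-registered", call. = FALSE)
  keep <- is.finite(a) & is.finite(b)
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  if (!any(keep)) stop("empty overlap between maps", call. = FALSE)
  a <- a[keep]; b <- b[keep]
  cc <- suppressWarnings(stats::cor(a, b))
  list(R2 = if (is.finite(cc)) cc^2 else 1,
       bias = mean(b - a),
       RMSE = sqrt(mean((b - a)^2)),
       N = length(a),
       scatter = data.frame(a = a, b = b))
}

#' Export feature relevances for a polar plot
#'
#' Lays the 0-100 relevance scores on a circle: feature k of n sits at
#' angle `2 pi (k - 1) / n` with radius equal to its relevance (the further
#' out, the more relevant). Labels are wavelengths (nm) in band-ranking
#' mode and component indices in PCA mode.
#'
#' @param relevance Numeric relevances in `[0, 100]` (see
#'   [band_relevance()]).
#' @param labels Feature labels; defaults to the names of `relevance` or
#'   indices.
#' @param path Optional CSV output path.
#' @return `data.frame` with `label`, `angle` (radians), `radius`.
#' @export
relevance_export <- function(relevance, labels = NULL, path = NULL) {
  if (any(relevance < 0 | relevance > 100)) {
    stop("relevance values must lie in [0, 100]", call. = FALSE)
  }
  n <- length(relevance)
  if (is.null(labels)) {
    labels <- if (!is.null(names(relevance))) names(relevance)
              else as.character(seq_len(n))
  }
  out <- data.frame(label = labels,
                    angle = 2 * pi * (seq_len(n) - 1) / n,
                    radius = as.numeric(relevance))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
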