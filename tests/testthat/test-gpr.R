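test_that("ARD-RQ kernel values match direct scalar evaluation", {
  th <- gpr_hyperparams(1, 1, 1, 0)
  # zero distance -> signal variance
  th2 <- gpr_hyperparams(2.5, 1.3, c(1, 2), 0.1)
  x <- matrix(c(0.3, -1), 1, 2)
  expect_equal(kernel_matrix(x, x, th2)[1, 1], 2.5, tolerance = 1e-14)
  # |d| = sqrt(2), sigma = 1, alpha = 1: (1 + 2/2)^-1 = 0.5
  K <- kernel_matrix(matrix(0), matrix(sqrt(2)), th)
  expect_equal(K[1, 1], 0.5, tolerance = 1e-14)
  # hand arithmetic on a 2-feature pair
  xi <- matrix(c(1, 2), 1); xj <- matrix(c(2, 4), 1)
  D <- (1 - 2)^2 / 1 + (2 - 4)^2 / 4
  expect_equal(kernel_matrix(xi, xj, th2)[1, 1],
               2.5 * (1 + D / (2 * 1.3))^(-1.3), tolerance = 1e-14)
  expect_error(kernel_matrix(matrix(1, 1, 3), matrix(1, 1, 3), th2),
               "dimension")
})

test_that("kernel tends to the squared exponential for large alpha", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  s <- c(0.8, 1.2, 2)
  th <- gpr_hyperparams(1, 1e6, s, 0)
  K <- kernel_matrix(X, X, th)
  D <- hytrait:::scaled_sqdist(X, X, s)
  expect_lt(max(abs(K - exp(-D / 2))), 1e-4)
})

test_that("kernel matrices are symmetric and positive semi-definite", {
  set.seed(3)
  for (i in 1:5) {
    X <- matrix(rnorm(24), 8, 3)
    th <- gpr_hyperparams(exp(runif(1, -1, 1)), exp(runif(1, -1, 1)),
                          exp(runif(3, -1, 1)), 0.05)
    K <- kernel_matrix(X, X, th)
    expect_true(isSymmetric(K, tol = 1e-12))
    ev <- eigen(K + diag(th$sigma_n2, 8), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), th$sigma_n2 - 1e-10)
  }
})

test_that("log evidence matches closed forms and a dense oracle", {
  # N = 1, y = 0: univariate Gaussian log-density at zero
  th <- gpr_hyperparams(2, 1, 1, 0.5)
  ll <- log_marginal_likelihood(matrix(0), 0, th)
  expect_equal(as.numeric(ll), -0.5 * log(2 * pi * (2 + 0.5)),
               tolerance = 1e-12)
  # dense oracle: direct multivariate normal density
  set.seed(5)
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5)
  th <- gpr_hyperparams(1.4, 0.9, c(1, 0.6, 1.8), 0.2)
  Ky <- kernel_matrix(X, X, th) + diag(0.2, 5)
  ll_dense <- -0.5 * drop(t(y) %*% solve(Ky, y)) -
    0.5 * determinant(Ky)$modulus[1] - 2.5 * log(2 * pi)
  expect_equal(as.numeric(log_marginal_likelihood(X, y, th)), ll_dense,
               tolerance = 1e-10)
  # scaling y by c changes only the quadratic data-fit term
  for (c0 in c(2, -3)) {
    llc <- as.numeric(log_marginal_likelihood(X, c0 * y, th))
    quad <- -0.5 * drop(t(y) %*% solve(Ky, y))
    expect_equal(llc - ll_dense, (c0^2 - 1) * quad, tolerance = 1e-9)
  }
})

test_that("analytic evidence gradient matches central finite differences", {
  set.seed(7)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  p0 <- c(log(1.3), log(0.8), log(0.05), log(c(0.7, 1.4, 1.1)))
  f <- function(p) {
    as.numeric(log_marginal_likelihood(X, y, hytrait:::par_to_theta(p)))
  }
  g_an <- attr(log_marginal_likelihood(X, y, hytrait:::par_to_theta(p0),
                                       grad = TRUE), "gradient")
  h <- 1e-6
  g_fd <- vapply(seq_along(p0), function(i) {
    e <- replace(numeric(length(p0)), i, h)
    (f(p0 + e) - f(p0 - e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g_an - g_fd) / pmax(abs(g_fd), 1e-6)), 1e-5)
})

test_that("posterior agrees with a brute-force dense solve on small instances", {
  set.seed(11)
  for (n in c(3, 6, 10)) {
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    th <- gpr_hyperparams(1.5, 1.2, c(0.9, 1.6), 0.1)
    model <- gpr_fit(X, y, init = th, optimize = FALSE)
    Xs <- matrix(rnorm(8), 4, 2)
    pr <- gpr_predict(model, Xs)
    # the oracle works in the model's standardized space with centered y
    Zs <- sweep(sweep(Xs, 2, model$x_center), 2, model$x_scale, "/")
    oracle <- dense_gp_posterior(model$Z, y - model$y_center, Zs, th)
    expect_equal(pr$mean, oracle$mean + model$y_center, tolerance = 1e-10)
    expect_equal(pr$variance, oracle$var, tolerance = 1e-10)
  }
})

test_that("a noiseless GP interpolates its training data", {
  set.seed(13)
  X <- matrix(rnorm(16), 8, 2)
  y <- rnorm(8)
  model <- gpr_fit(X, y, init = gpr_hyperparams(1, 1, c(1, 1), 0),
                   optimize = FALSE)
  pr <- gpr_predict(model, X)
  expect_lt(max(abs(pr$mean - y)), 1e-8)
  expect_lt(max(pr$variance), 1e-8 * model$theta$sigma_f2)
})

test_that("far from the data the posterior reverts to the prior", {
  set.seed(17)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10, mean = 5)
  model <- gpr_fit(X, y, init = gpr_hyperparams(2, 1, c(1, 1), 0.1),
                   optimize = FALSE)
  far <- matrix(1e4, 1, 2)
  pr <- gpr_predict(model, far)
  expect_equal(pr$mean, model$y_center, tolerance = 1e-6)
  expect_equal(pr$variance, model$theta$sigma_f2, tolerance = 1e-6)
})

test_that("fitting recovers lengthscale ordering from a known GP", {
  # data from a GP with one clearly narrow (relevant) feature
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 120
    X <- matrix(runif(n * 3, -2, 2), n, 3)
    true_th <- gpr_hyperparams(1, 1e5, c(0.4, 3, 3), 0)
    K <- kernel_matrix(X, X, true_th) + diag(1e-8, n)
    y <- drop(t(chol(K)) %*% rnorm(n)) + 0.05 * rnorm(n)
    # maxit deliberately tight; non-convergence warnings are expected noise
    model <- suppressWarnings(gpr_fit(X, y, restarts = 1, seed = s,
                                      maxit = 60))
    if (which.min(model$theta$lengthscales) == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("fitting improves the evidence and tolerates duplicated rows", {
  set.seed(19)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1]^2 + rnorm(20, sd = 0.1)
  init <- gpr_hyperparams(var(y), 1, c(2, 2), 0.01 * var(y))
  model <- gpr_fit(X, y, init = init, restarts = 1, seed = 1)
  Z <- model$Z; yc <- y - model$y_center
  ll0 <- as.numeric(log_marginal_likelihood(Z, yc, init))
  expect_gte(model$log_evidence, ll0 - 1e-8)
  # duplicated training row under a fixed noiseless kernel: the duplicate
  # adds no information and the jitter ladder rescues the factorization.
  # The duplicated target is pinned at the sample mean so target centering
  # (the prior constant) is unchanged by the duplication.
  th0 <- gpr_hyperparams(1, 1, c(0.6, 0.6), 0)
  y[1] <- mean(y[-1])
  Xd <- rbind(X, X[1, , drop = FALSE])
  yd <- c(y, y[1])
  md <- gpr_fit(Xd, yd, init = th0, optimize = FALSE, standardize = FALSE)
  Xs <- matrix(rnorm(10), 5, 2)
  p1 <- gpr_predict(gpr_fit(X, y, init = th0, optimize = FALSE,
                            standardize = FALSE), Xs)
  p2 <- gpr_predict(md, Xs)
  expect_lt(max(abs(p1$mean - p2$mean)), 1e-6)
  # constant targets: centered prediction returns the constant
  mc <- gpr_fit(X, rep(3, 20), init = init, optimize = FALSE)
  expect_equal(gpr_predict(mc, Xs)$mean, rep(3, 5), tolerance = 1e-8)
})

test_that("predictions are invariant to consistent feature permutation", {
  set.seed(23)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  th <- gpr_hyperparams(1.2, 1.1, c(0.5, 1, 2), 0.05)
  perm <- c(3, 1, 2)
  thp <- gpr_hyperparams(1.2, 1.1, th$lengthscales[perm], 0.05)
  m1 <- gpr_fit(X, y, init = th, optimize = FALSE)
  m2 <- gpr_fit(X[, perm], y, init = thp, optimize = FALSE)
  Xs <- matrix(rnorm(6), 2, 3)
  expect_equal(gpr_predict(m1, Xs)$mean, gpr_predict(m2, Xs[, perm])$mean,
               tolerance = 1e-10)
})

test_that("band relevance converts lengthscales as specified", {
  set.seed(29)
  X <- matrix(rnorm(20), 10, 2)
  m <- gpr_fit(X, rnorm(10),
               init = gpr_hyperparams(1, 1, c(1, 2), 0.1), optimize = FALSE)
  # sigma^2 = (1, 4): max-normalized r = (75, 0)
  expect_equal(unname(band_relevance(m)), c(75, 0), tolerance = 1e-12)
  # sum-normalized alternative: 100 (1 - s2/sum)
  expect_equal(unname(band_relevance(m, method = "sum")),
               100 * (1 - c(1, 4) / 5), tolerance = 1e-12)
  # all equal lengthscales -> all relevances equal (0 under max form)
  me <- gpr_fit(X, rnorm(10),
                init = gpr_hyperparams(1, 1, c(2, 2), 0.1), optimize = FALSE)
  expect_equal(unname(band_relevance(me)), c(0, 0))
  # single-feature model flagged, relevance 0 by convention
  m1 <- gpr_fit(X[, 1, drop = FALSE], rnorm(10),
                init = gpr_hyperparams(1, 1, 1, 0.1), optimize = FALSE)
  expect_warning(r1 <- band_relevance(m1), "single-feature")
  expect_equal(unname(r1), 0)
})
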