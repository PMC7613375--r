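# shared small fixtures, built in code at test time

# coarse band grid keeping tests fast while spanning the full range
coarse_grid <- function(step = 50) band_grid(400, 2500, step, step)

small_library <- function(n = 40, seed = 1, step = 50) {
  generate_library(n = n, grid = coarse_grid(step), seed = seed,
                   fine_step = 5)
}

# a single fully specified trait sample (all simulator inputs)
fixed_sample <- function(...) {
  s <- list(N = 1.5, Cab = 45, Cm = 0.0075, Cw = 0.015, Cxc = 10,
            LAI = 2, LIDF = 0, alpha_soil = 0.5, SZA = 30, OZA = 10,
            RAA = 90, SMC = 25, B_soil = 0.5, BSM_lat = 25, BSM_lon = 50)
  ov <- list(...)
  s[names(ov)] <- ov
  s
}

# brute-force GP posterior via dense solve(); the independent oracle
dense_gp_posterior <- function(X, y, Xs, theta) {
  K <- kernel_matrix(X, X, theta) + diag(theta$sigma_n2, nrow(X))
  Ks <- kernel_matrix(Xs, X, theta)
  Ki <- solve(K)
  list(mean = drop(Ks %*% Ki %*% y),
       var = theta$sigma_f2 - diag(Ks %*% Ki %*% t(Ks)))
}
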