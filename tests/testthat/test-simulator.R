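test_that("leaf spectrum equals the per-band closed form", {
  wl <- seq(400, 2500, by = 5)
  s <- fixed_sample()
  out <- simulate_leaf(s, wl)
  # brute-force scalar evaluation per band, independent of the matrix path
  tpl <- default_absorption_templates()
  gsum <- function(tp, l) sum(tp$amplitude * exp(-(l - tp$center)^2 /
                                                   (2 * tp$width^2)))
  for (l in wl[c(1, 13, 115, 211, 400)]) {
    a <- (s$Cab * gsum(tpl$k_ab, l) + s$Cxc * gsum(tpl$k_xc, l) +
            s$Cw * gsum(tpl$k_w, l) + s$Cm * gsum(tpl$k_m, l)) / s$N
    A <- 1 - exp(-a)
    rho <- 0.02 + (0.46 + 0.05 * (s$N - 1.5)) * (1 - A)
    i <- which(wl == l)
    expect_equal(out$absorptance[i], A, tolerance = 1e-12)
    expect_equal(out$reflectance[i], rho, tolerance = 1e-12)
  }
  expect_true(all(out$reflectance >= 0 & out$reflectance <= 1))
})

test_that("zero constituents give zero absorptance and the scattering plateau", {
  wl <- seq(400, 2500, by = 10)
  out <- simulate_leaf(fixed_sample(Cab = 0, Cw = 0, Cm = 0, Cxc = 0), wl)
  expect_true(all(out$absorptance == 0))
  expect_true(all(abs(out$reflectance - (0.02 + 0.46)) < 1e-12))
  expect_error(simulate_leaf(fixed_sample(Cab = -1), wl), "negative")
})

test_that("absorption features respond monotonically to their constituents", {
  wl <- c(660, 1450)
  r1 <- simulate_canopy(fixed_sample(), wl)$reflectance
  r_cab <- simulate_canopy(fixed_sample(Cab = 60), wl)$reflectance
  r_cw <- simulate_canopy(fixed_sample(Cw = 0.030), wl)$reflectance
  expect_lt(r_cab[1], r1[1])  # more chlorophyll darkens the red
  expect_lt(r_cw[2], r1[2])   # more water deepens the 1450 nm feature
  a1 <- simulate_leaf(fixed_sample(), 1450)$absorptance
  a2 <- simulate_leaf(fixed_sample(Cw = 0.030), 1450)$absorptance
  expect_gt(a2, a1)
})

test_that("canopy mixing honors the gap-fraction limits", {
  wl <- seq(400, 2500, by = 50)
  bare <- simulate_canopy(fixed_sample(LAI = 0), wl)
  expect_equal(bare$P, 1, tolerance = 1e-15)
  closed <- simulate_canopy(fixed_sample(LAI = 50), wl)
  leaf <- simulate_leaf(fixed_sample(LAI = 50), wl)
  s <- fixed_sample()
  deg <- pi / 180
  g <- 1 + 0.05 * (cos(s$OZA * deg) - 1) +
    0.02 * cos(s$RAA * deg) * sin(s$SZA * deg) * sin(s$OZA * deg)
  expect_equal(closed$reflectance,
               pmin(g * leaf$reflectance * (1 + 0.8 * (1 - leaf$absorptance)), 1),
               tolerance = 1e-6)
  # P = exp(-k LAI): k_ext = 0.5 at LIDF = 0
  mid <- simulate_canopy(fixed_sample(LAI = 2), wl)
  expect_equal(mid$P, exp(-1), tolerance = 1e-12)
  expect_error(simulate_canopy(fixed_sample(LAI = -1), wl), "LAI")
})

test_that("derived targets follow the upscaling arithmetic", {
  wl <- seq(400, 2500, by = 10)
  s <- fixed_sample(LAI = 2, Cab = 45, Cw = 0.015, Cm = 0.0075)
  cn <- simulate_canopy(s, wl)
  tg <- derive_traits(s, cn$absorptance, cn$P, wl)
  expect_equal(tg$CCC, 0.9, tolerance = 1e-12)   # 2 * 45 * 1e-2
  expect_equal(tg$CWC, 300, tolerance = 1e-12)   # 2 * 0.015 * 1e4
  expect_equal(tg$SLA, 1 / 0.0075, tolerance = 1e-12)
  expect_equal(tg$FVC, 1 - exp(-1), tolerance = 1e-12)
  # no canopy, no interception
  s0 <- fixed_sample(LAI = 0)
  c0 <- simulate_canopy(s0, wl)
  t0 <- derive_traits(s0, c0$absorptance, c0$P, wl)
  expect_equal(t0$FVC, 0)
  expect_equal(t0$FAPAR, 0)
  expect_error(derive_traits(fixed_sample(Cm = 0), cn$absorptance, cn$P, wl),
               "SLA")
})

test_that("randomized trait derivations match direct arithmetic", {
  set.seed(99)
  wl <- seq(400, 2500, by = 20)
  for (i in 1:20) {
    s <- fixed_sample(LAI = runif(1, 0.1, 8), Cab = runif(1, 1, 80),
                      Cw = runif(1, 0.005, 0.035),
                      Cm = runif(1, 0.002, 0.02),
                      LIDF = runif(1, -1, 1))
    cn <- simulate_canopy(s, wl)
    tg <- derive_traits(s, cn$absorptance, cn$P, wl)
    k <- 0.5 * (1 + 0.3 * s$LIDF)
    expect_equal(tg$CCC, s$LAI * s$Cab * 1e-2, tolerance = 1e-12)
    expect_equal(tg$CWC, s$LAI * s$Cw * 1e4, tolerance = 1e-12)
    expect_equal(tg$SLA, 1 / s$Cm, tolerance = 1e-12)
    expect_equal(tg$FVC, 1 - exp(-k * s$LAI), tolerance = 1e-12)
    expect_true(tg$FAPAR >= 0 && tg$FAPAR <= tg$FVC)
  }
})

test_that("generated libraries satisfy their structural invariants", {
  lib <- small_library(n = 60, seed = 5)
  expect_s3_class(lib, "spectral_library")
  expect_equal(nrow(lib$reflectance), 60)
  expect_equal(nrow(lib$traits), 60)
  expect_false(is.unsorted(lib$wavelengths, strictly = TRUE))
  expect_true(all(lib$reflectance >= 0 & lib$reflectance <= 1))
  expect_true(all(lib$traits$FVC >= 0 & lib$traits$FVC <= 1))
  expect_true(all(lib$traits$FAPAR >= 0 & lib$traits$FAPAR <= 1))
  expect_true(all(lib$traits$FAPAR <= lib$traits$FVC + 1e-12))
  # determinism contract
  lib2 <- small_library(n = 60, seed = 5)
  expect_identical(lib$reflectance, lib2$reflectance)
  expect_identical(lib$traits, lib2$traits)
})

test_that("LAI and FVC are strongly positively linked across a large draw", {
  tr <- sample_inputs(default_trait_specs(), 5000, seed = 21)
  k <- 0.5 * (1 + 0.3 * tr$LIDF)
  fvc <- 1 - exp(-k * tr$LAI)
  expect_gt(cor(tr$LAI, fvc), 0.5)
})

test_that("non-vegetated augmentation spectra carry zero targets", {
  nv <- generate_nonvegetated(26, grid = coarse_grid(), seed = 9,
                              fine_step = 5)
  expect_equal(nrow(nv$reflectance), 26)
  for (v in c("SLA", "LAI", "CCC", "CWC", "FAPAR", "FVC")) {
    expect_true(all(nv$traits[[v]] == 0), info = v)
  }
  # water darkens into the SWIR by construction
  wlf <- seq(400, 2500, by = 5)
  w <- hytrait:::nonveg_template("water", wlf)
  expect_lt(mean(w[wlf >= 1500 & wlf <= 2300]), mean(w[wlf <= 700]))
  # zero jitter reproduces the stored archetype exactly
  nv0 <- generate_nonvegetated(5, seed = 1, jitter = 0, fine_step = 5,
                               proportions = c(soil_bright = 1))
  tmpl <- hytrait:::nonveg_template("soil_bright", seq(400, 2500, by = 5))
  expect_equal(unname(nv0$reflectance[1, ]), tmpl, tolerance = 1e-15)
})

test_that("synthetic cubes agree with the library path and are reproducible", {
  g <- coarse_grid()
  cube <- generate_synthetic_cube(6, 5, grid = g, seed = 3, fine_step = 5)
  expect_equal(dim(cube$cube), c(6, 5, length(g$centers)))
  expect_equal(dim(cube$truth$LAI), c(6, 5))
  # pixel spectrum identical to the library path on the same trait row
  i <- which(!as.vector(cube$nonveg))[1]
  lib <- simulate_from_traits(cube$traits[i, hytrait:::simulator_input_names()],
                              grid = g, fine_step = 5)
  rc <- matrix(cube$cube, 30, length(g$centers))[i, ]
  expect_equal(unname(rc), unname(lib$reflectance[1, ]), tolerance = 1e-12)
  # non-vegetated pixels have all-zero truth
  if (any(cube$nonveg)) {
    j <- which(cube$nonveg)[1]
    expect_equal(cube$truth$LAI[j], 0)
    expect_equal(cube$truth$FVC[j], 0)
  }
  # fixed seed -> identical cube array
  cube2 <- generate_synthetic_cube(6, 5, grid = g, seed = 3, fine_step = 5)
  expect_identical(cube$cube, cube2$cube)
})
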