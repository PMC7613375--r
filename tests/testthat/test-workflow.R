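# shared small-scale strategy setup: coarse grid keeps GPR fits quick
wf_setup <- function() {
  g <- coarse_grid()
  pool <- generate_library(n = 150, grid = g, seed = 301, fine_step = 5)
  list(g = g, pool = pool)
}

test_that("PCA-mode strategies train a 20-feature model end to end", {
  s <- wf_setup()
  cfg <- strategy_config("LAI", mode = "PCA", grid = s$g, seed = 5,
                         bypass_n = 80, n_nonveg = 10, fit_maxit = 40)
  bundle <- run_strategy(cfg, pool = s$pool)
  expect_s3_class(bundle, "trait_model")
  expect_equal(ncol(bundle$gpr$Z), 20)
  expect_equal(bundle$n_train, 90)  # 80 bypass + 10 non-vegetated
  expect_equal(bundle$transform$kind, "pca")
  expect_true(is.finite(bundle$stats$R2))
})

test_that("BR-mode strategies store 20 ranked wavelengths", {
  g <- band_grid(400, 2500, 100, 100)  # 22 bands keep the wrapper quick
  pool <- generate_library(n = 120, grid = g, seed = 303, fine_step = 5)
  # no exclusion here: the coarse grid must keep >= 20 candidate bands
  cfg <- strategy_config("LAI", mode = "BR", grid = g, seed = 7,
                         windows = exclusion_windows(
                           data.frame(min = numeric(0), max = numeric(0))),
                         bypass_n = 60, n_nonveg = 8, sbbr_rows = 50,
                         fit_maxit = 40)
  bundle <- run_strategy(cfg, pool = pool)
  expect_equal(bundle$transform$kind, "bands")
  expect_equal(length(bundle$transform$wavelengths), 20)
  expect_true(all(bundle$transform$wavelengths %in% bundle$kept_wavelengths))
  expect_equal(ncol(bundle$gpr$Z), 20)
})

test_that("ALL_BANDS mode keeps every surviving band", {
  s <- wf_setup()
  cfg <- strategy_config("FVC", mode = "ALL_BANDS", grid = s$g, seed = 9,
                         bypass_n = 60, n_nonveg = 5, fit_maxit = 30)
  bundle <- run_strategy(cfg, pool = s$pool)
  expect_equal(ncol(bundle$gpr$Z), length(bundle$kept_wavelengths))
})

test_that("trait maps agree with batch library prediction", {
  s <- wf_setup()
  cfg <- strategy_config("FVC", mode = "PCA", grid = s$g, seed = 11,
                         bypass_n = 80, n_nonveg = 10, fit_maxit = 40)
  bundle <- run_strategy(cfg, pool = s$pool)
  cube <- generate_synthetic_cube(5, 4, grid = s$g, seed = 13, fine_step = 5)
  cube_red <- apply_exclusion_windows(cube, default_exclusion_windows())
  tm <- map_traits(bundle, cube_red)
  expect_equal(dim(tm$estimate), c(5, 4))
  expect_true(all(tm$sd[tm$mask] >= 0))
  # per-pixel outputs identical to batch prediction on the flattened cube
  X <- matrix(cube_red$cube, 20, length(cube_red$wavelengths))
  F <- hytrait:::apply_feature_transform(bundle$transform, X)
  pr <- gpr_predict(bundle$gpr, F)
  expect_equal(as.vector(tm$estimate), pr$mean, tolerance = 1e-12)
  # full-grid cubes are aligned via the recorded kept index
  tm2 <- map_traits(bundle, cube)
  expect_equal(tm2$estimate, tm$estimate, tolerance = 1e-12)
  # unalignable grids are hard errors
  bad <- generate_synthetic_cube(2, 2, grid = band_grid(400, 900, 100, 100),
                                 seed = 1, fine_step = 5)
  expect_error(map_traits(bundle, bad), "aligned")
})

test_that("a noiseless model interpolates a training pixel on the map", {
  g <- coarse_grid()
  lib <- generate_library(n = 30, grid = g, seed = 307, fine_step = 5)
  model <- gpr_fit(lib$reflectance, lib$traits$LAI,
                   init = gpr_hyperparams(var(lib$traits$LAI), 1,
                                          rep(3, ncol(lib$reflectance)), 0),
                   optimize = FALSE)
  bundle <- structure(
    list(variable = "LAI", mode = "ALL_BANDS", grid_id = g$id, grid = g,
         windows = NULL, kept_wavelengths = lib$wavelengths,
         kept_index = seq_along(lib$wavelengths),
         transform = list(kind = "identity"), gpr = model,
         stats = NULL, n_train = 30, seed = 1),
    class = "trait_model")
  cube <- array(lib$reflectance[1, ], c(1, 1, length(lib$wavelengths)))
  tm <- map_traits(bundle, cube, wavelengths = lib$wavelengths)
  expect_equal(tm$estimate[1, 1], lib$traits$LAI[1], tolerance = 1e-6)
})

test_that("model bundles survive a JSON round trip", {
  s <- wf_setup()
  for (mode in c("PCA", "ALL_BANDS")) {
    cfg <- strategy_config("CCC", mode = mode, grid = s$g, seed = 17,
                           bypass_n = 50, n_nonveg = 5, fit_maxit = 30)
    bundle <- run_strategy(cfg, pool = s$pool)
    path <- file.path(tempdir(), paste0("model_", mode, ".json"))
    save_trait_model(bundle, path)
    back <- load_trait_model(path)
    cube <- generate_synthetic_cube(3, 3, grid = s$g, seed = 19,
                                    fine_step = 5)
    cube <- apply_exclusion_windows(cube, default_exclusion_windows())
    t1 <- map_traits(bundle, cube)
    t2 <- map_traits(back, cube)
    expect_equal(t2$estimate, t1$estimate, tolerance = 1e-8)
    expect_equal(t2$sd, t1$sd, tolerance = 1e-8)
    unlink(path)
  }
})

test_that("strategies are deterministic end to end under a fixed seed", {
  s <- wf_setup()
  cfg <- strategy_config("LAI", mode = "PCA", grid = s$g, seed = 23,
                         bypass_n = 40, n_nonveg = 5, fit_maxit = 25)
  b1 <- run_strategy(cfg, pool = s$pool)
  b2 <- run_strategy(cfg, pool = s$pool)
  expect_identical(b1$gpr$theta, b2$gpr$theta)
  cube <- generate_synthetic_cube(3, 3, grid = s$g, seed = 29, fine_step = 5)
  cube <- apply_exclusion_windows(cube, default_exclusion_windows())
  expect_identical(map_traits(b1, cube)$estimate,
                   map_traits(b2, cube)$estimate)
})

test_that("manifests record the invocation and seed", {
  path <- file.path(tempdir(), "manifest.json")
  write_manifest(path, invocation = "hytrait simulate --n 10 --seed 7",
                 seed = 7, extra = list(n = 10))
  m <- jsonlite::read_json(path)
  expect_equal(m$invocation, "hytrait simulate --n 10 --seed 7")
  expect_equal(m$seed, 7)
  expect_equal(m$package, "hytrait")
  unlink(path)
})
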