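# Synthetic-section generator: atlas geometry, Poisson count structure,
# survival gradient, probability maps, simulated observers.

test_that("toy atlas satisfies its construction contract", {
  atl <- build_toy_atlas(c(2000, 1500), 10)
  expect_s3_class(atl, "toy_atlas")
  expect_gte(length(atl$regions), 12)
  expect_equal(anyDuplicated(atl$region_info$region_id), 0L)
  # nuclei present
  expect_true(all(c("IML", "ICI", "IMM", "D", "LDCom") %in% names(atl$regions)))
  # every region polygon is simple and its centroid lies inside the outline
  for (id in names(atl$regions)) {
    poly <- atl$regions[[id]]
    expect_true(polygon_is_simple(poly))
    cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
    expect_true(points_in_polygon(cx, cy, atl$grey_outline))
  }
  # regions tile the outline: areas sum to at most the outline area
  expect_lte(sum(region_areas(atl)),
             polygon_area(atl$grey_outline) * (1 + 1e-9))
  # determinism: identical vertex lists on a second call
  atl2 <- build_toy_atlas(c(2000, 1500), 10)
  expect_identical(atl$regions, atl2$regions)
  expect_identical(atl$grey_outline, atl2$grey_outline)
})

test_that("invalid atlas parameters are rejected", {
  expect_error(build_toy_atlas(c(-10, 100), 5), "frame")
  expect_error(build_toy_atlas(c(100, 100), 2), "n_laminae")
  expect_error(build_toy_atlas(c(100, 100), 16), "n_laminae")
})

test_that("point-in-polygon agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  atl <- tiny_atlas()
  set.seed(42)
  px <- runif(500, 0, 800); py <- runif(500, 0, 600)
  mine <- points_in_polygon(px, py, atl$grey_outline)
  ref <- mgcv::in.out(atl$grey_outline, cbind(px, py))
  expect_equal(mine, as.logical(ref))
})

test_that("degenerate zero-density config yields an empty section", {
  atl <- tiny_atlas()
  cfg <- simulation_config(pixel_size_um = 4, densities = 0,
                           artifact_rate = 0, seed = 3)
  sec <- simulate_section(atl, cfg)
  expect_equal(nrow(sec$truth$neurons), 0L)
  expect_equal(nrow(sec$truth$artifacts), 0L)
  # image is background + noise only
  expect_lt(max(sec$image$neuronal), 0.2)
})

test_that("per-region truth counts recover the Poisson mean", {
  atl <- tiny_atlas()
  dens <- setNames(rep(0, nrow(atl$region_info)), atl$region_info$region_id)
  dens["L2"] <- 100
  cfg <- simulation_config(pixel_size_um = 8, densities = dens,
                           artifact_rate = 0, noise_sd = 0, psf_sigma_px = 0,
                           seed = 11)
  lambda <- 100 * region_areas(atl)[["L2"]] / 1e6
  counts <- vapply(1:200, function(i) {
    nrow(simulate_section(atl, cfg, seed = i)$truth$neurons)
  }, numeric(1))
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # variance is Poisson-like (generous factor-2 band)
  expect_gt(var(counts), lambda / 2)
  expect_lt(var(counts), lambda * 2)
})

test_that("simulation is deterministic and truth is contained and consistent", {
  atl <- tiny_atlas()
  cfg <- simulation_config(pixel_size_um = 4, seed = 5)
  a <- simulate_section(atl, cfg)
  b <- simulate_section(atl, cfg)
  expect_identical(a$image$neuronal, b$image$neuronal)
  expect_identical(a$image$nuclear, b$image$nuclear)
  expect_identical(a$truth$neurons, b$truth$neurons)
  # counts conservation: truth list length equals summed region counts
  expect_equal(nrow(a$truth$neurons), sum(truth_region_counts(a$truth, atl)))
  # containment: every neuron inside its region polygon and the outline
  tr <- a$truth$neurons
  for (id in unique(tr$region_id)) {
    sel <- tr$region_id == id
    expect_true(all(points_in_polygon(tr$x[sel], tr$y[sel],
                                      atl$regions[[id]])))
  }
  expect_true(all(points_in_polygon(tr$x, tr$y, atl$grey_outline)))
})

test_that("default survival curve matches the configured gradient anchors", {
  cfg <- simulation_config()
  expect_equal(survival_fraction(cfg, 1.0), 0.40)
  expect_equal(survival_fraction(cfg, 0.6), 0.023)
  expect_equal(survival_fraction(cfg, 0.8), 0.20)
  expect_equal(survival_fraction(cfg, 1.2), 0.40)
  expect_equal(survival_fraction(cfg, NULL), 1)
  # plateau beyond the last anchor, floor below the first
  expect_equal(survival_fraction(cfg, 1.5), 0.40)
  expect_equal(survival_fraction(cfg, 0.4), 0.023)
  # interpolation midway: ~20 percentage points per 200 um pace
  expect_equal(survival_fraction(cfg, 0.9), 0.30)
})

test_that("region survival factors preserve the density-weighted mean", {
  atl <- tiny_atlas()
  cfg <- simulation_config()
  s <- region_survival_fractions(atl, cfg, 0.8)
  dens <- default_densities(atl)
  w <- dens * region_areas(atl)
  expect_equal(sum(w * s) / sum(w), 0.20, tolerance = 1e-9)
  # dorsal laminae spared relative to intermediate grey
  expect_gt(s[["L1"]], s[["IML"]])
  expect_true(all(s >= 0 & s <= 1))
})

test_that("noiseless probability map is the exact truth indicator", {
  atl <- tiny_atlas()
  cfg <- noiseless_config(pixel_size_um = 2, seed = 21, artifact_rate = 5)
  sec <- simulate_section(atl, cfg)
  pm <- simulate_probability_map(sec$truth, sec$image, 0)
  expect_true(all(pm %in% c(0, 1)))
  # artifact pixels are 0 even though they are bright in the neuronal channel
  iso <- sec$truth$artifacts
  if (nrow(iso)) {
    ij <- cbind(pmin(nrow(pm), pmax(1, round(iso$y / 2 + 0.5))),
                pmin(ncol(pm), pmax(1, round(iso$x / 2 + 0.5))))
    expect_true(all(pm[ij] == 0))
  }
  # miscalibrated map stays in [0, 1] and stays ordered on average
  pm2 <- simulate_probability_map(sec$truth, sec$image, 0.2, seed = 4)
  expect_true(all(pm2 >= 0 & pm2 <= 1))
  expect_gt(mean(pm2[pm == 1]), mean(pm2[pm == 0]))
})

test_that("thresholding the noiseless map recovers sufficiently large somas", {
  atl <- tiny_atlas()
  # sparse so somas never touch; all somas >= 25 um^2 by construction
  dens <- setNames(rep(20, nrow(atl$region_info)), atl$region_info$region_id)
  cfg <- noiseless_config(pixel_size_um = 1, seed = 8, densities = dens,
                          artifact_rate = 0)
  sec <- simulate_section(atl, cfg)
  pm <- simulate_probability_map(sec$truth, sec$image, 0)
  det <- probmap_to_detections(pm, 1)
  expect_equal(nrow(det), nrow(sec$truth$neurons))
})

test_that("observer model reduces to truth for a perfect observer", {
  atl <- tiny_atlas()
  cfg <- noiseless_config(pixel_size_um = 4, seed = 13)
  sec <- simulate_section(atl, cfg)
  perfect <- simulate_observer(sec$truth, atl,
                               observer_profile(1, 0, 0, seed = 2))
  expect_equal(perfect$x, sec$truth$neurons$x)
  expect_equal(perfect$y, sec$truth$neurons$y)
  blind <- simulate_observer(sec$truth, atl,
                             observer_profile(0, 0, 0, seed = 2))
  expect_equal(nrow(blind), 0L)
})

test_that("observer profile validation rejects invalid rates", {
  expect_error(observer_profile(1.2), "sensitivity")
  expect_error(observer_profile(0.5, -1), ">= 0")
})
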