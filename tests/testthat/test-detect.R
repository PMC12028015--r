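# Threshold selection, connected components, segmentation rules, and the
# probability-map particle rule.

test_that("threshold selectors behave on separable and degenerate inputs", {
  img <- matrix(c(rep(0.1, 90), rep(0.9, 10)), 10, 10)
  t_otsu <- select_threshold(img, "otsu")
  expect_gt(t_otsu, 0.1); expect_lt(t_otsu, 0.9)
  expect_equal(select_threshold(img, "fixed", fixed_threshold = 50/255),
               50/255)
  t_iso <- select_threshold(img, "isodata")
  expect_gt(t_iso, 0.1); expect_lt(t_iso, 0.9)
  expect_equal(select_threshold(img, "mean"), mean(img))
  expect_warning(t_const <- select_threshold(matrix(0.5, 5, 5), "otsu"),
                 "constant")
  expect_equal(t_const, 0.5)
  expect_error(select_threshold(img, "fixed"), "fixed_threshold")
})

test_that("otsu equals exhaustive between-class-variance maximization", {
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(c(rnorm(300, 0.25, 0.05), rnorm(100, 0.7, 0.08)), 20, 20)
    img <- pmin(1, pmax(0, img))
    expect_lt(abs(select_threshold(img, "otsu") - brute_force_otsu(img)),
              2 / 256)
  }
})

test_that("auto threshold picks a contrast-maximizing separable cut", {
  img <- matrix(c(rep(0.1, 350), rep(0.85, 50)), 20, 20)
  t <- select_threshold(img, "auto")
  expect_gt(t, 0.1); expect_lt(t, 0.85)
})

test_that("component labeling is 8-connected and matches flood fill", {
  m <- matrix(0, 5, 5); m[2, 2] <- 1; m[3, 3] <- 1
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
  set.seed(7)
  for (rep in 1:5) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    mine <- label_components(mask, 8)
    oracle <- flood_fill_label(mask)
    expect_equal(max(mine), max(oracle))
    # identical partitions up to label naming: label maps are bijective
    tab <- table(mine, oracle)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("segmentation finds a single synthetic soma at its centroid", {
  # one disc of ~30 um^2 (r ~ 3.1 um) at 1 um/px with a colocalized nucleus
  img <- structure(list(
    neuronal = matrix(0.02, 60, 60), nuclear = matrix(0.02, 60, 60),
    pixel_size_um = 1, section_id = "one", condition = "control",
    distance_mm = NULL, gain = 1), class = "section_image")
  cx <- 30.5; cy <- 25.5; r <- 3.1
  for (i in 1:60) for (j in 1:60) {
    if (((j - 0.5) - cx)^2 + ((i - 0.5) - cy)^2 <= r^2) {
      img$neuronal[i, j] <- 0.9
      img$nuclear[i, j] <- 0.8
    }
  }
  res <- segment_neurons(img, detect_params(
    threshold_method = "fixed", fixed_threshold = 0.5,
    grey_mask = matrix(TRUE, 60, 60)))
  expect_equal(nrow(res$detections), 1L)
  expect_lt(abs(res$detections$x - cx), 1)
  expect_lt(abs(res$detections$y - cy), 1)
  expect_gt(res$detections$area_um2, 25)
  expect_equal(max(res$labels), 1L)
})

test_that("blank image yields no detections and missing mask is logged", {
  img <- structure(list(
    neuronal = matrix(0.02, 30, 30), nuclear = matrix(0.02, 30, 30),
    pixel_size_um = 2, section_id = "blank", condition = NULL,
    distance_mm = NULL, gain = 1), class = "section_image")
  expect_message(
    res <- segment_neurons(img, detect_params(threshold_method = "fixed",
                                              fixed_threshold = 0.5)),
    "mask")
  expect_equal(nrow(res$detections), 0L)
})

test_that("segmentation matches truth on sparse noiseless sections", {
  atl <- tiny_atlas()
  dens <- setNames(rep(25, nrow(atl$region_info)), atl$region_info$region_id)
  cfg <- noiseless_config(pixel_size_um = 1, seed = 17, densities = dens,
                          artifact_rate = 0)
  sec <- simulate_section(atl, cfg)
  res <- segment_neurons(sec$image, detect_params(
    threshold_method = "fixed", fixed_threshold = 0.3,
    grey_mask = atl$grey_outline))
  expect_equal(nrow(res$detections), nrow(sec$truth$neurons))
  # every detection centroid lies inside the grey mask
  expect_true(all(points_in_polygon(res$detections$x, res$detections$y,
                                    atl$grey_outline)))
})

test_that("nuclear colocalization removes artifact-only objects", {
  atl <- tiny_atlas()
  dens <- setNames(rep(15, nrow(atl$region_info)), atl$region_info$region_id)
  cfg <- noiseless_config(pixel_size_um = 1, seed = 23, densities = dens,
                          artifact_rate = 15)
  sec <- simulate_section(atl, cfg)
  p_on <- detect_params(threshold_method = "fixed", fixed_threshold = 0.3,
                        grey_mask = atl$grey_outline)
  p_off <- detect_params(threshold_method = "fixed", fixed_threshold = 0.3,
                         grey_mask = atl$grey_outline,
                         require_nuclear_colocalization = FALSE)
  on <- segment_neurons(sec$image, p_on)$detections
  off <- segment_neurons(sec$image, p_off)$detections
  expect_gte(nrow(off), nrow(on))
  # with colocalization every detection sits on (or touches) a true soma
  tr <- sec$truth$neurons
  d_on <- sqrt(outer(on$x, tr$x, "-")^2 + outer(on$y, tr$y, "-")^2)
  expect_true(all(apply(d_on, 1, min) <
                    max(tr$soma_radius_um) + max(sec$truth$artifacts$radius_um)))
  # artifacts isolated from every soma produce no colocalized detection
  ar <- sec$truth$artifacts
  d_iso <- sqrt(outer(ar$x, tr$x, "-")^2 + outer(ar$y, tr$y, "-")^2)
  iso <- apply(d_iso, 1, min) > (ar$radius_um + max(tr$soma_radius_um) + 3)
  if (any(iso)) {
    d_art <- sqrt(outer(on$x, ar$x[iso], "-")^2 + outer(on$y, ar$y[iso], "-")^2)
    expect_true(all(d_art > ar$radius_um[iso][col(d_art)]))
  }
  # colocalization requested without a nuclear channel is an input error
  img2 <- sec$image; img2$nuclear <- NULL
  expect_error(segment_neurons(img2, p_on), "nuclear")
})

test_that("raising the area threshold never increases detections", {
  atl <- tiny_atlas()
  cfg <- noiseless_config(pixel_size_um = 2, seed = 29)
  sec <- simulate_section(atl, cfg)
  counts <- vapply(c(5, 25, 50, 80), function(a) {
    nrow(segment_neurons(sec$image, detect_params(
      threshold_method = "fixed", fixed_threshold = 0.3,
      grey_mask = atl$grey_outline, min_area_um2 = a))$detections)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("particle rule on probability maps is strict at 25 um^2", {
  # empty map
  expect_equal(nrow(probmap_to_detections(matrix(0, 20, 20), 1)), 0L)
  # a 24-px component at 1 um/px and p = 0.9 is below the area cut
  pm <- matrix(0, 20, 20); pm[5:10, 5:8] <- 0.9   # 24 px = 24 um^2
  expect_equal(nrow(probmap_to_detections(pm, 1)), 0L)
  pm[5:10, 5:9] <- 0.9                            # 30 px > 25 um^2
  expect_equal(nrow(probmap_to_detections(pm, 1)), 1L)
  # exactly 25 um^2 is not "above 25 um^2"
  pm2 <- matrix(0, 20, 20); pm2[1:5, 1:5] <- 1
  expect_equal(nrow(probmap_to_detections(pm2, 1)), 0L)
  # p exactly at the cut is not "above 50%"
  pm3 <- matrix(0, 20, 20); pm3[1:6, 1:6] <- 0.5
  expect_equal(nrow(probmap_to_detections(pm3, 1)), 0L)
  expect_error(probmap_to_detections(matrix(2, 3, 3), 1), "\\[0, 1\\]")
})

test_that("particle counts equal the flood-fill oracle on random maps", {
  set.seed(41)
  for (rep in 1:8) {
    pm <- matrix(runif(2500), 50, 50)
    pm[pm < 0.45] <- 0
    mine <- nrow(probmap_to_detections(pm, 3, p_cut = 0.5,
                                       min_area_um2 = 25))
    oracle <- flood_fill_particle_count(pm, 3, 0.5, 25)
    expect_equal(mine, oracle)
  }
})

test_that("area bookkeeping: component areas sum to at most the mask area", {
  atl <- tiny_atlas()
  cfg <- noiseless_config(pixel_size_um = 2, seed = 37)
  sec <- simulate_section(atl, cfg)
  res <- segment_neurons(sec$image, detect_params(
    threshold_method = "fixed", fixed_threshold = 0.3,
    grey_mask = atl$grey_outline))
  mask_area <- sum(sec$image$neuronal > 0.3) * 4
  expect_lte(sum(res$detections$area_um2), mask_area)
})
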