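# Multi-analysis matching, agreement classes, the reference neuron number,
# and method-vs-manual overlap.

test_that("identical sets match object-for-object with full agreement", {
  a <- detection_set(c(10, 50, 90), c(10, 50, 90), source_id = "a")
  b <- detection_set(c(10, 50, 90), c(10, 50, 90), source_id = "b")
  tab <- match_detection_sets(list(a = a, b = b), 10)
  expect_equal(nrow(tab$objects), 3L)
  expect_true(all(tab$objects$k == 2))
  expect_equal(reference_number_of_neurons(tab), 3)
})

test_that("sets far beyond the radius never merge", {
  a <- detection_set(c(0, 100), c(0, 0), source_id = "a")
  b <- detection_set(c(50, 150), c(50, 50), source_id = "b")
  tab <- match_detection_sets(list(a = a, b = b), 10)
  expect_equal(nrow(tab$objects), 4L)
  expect_true(all(tab$objects$k == 1))
})

test_that("matching rejects a non-positive radius", {
  a <- detection_set(1, 1)
  expect_error(match_detection_sets(list(a), 0), "radius")
  expect_error(match_detection_sets_exhaustive(list(a), -1), "radius")
})

test_that("objects never take two points from one source and keep all points", {
  set.seed(19)
  for (rep in 1:10) {
    inst <- random_match_instance(rep + 400)
    tab <- match_detection_sets(inst$sets, inst$radius)
    # point conservation
    expect_equal(nrow(tab$members), sum(vapply(inst$sets, nrow, numeric(1))))
    # one point per source per object
    dup <- tapply(tab$members$source_id, tab$members$object_id,
                  function(s) anyDuplicated(s))
    expect_true(all(dup == 0))
    # all pairwise member distances within the radius
    for (o in unique(tab$members$object_id)) {
      mm <- tab$members[tab$members$object_id == o, ]
      if (nrow(mm) > 1) {
        expect_lte(max(dist(cbind(mm$x, mm$y))), inst$radius)
      }
    }
  }
})

test_that("greedy matching equals the exhaustive minimum-cost assignment", {
  ok <- 0L; n_inst <- 25L
  for (rep in seq_len(n_inst)) {
    inst <- random_match_instance(rep)
    g <- match_detection_sets(inst$sets, inst$radius)
    e <- match_detection_sets_exhaustive(inst$sets, inst$radius)
    expect_equal(nrow(g$members), nrow(e$members))
    if (abs(g$cost - e$cost) < 1e-9) ok <- ok + 1L
  }
  expect_equal(ok, n_inst)
})

test_that("histogram and RNN are invariant to the order of the sets", {
  inst <- random_match_instance(77)
  tab1 <- match_detection_sets(inst$sets, inst$radius)
  tab2 <- match_detection_sets(rev(inst$sets), inst$radius)
  expect_equal(agreement_histogram(tab1), agreement_histogram(tab2))
  expect_equal(reference_number_of_neurons(tab1),
               reference_number_of_neurons(tab2))
})

test_that("RNN equals the arithmetic mean of per-analyst counts", {
  for (rep in 1:10) {
    inst <- random_match_instance(rep + 100)
    tab <- match_detection_sets(inst$sets, inst$radius)
    expect_equal(reference_number_of_neurons(tab),
                 mean(vapply(inst$sets, nrow, numeric(1))),
                 tolerance = 1e-12)
  }
  # single analyst: RNN is that analyst's count
  one <- detection_set(runif(7, 0, 100), runif(7, 0, 100), source_id = "solo")
  tab1 <- match_detection_sets(list(solo = one), 10)
  expect_equal(reference_number_of_neurons(tab1), 7)
})

test_that("agreement histogram separates manual classes from class 0", {
  a <- detection_set(c(10, 50), c(10, 50), source_id = "a")
  b <- detection_set(c(10, 90), c(10, 90), source_id = "b")
  tab <- match_detection_sets(list(a = a, b = b), 10)
  h <- agreement_histogram(tab)
  expect_named(h, c("0", "1", "2"))
  expect_equal(unname(h), c(0, 2, 1))
  # an automated set contributes class 0 only where no manual point matches
  m <- detection_set(c(10, 200), c(10, 200), source_id = "macro")
  h2 <- agreement_histogram(tab, extra_sets = list(macro = m))
  expect_equal(unname(h2), c(1, 2, 1))
  # normalization: manual classes sum to 100
  h3 <- agreement_histogram(tab, extra_sets = list(macro = m),
                            normalize = TRUE)
  expect_equal(sum(h3[-1]), 100)
})

test_that("agreement classes follow the binomial law for iid observers", {
  # K = 5 observers at sensitivity 0.8 over a grid of well-separated
  # truth objects: observed classes 1..5 ~ truncated Binomial(5, 0.8)
  set.seed(55)
  gx <- rep(seq(20, 980, by = 45), times = 22)[1:484]
  gy <- rep(seq(20, 980, by = 45), each = 22)[1:484]
  sets <- lapply(1:5, function(k) {
    hit <- runif(484) < 0.8
    detection_set(gx[hit] + rnorm(sum(hit), 0, 1.5),
                  gy[hit] + rnorm(sum(hit), 0, 1.5),
                  source_id = paste0("obs", k))
  })
  tab <- match_detection_sets(sets, 10)
  h <- agreement_histogram(tab)[-1]
  pk <- dbinom(1:5, 5, 0.8); pk <- pk / sum(pk)
  expected <- sum(h) * pk
  chisq <- sum((h - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.99, df = 4))
})

test_that("method overlap statistics match their defining cases", {
  a <- detection_set(c(10, 50, 90), c(10, 50, 90), source_id = "a")
  b <- detection_set(c(10, 50), c(10, 50), source_id = "b")
  tab <- match_detection_sets(list(a = a, b = b), 10)
  # method identical to analyst a: every object matched, no extras
  st <- method_overlap_stats(a, tab)
  expect_equal(st$extra_percent, 0)
  expect_equal(st$n_extra, 0L)
  expect_equal(unname(st$class_fraction), c(1, 1))
  # empty method set
  st0 <- method_overlap_stats(detection_set(numeric(0), numeric(0)), tab)
  expect_equal(st0$extra_percent, 0)
  expect_true(all(st0$class_fraction == 0))
  # method with one unmatched point: extra% relative to manual objects
  m <- detection_set(c(10, 300), c(10, 300), source_id = "m")
  st1 <- method_overlap_stats(m, tab)
  expect_equal(st1$n_extra, 1L)
  expect_equal(st1$extra_percent, 100 * 1 / 3)
})

test_that("a truth-based method detects high-agreement classes more often", {
  atl <- tiny_atlas()
  cfg <- noiseless_config(pixel_size_um = 4, seed = 61)
  sec <- simulate_section(atl, cfg)
  obs <- lapply(1:5, function(i) {
    simulate_observer(sec$truth, atl,
                      observer_profile(0.75, 0.5, 2, seed = 300 + i),
                      paste0("obs", i))
  })
  tab <- match_detection_sets(obs, 10)
  truth_set <- detection_set(sec$truth$neurons$x, sec$truth$neurons$y,
                             source_id = "truth")
  st <- method_overlap_stats(truth_set, tab)
  cf <- st$class_fraction[!is.na(st$class_fraction)]
  # non-decreasing detection fraction with agreement class
  expect_true(all(diff(cf) >= -1e-9))
})

test_that("agreement CSV round-trips the per-source flags", {
  a <- detection_set(c(10, 50), c(10, 50), source_id = "a")
  b <- detection_set(c(10, 90), c(10, 90), source_id = "b")
  tab <- match_detection_sets(list(a = a, b = b), 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_agreement_csv(tab, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$k, back$a + back$b)
})
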