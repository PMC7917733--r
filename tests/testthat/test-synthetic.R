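test_that("gait_params validates its invariants", {
  expect_error(gait_params("standing", mean_angle = 100, amplitude = 110),
               class = "gait_bad_param")
  expect_error(gait_params("standing", frequency = 0), class = "gait_bad_param")
  expect_error(gait_params("standing", invalid_prob = 0.5), class = "gait_bad_param")
  expect_error(gait_params("trot"), class = "gait_bad_label")
  p <- gait_params("galloping")
  expect_equal(p$mean_angle + p$amplitude, 180)  # printed galloping ceiling
  expect_equal(gait_params("standing")$mean_angle - gait_params("standing")$amplitude, 140)
})

test_that("noiseless simulation inverts to the programmed sinusoid", {
  p <- gait_params("ambling", jitter_sd = 0, invalid_prob = 0)
  cb <- simulate_clip(p, n_frames = 120L, fps = 30, seed = 4, phase0 = 0.3,
                      render_masks = FALSE)
  s <- angle_series(cb$pose)
  tt <- (0:119) / 30
  expect_equal(s$hind, 140 + 40 * sin(2 * pi * 1.0 * tt + 0.3), tolerance = 1e-8)
  expect_equal(s$front, 140 + 40 * sin(2 * pi * 1.0 * tt + 0.3 + pi), tolerance = 1e-8)
  expect_lt(max(abs(s$hind - (140 + 40 * sin(2 * pi * tt + 0.3)))), 1e-6)
})

test_that("standing stays in [140, 160] and hits the extremes noiselessly", {
  p <- gait_params("standing", jitter_sd = 0, invalid_prob = 0)
  cb <- simulate_clip(p, n_frames = 61L, seed = 1, phase0 = pi / 2,
                      render_masks = FALSE)
  s <- angle_series(cb$pose)
  expect_equal(min(s$hind), 140, tolerance = 1e-6)
  expect_equal(max(s$hind), 160, tolerance = 1e-6)
  expect_true(all(s$hind >= 140 - 1e-9 & s$hind <= 160 + 1e-9))
})

test_that("zero amplitude gives a constant series at the mean angle", {
  p <- gait_params("standing", amplitude = 0, jitter_sd = 0, invalid_prob = 0)
  cb <- simulate_clip(p, n_frames = 20L, seed = 2, render_masks = FALSE)
  s <- angle_series(cb$pose)
  expect_equal(s$hind, rep(150, 20), tolerance = 1e-9)
  expect_equal(s$front, rep(150, 20), tolerance = 1e-9)
})

test_that("simulation is bit-reproducible from (params, seed)", {
  p <- gait_params("galloping")
  a <- simulate_clip(p, n_frames = 40L, seed = 99)
  b <- simulate_clip(p, n_frames = 40L, seed = 99)
  expect_identical(a, b)
  c_ <- simulate_clip(p, n_frames = 40L, seed = 100)
  expect_false(identical(a$pose$coords, c_$pose$coords))
})

test_that("perpendicular view collapses all knee angles to 180", {
  for (lbl in action_levels()) {
    p <- gait_params(lbl, jitter_sd = 0, invalid_prob = 0)
    cb <- simulate_clip(p, n_frames = 10L, seed = 3, view = "perpendicular",
                        render_masks = FALSE)
    s <- angle_series(cb$pose)
    expect_equal(c(s$front, s$hind), rep(180, 20), tolerance = 1e-6)
    expect_true(all(c(s$front, s$hind) <= 180))
  }
})

test_that("amplitude ordering survives the full pipeline at default params", {
  for (seed in c(0, 7, 21)) {
    ptp <- vapply(default_gait_params(), function(p) {
      s <- angle_series(simulate_clip(p, n_frames = 150L, seed = seed,
                                      render_masks = FALSE)$pose)
      diff(range(s$hind))
    }, 0)
    expect_gt(ptp[["galloping"]], ptp[["ambling"]])
    expect_gt(ptp[["ambling"]], ptp[["standing"]])
  }
})

test_that("invalid_prob drops landmarks and the RNG state is restored", {
  before <- stats::runif(1)
  set.seed(123); before_draw <- stats::runif(1)
  set.seed(123)
  p <- gait_params("ambling", invalid_prob = 0.3)
  cb <- simulate_clip(p, n_frames = 200L, seed = 5, render_masks = FALSE)
  expect_gt(sum(!cb$pose$visible), 0)
  expect_identical(stats::runif(1), before_draw)  # global RNG untouched
})

test_that("render_silhouette draws capsules and flags empty poses", {
  coords <- matrix(c(5, 16, rep(NA, 34)), 18L, 2L, byrow = TRUE)
  coords[1, ] <- c(4, 16); coords[2, ] <- c(28, 16)
  vis <- c(TRUE, TRUE, rep(FALSE, 16))
  m <- render_silhouette(coords, vis, limb_width = 3, canvas = c(32L, 32L),
                         autoscale = FALSE)
  expect_true(all(m %in% c(0L, 1L)))
  expect_gt(sum(m), 0)
  heights <- colSums(m[, 10:20])
  expect_true(all(heights >= 3 & heights <= 4))  # ~3 px thick bar
  expect_error(render_silhouette(coords, c(TRUE, rep(FALSE, 17))),
               class = "gait_empty_pose")
})

test_that("outline of a rendered pose encloses every skeleton landmark", {
  for (lbl in action_levels()) {
    cb <- simulate_clip(gait_params(lbl), n_frames = 12L, seed = 8)
    f <- 6L
    poly <- extract_outline(cb$masks[[f]])
    vis <- cb$pose$visible[f, ]
    inside <- gaitstream:::point_in_polygon(cb$pose$coords[f, vis, 1],
                                            cb$pose$coords[f, vis, 2], poly)
    expect_true(all(inside))
  }
})

test_that("make_gait_dataset builds balanced disjoint splits deterministically", {
  ds <- make_gait_dataset(10L, split = 0.5, seed = 1, render_masks = FALSE)
  expect_length(ds$train, 15L)
  expect_length(ds$test, 15L)
  for (part in ds) {
    tab <- table(vapply(part, function(b) b$label, ""))
    expect_true(max(tab) - min(tab) <= 1L)
  }
  ids <- vapply(c(ds$train, ds$test), function(b) b$pose$clip_id, "")
  expect_false(anyDuplicated(ids) > 0)
  ds2 <- make_gait_dataset(10L, split = 0.5, seed = 1, render_masks = FALSE)
  expect_identical(
    lapply(ds$train, function(b) c(b$pose$clip_id, b$label, b$seed)),
    lapply(ds2$train, function(b) c(b$pose$clip_id, b$label, b$seed)))
  nf <- vapply(c(ds$train, ds$test), function(b) dim(b$pose$coords)[1], 0L)
  expect_true(all(nf >= 60L & nf <= 240L))
})
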