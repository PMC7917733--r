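test_that("bending_angle matches closed-form examples", {
  expect_equal(bending_angle(c(0, 0), c(1, 0), c(2, 0)), 180)
  expect_equal(bending_angle(c(0, 0), c(1, 0), c(1, 1)), 90)
  # frozen from the independent atan2 oracle: interior angle of
  # hip (0,0), knee (2,0), ankle (3, sqrt(3)) is 120 degrees
  expect_equal(oracle_angle(c(0, 0), c(2, 0), c(3, sqrt(3))), 120)
  expect_equal(bending_angle(c(0, 0), c(2, 0), c(3, sqrt(3))), 120)
})

test_that("bending_angle agrees with the vector-angle oracle on random triples", {
  set.seed(7)
  err <- vapply(1:1000, function(i) {
    p <- random_triple()
    abs(bending_angle(p[1, ], p[2, ], p[3, ]) -
          oracle_angle(p[1, ], p[2, ], p[3, ]))
  }, 0)
  expect_lt(max(err), 1e-9)  # degrees, absolute
})

test_that("bending_angle is invariant under rigid motion and uniform scale", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_triple()
    ref <- bending_angle(p[1, ], p[2, ], p[3, ])
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    s <- exp(runif(1, -3, 3))
    shift <- runif(2, -50, 50)
    q <- s * p %*% t(R) + matrix(shift, 3L, 2L, byrow = TRUE)
    expect_equal(bending_angle(q[1, ], q[2, ], q[3, ]), ref, tolerance = 1e-9)
  }
})

test_that("bending_angle is symmetric in hip and ankle, bounded in (0, 180]", {
  set.seed(13)
  for (i in 1:200) {
    p <- random_triple()
    a1 <- bending_angle(p[1, ], p[2, ], p[3, ])
    expect_identical(a1, bending_angle(p[3, ], p[2, ], p[1, ]))
    expect_gt(a1, 0)
    expect_lte(a1, 180)
  }
  # adversarial near-collinear: cosine argument would exceed 1 without clamp
  for (eps in 10^-(6:15)) {
    a <- bending_angle(c(0, 0), c(1, eps), c(2, 0))
    expect_true(a > 0 && a <= 180)
  }
})

test_that("bending_angle rejects degenerate and non-finite geometry", {
  expect_error(bending_angle(c(0, 0), c(0, 0), c(1, 0)),
               class = "gait_degenerate_geometry")
  expect_error(bending_angle(c(0, 0), c(1, 0), c(1, 1e-10)),
               class = "gait_degenerate_geometry")
  expect_error(bending_angle(c(NA, 0), c(1, 0), c(2, 0)),
               class = "gait_degenerate_geometry")
})

test_that("angle_series handles a constant collinear clip", {
  s <- angle_series(constant_pose_seq(10L))
  expect_equal(s$front, rep(180, 10))
  expect_equal(s$hind, rep(180, 10))
  expect_true(all(s$valid))
})

test_that("angle_series interpolates invalid interior frames linearly", {
  # knee y-offsets chosen so frames 4 and 6 give 100 and 120 degrees
  n <- 10L
  seq0 <- constant_pose_seq(n, hip = c(0, 0), knee = c(1, 0), ankle = c(2, 0))
  off <- function(theta) tan((180 - theta) / 2 * pi / 180)  # isoceles construction
  for (f in seq_len(n)) {
    theta <- c(150, 150, 150, 100, 150, 120, 150, 150, 150, 150)[f]
    # hip (0,0), knee (1, h), ankle (2, 0): interior angle at the knee
    h <- off(theta)
    for (tri in list(c(10L, 11L, 12L), c(14L, 15L, 16L))) {
      seq0$coords[f, tri[2], 2] <- h
    }
  }
  expect_equal(angle_series(seq0)$front[4], 100, tolerance = 1e-9)
  seq0$visible[5, 11L] <- FALSE  # front knee lost in frame 5
  s <- angle_series(seq0)
  expect_false(s$valid[5])
  expect_equal(s$front[5], (100 + 120) / 2, tolerance = 1e-9)
  expect_equal(s$hind[5], 150, tolerance = 1e-9)  # hind leg untouched by the drop
})

test_that("angle_series copies nearest valid value at the ends", {
  seq0 <- constant_pose_seq(6L)
  seq0$visible[1, 11L] <- FALSE
  seq0$visible[6, 15L] <- FALSE
  s <- angle_series(seq0)
  expect_equal(s$front[1], 180)
  expect_equal(s$hind[6], 180)
  expect_false(s$valid[1]); expect_false(s$valid[6])
})

test_that("angle_series matches per-frame oracle on an oscillating clip", {
  n <- 20L
  seq0 <- constant_pose_seq(n)
  theta <- 150 + 10 * sin(2 * pi * seq_len(n) / n)
  for (f in seq_len(n)) {
    h <- tan((180 - theta[f]) / 2 * pi / 180)
    seq0$coords[f, 15L, 2] <- h  # hind knee
  }
  s <- angle_series(seq0)
  direct <- vapply(seq_len(n), function(f) {
    oracle_angle(seq0$coords[f, 14L, ], seq0$coords[f, 15L, ], seq0$coords[f, 16L, ])
  }, 0)
  expect_equal(s$hind, direct, tolerance = 1e-9)
  expect_equal(s$hind, theta, tolerance = 1e-9)
  expect_equal(range(s$hind), range(theta), tolerance = 0.5)
})

test_that("angle_series rejects clips with too many invalid frames", {
  seq0 <- constant_pose_seq(10L)
  seq0$visible[1:4, 11L] <- FALSE  # 40% invalid on the front leg
  expect_error(angle_series(seq0), class = "gait_clip_unusable")
})

test_that("domain type validation catches malformed inputs", {
  expect_error(pose_sequence("x", array(0, c(5, 17, 2))),
               class = "gait_schema_mismatch")
  expect_error(pose_sequence("x", array(0, c(1, 18, 2))),
               class = "gait_too_short")
  expect_error(pose_sequence("x", array(0, c(5, 18, 2)), fps = 0),
               class = "gait_bad_param")
  expect_error(skeleton_schema(front_triple = c(1, 2, 3), hind_triple = c(3, 4, 5)),
               class = "gait_schema_mismatch")
  expect_error(skeleton_schema(landmark_names = letters),
               class = "gait_schema_mismatch")
  expect_error(action_factor("trotting"), class = "gait_bad_label")
  expect_identical(as.integer(action_factor(c("standing", "ambling", "galloping"))),
                   1:3)
})
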