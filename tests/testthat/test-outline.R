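test_that("extract_outline traces a filled square with matching area", {
  m <- matrix(0L, 10L, 10L)
  m[4:7, 3:6] <- 1L
  poly <- extract_outline(m)
  # marching squares cuts the four corners: area = 16 - 0.5
  expect_lt(abs(abs(gaitstream:::shoelace_area(poly)) - 16), 1)
  expect_false(any(duplicated(poly)))  # closed, no repeated vertex
})

test_that("extract_outline handles degenerate and multi-component masks", {
  single <- matrix(0L, 5L, 5L)
  single[3, 3] <- 1L
  poly <- extract_outline(single)
  expect_true(nrow(poly) >= 3L)
  expect_true(all(abs(poly[, 1] - 3) <= 1 & abs(poly[, 2] - 3) <= 1))

  two <- matrix(0L, 12L, 12L)
  two[2:6, 2:5] <- 1L      # 20 px component
  two[9:10, 8:10] <- 1L    # 6 px component (well separated)
  poly <- extract_outline(two)
  expect_true(all(poly[, 1] <= 7))  # traces only the large component
  expect_true(all(poly[, 2] <= 8))

  expect_error(extract_outline(matrix(0L, 4L, 4L)), class = "gait_empty_mask")
})

test_that("rasterize_outline produces a hollow normalized 112x112 ring", {
  sq <- cbind(x = c(10, 40, 40, 10), y = c(10, 10, 40, 40))
  img <- rasterize_outline(sq, canvas = c(50L, 50L))
  expect_identical(dim(img), c(112L, 112L))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(max(img), 1)
  # hollow: the centre of the square is empty
  expect_equal(sum(img[50:60, 50:60]), 0)
  filled <- rasterize_outline(sq, canvas = c(50L, 50L), fill = TRUE)
  expect_gt(sum(filled[50:60, 50:60]), 0)
})

test_that("softmax matches its closed form and is shift invariant", {
  expect_equal(unname(softmax_scores(c(0, 0, 0))), rep(1 / 3, 3))
  expect_equal(unname(softmax_scores(c(1, 2, 3))),
               c(0.09003057, 0.24472847, 0.66524096), tolerance = 1e-7)
  z <- c(0.3, -1.2, 2.2)
  expect_equal(softmax_scores(z), softmax_scores(z + 500))
  expect_equal(softmax_scores(z), softmax_scores(z - 900))
  expect_error(softmax_scores(c(1, Inf, 0)), class = "gait_bad_param")
  expect_equal(sum(softmax_scores(rnorm(3))), 1)
})

test_that("feature-map shapes follow the three conv/pool blocks", {
  sh <- tiny_vgg_shapes(tiny_vgg_config())
  pools <- sh[grepl("maxpool", sh$layer), ]
  expect_equal(pools$out_h, c(56L, 28L, 14L))
  expect_equal(pools$out_w, c(56L, 28L, 14L))
  final_conv <- sh[sh$layer == "maxpool3_2x2", ]
  expect_equal(unlist(final_conv[c("out_h", "out_w", "channels")], use.names = FALSE),
               c(14L, 14L, 256L))
  expect_equal(sh$channels[sh$layer == "conv1_3x3"], 64L)
})

test_that("the tiny network is far smaller than VGG16 at the same input", {
  tiny <- tiny_vgg_param_count(tiny_vgg_config())
  # independent recount: conv 640 + 73856 + 295168, fc 50176*256+256, 256*3+3
  expect_equal(tiny, 640 + 73856 + 295168 + (50176 * 256 + 256) + (256 * 3 + 3))
  expect_lt(tiny, vgg16_param_count(112L))
  expect_lt(tiny, 138357544)  # canonical VGG16 at 224 as a second anchor
})

test_that("compiled convolution agrees with a naive R oracle", {
  set.seed(5)
  H <- 6L; W <- 5L; C <- 3L; K <- 4L; B <- 2L
  x <- matrix(rnorm(C * H * W * B), C)
  Wm <- matrix(rnorm(K * 9L * C), K)
  b <- rnorm(K)
  got <- gaitstream:::cpp_conv3_fwd(x, Wm, b, H, W, C, B)
  expect_equal(got, naive_conv3(x, Wm, b, H, W, C, B), tolerance = 1e-12)
  # backward consistency via finite differences on one weight and one input
  dy <- matrix(rnorm(K * H * W * B), K)
  g <- gaitstream:::cpp_conv3_bwd(x, dy, Wm, H, W, C, B, TRUE)
  eps <- 1e-6
  x2 <- x; x2[17] <- x2[17] + eps
  expect_equal(sum((gaitstream:::cpp_conv3_fwd(x2, Wm, b, H, W, C, B) - got) * dy) / eps,
               g$dx[17], tolerance = 1e-4)
  W2 <- Wm; W2[23] <- W2[23] + eps
  expect_equal(sum((gaitstream:::cpp_conv3_fwd(x, W2, b, H, W, C, B) - got) * dy) / eps,
               g$dW[23], tolerance = 1e-4)
})

test_that("max pooling picks the first maximum and scatters gradients back", {
  x <- matrix(c(1, 3, 3, 2,
                5, 5, 0, 0), 1L, 8L, byrow = TRUE)  # one channel, 4x2, B=1
  pl <- gaitstream:::cpp_maxpool2_fwd(x, 4L, 2L, 1L)
  # block (rows 1:2 x cols 1:2) holds {1,3,5,5} -> 5; block (rows 3:4) -> 3
  expect_equal(as.vector(pl$y), c(5, 3))
  dx <- gaitstream:::cpp_maxpool2_bwd(matrix(c(1, 1), 1L), pl$amax, 4L, 2L, 1L)
  expect_equal(which(dx != 0), c(3L, 5L))  # col 5 = first of the tied 5s
})

test_that("fit_tiny_vgg separates a toy two-class problem and seeds deterministically", {
  toy <- toy_rasters(n_per_class = 6L, size = 32L)
  cfg <- tiny_vgg_config(input_size = 32L, n_classes = 2L)
  m <- fit_tiny_vgg(toy$images, factor(toy$labels, levels = c("standing", "ambling")),
                    cfg, epochs = 30L, lr = 0.01, seed = 0L)
  expect_equal(utils::tail(m$log$accuracy, 1), 1.0)
  expect_lte(utils::tail(m$log$loss, 1), m$log$loss[1])
  p <- predict(m, toy$images)
  expect_equal(rowSums(p), rep(1, length(toy$images)), tolerance = 1e-9)
  m2 <- fit_tiny_vgg(toy$images, factor(toy$labels, levels = c("standing", "ambling")),
                     cfg, epochs = 30L, lr = 0.01, seed = 0L)
  expect_identical(m$params, m2$params)
  expect_error(fit_tiny_vgg(toy$images, factor(rep("standing", 12),
                                               levels = c("standing", "ambling")),
                            cfg, epochs = 1L),
               class = "gait_class_missing")
})

test_that("predict_outline_clip averages per-frame scores", {
  toy <- toy_rasters(n_per_class = 2L, size = 32L)
  cfg <- tiny_vgg_config(input_size = 32L, n_classes = 2L)
  m <- fit_tiny_vgg(toy$images, factor(toy$labels, levels = c("standing", "ambling")),
                    cfg, epochs = 2L, seed = 1L)
  single <- predict(m, toy$images[1])
  expect_equal(predict_outline_clip(m, toy$images[1]), single[1, ])
  pair <- predict_outline_clip(m, toy$images[1:2])
  expect_equal(pair, colMeans(predict(m, toy$images[1:2])))
  expect_equal(sum(pair), 1, tolerance = 1e-9)
  expect_error(predict_outline_clip(m, list()), class = "gait_empty_clip")
})
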