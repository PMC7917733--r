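test_that("fuse_scores matches the weighted-average closed form", {
  yp <- c(0.8, 0.1, 0.1); ys <- c(0.6, 0.3, 0.1)
  expect_equal(fuse_scores(yp, ys, 0.5), c(0.7, 0.2, 0.1))
  expect_equal(fuse_scores(yp, ys, 1 - 1e-12), yp, tolerance = 1e-10)
  expect_equal(fuse_scores(yp, ys, 1e-12), ys, tolerance = 1e-10)
  for (w in c(0.2, 0.5, 0.8)) expect_equal(fuse_scores(yp, yp, w), yp)
  expect_error(fuse_scores(yp, ys, 0), class = "gait_weight_range")
  expect_error(fuse_scores(yp, ys, 1), class = "gait_weight_range")
  expect_error(fuse_scores(c(0.5, 0.5, 0.5), ys, 0.5), class = "gait_bad_score")
})

test_that("fusion is a convex combination on random score pairs", {
  set.seed(3)
  yp <- random_scores(1000L); ys <- random_scores(1000L)
  w <- 0.37
  y <- fuse_scores(yp, ys, w)
  expect_equal(rowSums(y), rep(1, 1000L), tolerance = 1e-9)
  expect_true(all(y >= pmin(yp, ys) - 1e-12))
  expect_true(all(y <= pmax(yp, ys) + 1e-12))
})

test_that("select_fusion_weight maximizes validation accuracy with 0.5 tie-break", {
  set.seed(4)
  labels <- rep(action_levels(), each = 20L)
  perfect <- matrix(0.05, 60L, 3L)
  perfect[cbind(seq_len(60L), as.integer(action_factor(labels)))] <- 0.9
  noise <- random_scores(60L)
  # exhaustive grid-evaluation oracle replicated in-test: accuracy per
  # weight, maximum taken with the documented tie-break toward 0.5
  oracle_select <- function(yp, ys, grid = seq(0.1, 0.9, by = 0.1)) {
    acc <- vapply(grid, function(w) {
      fused <- w * yp + (1 - w) * ys
      pred <- apply(fused, 1L, which.max)
      cm <- table(factor(labels, levels = action_levels()),
                  factor(action_levels()[pred], levels = action_levels()))
      mean(diag(cm) / rowSums(cm))
    }, 0)
    cand <- which(acc > max(acc) - 1e-12)
    grid[cand[order(abs(grid[cand] - 0.5), grid[cand])][1]]
  }
  # outline perfect, skeleton random -> a weight favouring the outline stream
  w1 <- select_fusion_weight(perfect, noise, labels)
  expect_identical(w1, oracle_select(perfect, noise))
  expect_gte(w1, 0.5)
  # skeleton perfect, outline random -> leans the other way
  w2 <- select_fusion_weight(noise, perfect, labels)
  expect_identical(w2, oracle_select(noise, perfect))
  expect_lte(w2, 0.5)
  # identical streams -> tie broken to 0.5
  expect_equal(select_fusion_weight(perfect, perfect, labels), 0.5)
  expect_equal(select_fusion_weight(noise, noise, labels, grid = c(0.25)), 0.25)
  expect_error(select_fusion_weight(perfect, noise, labels, grid = numeric()),
               class = "gait_empty_grid")
  expect_error(select_fusion_weight(perfect, noise, labels, grid = c(0, 0.5)),
               class = "gait_weight_range")
})

test_that("evaluate_predictions counts the confusion matrix correctly", {
  labels <- c(rep("standing", 4), "ambling")
  scores <- rbind(c(.8, .1, .1), c(.7, .2, .1), c(.6, .3, .1),
                  c(.2, .7, .1),   # standing clip called ambling
                  c(.1, .8, .1))
  r <- evaluate_predictions(scores, labels)
  expect_equal(r$per_class_accuracy[["standing"]], 0.75)
  expect_equal(r$confusion[["standing", "ambling"]], 1)
  expect_equal(unname(rowSums(r$confusion)), c(4, 1, 0))
  expect_equal(r$n_clips, 5L)

  all_right <- matrix(0.1, 6L, 3L)
  lab6 <- rep(action_levels(), 2L)
  all_right[cbind(1:6, as.integer(action_factor(lab6)))] <- 0.8
  r2 <- evaluate_predictions(all_right, lab6)
  expect_equal(r2$average_accuracy, 1)
  expect_true(all(r2$confusion[upper.tri(r2$confusion)] == 0))
  expect_true(all(r2$confusion[lower.tri(r2$confusion)] == 0))

  expect_error(evaluate_predictions(all_right, lab6[1:3]),
               class = "gait_length_mismatch")
})

test_that("argmax ties break toward the lowest class index", {
  r <- evaluate_predictions(matrix(c(0.4, 0.4, 0.2), 1L), "ambling")
  expect_equal(r$confusion["ambling", "standing"], 1)
})

test_that("evaluate agrees with a brute-force recount on random predictions", {
  set.seed(9)
  for (rep_i in 1:100) {
    n <- sample(3:40, 1L)
    labels <- sample(action_levels(), n, replace = TRUE)
    while (length(unique(labels)) < 1L) labels <- sample(action_levels(), n, TRUE)
    scores <- random_scores(n)
    r <- evaluate_predictions(scores, labels)
    brute <- matrix(0L, 3L, 3L)
    for (i in seq_len(n)) {
      pred <- which(scores[i, ] == max(scores[i, ]))[1]
      tru <- match(labels[i], action_levels())
      brute[tru, pred] <- brute[tru, pred] + 1L
    }
    expect_equal(unname(unclass(r$confusion)), unname(brute))
    expect_equal(unname(rowSums(r$confusion)),
                 as.vector(table(factor(labels, levels = action_levels()))))
    pc <- diag(brute) / rowSums(brute)
    expect_equal(r$average_accuracy, mean(pc, na.rm = TRUE))
  }
})
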