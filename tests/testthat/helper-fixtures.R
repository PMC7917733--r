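# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

# Independent vector-angle oracle: angle at the knee via atan2 of the
# cross/dot products (never touches the law-of-cosines path).
oracle_angle <- function(hip, knee, ankle) {
  u <- hip - knee; v <- ankle - knee
  cr <- u[1] * v[2] - u[2] * v[1]
  dt <- sum(u * v)
  abs(atan2(cr, dt)) * 180 / pi
}

# Random non-degenerate (hip, knee, ankle) triple.
random_triple <- function() {
  repeat {
    pts <- matrix(stats::runif(6, -100, 100), 3L, 2L)
    d1 <- sqrt(sum((pts[1, ] - pts[2, ])^2))
    d2 <- sqrt(sum((pts[3, ] - pts[2, ])^2))
    if (d1 > 1e-3 && d2 > 1e-3) return(pts)
  }
}

# Pose sequence with every frame identical (18 landmarks at given triples).
constant_pose_seq <- function(n = 10L, hip = c(0, 0), knee = c(1, 0),
                              ankle = c(2, 0), clip_id = "const") {
  coords <- array(0, c(n, 18L, 2L))
  coords[, , 1] <- matrix(seq_len(18L) * 10, n, 18L, byrow = TRUE)  # spread others
  coords[, , 2] <- 5
  for (tri in list(c(10L, 11L, 12L), c(14L, 15L, 16L))) {
    coords[, tri[1], ] <- matrix(hip, n, 2L, byrow = TRUE)
    coords[, tri[2], ] <- matrix(knee, n, 2L, byrow = TRUE)
    coords[, tri[3], ] <- matrix(ankle, n, 2L, byrow = TRUE)
  }
  pose_sequence(clip_id, coords)
}

# Random row-normalized score matrix.
random_scores <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rexp(n * 3L), n, 3L)
  m / rowSums(m)
}

# Naive dense 3x3 SAME convolution in plain R loops (oracle for the compiled
# kernel; weight layout r = t*C + c with t = 3*dj + di).
naive_conv3 <- function(x, Wm, b, H, W, C, B) {
  K <- nrow(Wm)
  y <- matrix(0, K, H * W * B)
  for (bb in seq_len(B)) for (j in seq_len(W)) for (i in seq_len(H)) {
    p <- (bb - 1L) * H * W + (j - 1L) * H + i
    for (k in seq_len(K)) {
      acc <- b[k]
      for (cc in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
        ii <- i + di - 1L; jj <- j + dj - 1L
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          acc <- acc + Wm[k, (dj * 3L + di) * C + cc] *
            x[cc, (bb - 1L) * H * W + (jj - 1L) * H + ii]
        }
      }
      y[k, p] <- acc
    }
  }
  y
}

# Tiny separable two-class rasters: left-bright vs right-bright.
toy_rasters <- function(n_per_class = 6L, size = 32L, seed = 1L) {
  set.seed(seed)
  imgs <- list(); labs <- character()
  for (i in seq_len(n_per_class)) {
    left <- matrix(0, size, size); left[, 1:(size / 2)] <- 1
    right <- matrix(0, size, size); right[, (size / 2 + 1):size] <- 1
    imgs[[2 * i - 1]] <- pmin(pmax(left + matrix(rnorm(size^2, sd = 0.05), size), 0), 1)
    imgs[[2 * i]] <- pmin(pmax(right + matrix(rnorm(size^2, sd = 0.05), size), 0), 1)
    labs <- c(labs, "standing", "ambling")
  }
  list(images = imgs, labels = labs)
}
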