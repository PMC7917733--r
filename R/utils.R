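# Internal helpers shared across modules.

# Classed error constructor so callers can branch on condition class.
gait_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gait_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

gait_usage_error <- function(msg) gait_error("gait_usage_error", msg)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shoelace signed area of a polygon given as an n x 2 matrix (x, y columns).
shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(2:n, 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' Bilinear image resize
#'
#' Resizes a single-channel image (numeric matrix) to a new height and width
#' with bilinear interpolation, treating pixel values as samples at pixel
#' centres. Used to bring rasterized outlines to the network input size and to
#' downscale frames for key-frame clustering.
#'
#' @param img numeric matrix (rows = height, columns = width).
#' @param h,w target height and width in pixels.
#' @return an `h` x `w` numeric matrix.
#' @export
resize_bilinear <- function(img, h, w) {
  stopifnot(is.matrix(img), is_count(h), is_count(w))
  H <- nrow(img); W <- ncol(img)
  if (H == h && W == w) return(img)
  # map target pixel centres into source coordinates (align-centres convention)
  sy <- (seq_len(h) - 0.5) * H / h + 0.5 - 0.5  # in [0.5, H+0.5) pixel-centre space
  sx <- (seq_len(w) - 0.5) * W / w + 0.5 - 0.5
  y0 <- clamp(floor(sy - 0.5) + 0.5, 0.5, H - 0.5)  # lower sample centre
  x0 <- clamp(floor(sx - 0.5) + 0.5, 0.5, W - 0.5)
  wy <- clamp(sy - y0, 0, 1); wx <- clamp(sx - x0, 0, 1)
  i0 <- as.integer(y0 + 0.5); i1 <- pmin(i0 + 1L, H)
  j0 <- as.integer(x0 + 0.5); j1 <- pmin(j0 + 1L, W)
  a <- img[i0, j0, drop = FALSE]; b <- img[i0, j1, drop = FALSE]
  c_ <- img[i1, j0, drop = FALSE]; d <- img[i1, j1, drop = FALSE]
  wy <- matrix(wy, nrow = h, ncol = w)
  wx <- matrix(wx, nrow = h, ncol = w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

# Evaluate code under a fixed seed, restoring global RNG state afterwards:
# all simulator/training randomness flows through explicit seeds.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Ray-casting point-in-polygon (closed polygon, n x 2 matrix). Boundary points
# may fall either side; callers needing robustness shrink/grow the query.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    kk <- j[k]
    crosses <- ((y[k] > py) != (y[kk] > py)) &
      (px < (x[kk] - x[k]) * (py - y[k]) / (y[kk] - y[k]) + x[k])
    inside <- xor(inside, crosses)
  }
  inside
}
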