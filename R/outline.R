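# Spatial stream: outline extraction from binary masks, 112x112 contour
# rasters, and a small VGG-style CNN (three 3x3 conv blocks of 64/128/256
# channels, each followed by a stride-2 max pool, then two fully-connected
# layers and a softmax).

#' Extract the outline polygon of a binary mask
#'
#' Traces the boundary of the largest connected foreground component with
#' marching squares (`grDevices::contourLines` at level 0.5 on the
#' zero-padded mask). For a simply-connected mask the returned polygon is
#' closed and non-self-intersecting; its shoelace area matches the component
#' pixel count up to the half-pixel boundary convention.
#'
#' @param mask matrix of 0/1 (logical or numeric); at least one foreground
#'   pixel.
#' @return an `n x 2` matrix with columns `x` (column coordinate) and `y`
#'   (row coordinate) in mask pixel units; vertices ordered along the
#'   boundary, closure implicit (last vertex connects to first).
#' @export
extract_outline <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- (mask > 0) + 0
  if (!any(m > 0)) gait_error("gait_empty_mask", "mask has no foreground pixels")
  H <- nrow(m); W <- ncol(m)
  mp <- matrix(0, H + 2L, W + 2L)
  mp[2:(H + 1L), 2:(W + 1L)] <- m
  # contourLines' x follows rows, y follows columns; coordinates are pixel
  # indices in the padded frame
  cls <- grDevices::contourLines(seq_len(H + 2L), seq_len(W + 2L), mp, levels = 0.5)
  if (length(cls) == 0L) gait_error("gait_empty_mask", "no contour found")
  areas <- vapply(cls, function(cl) abs(shoelace_area(cbind(cl$x, cl$y))), 0)
  cl <- cls[[which.max(areas)]]
  poly <- cbind(x = cl$y - 1, y = cl$x - 1)  # back to (col, row), unpadded
  n <- nrow(poly)
  if (n > 1L && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

#' Rasterize an outline polygon to the network input raster
#'
#' Draws the contour as a 1-pixel stroke on a zero canvas of the source mask
#' size, resizes to `out_size` x `out_size` with bilinear interpolation, and
#' renormalizes to `[0, 1]`.
#'
#' @param polygon `n x 2` matrix from [extract_outline()] (columns x, y).
#' @param canvas `(height, width)` of the source coordinate frame.
#' @param out_size network input side length (default 112).
#' @param fill if `TRUE`, rasterize the filled silhouette instead of the
#'   hollow contour.
#' @return an `out_size` x `out_size` numeric matrix in `[0, 1]`.
#' @export
rasterize_outline <- function(polygon, canvas, out_size = 112L, fill = FALSE) {
  if (is.null(polygon) || nrow(polygon) == 0L) {
    gait_error("gait_empty_mask", "polygon is empty")
  }
  h <- canvas[1]; w <- canvas[2]
  img <- matrix(0, h, w)
  n <- nrow(polygon)
  nxt <- c(2:n, 1L)
  for (e in seq_len(n)) {
    p1 <- polygon[e, ]; p2 <- polygon[nxt[e], ]
    len <- sqrt(sum((p2 - p1)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4) + 1L))
    xs <- clamp(round(p1[1] + ts * (p2[1] - p1[1])), 1, w)
    ys <- clamp(round(p1[2] + ts * (p2[2] - p1[2])), 1, h)
    img[cbind(ys, xs)] <- 1
  }
  if (fill) {
    px <- rep(seq_len(w), each = h); py <- rep(seq_len(h), times = w)
    img[matrix(point_in_polygon(px, py, polygon), h, w)] <- 1
  }
  out <- resize_bilinear(img, out_size, out_size)
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

#' Class-probability softmax
#'
#' `p(y = n | x) = exp(z_n) / sum_k exp(z_k)`, computed with max-subtraction
#' for numerical stability.
#'
#' @param logits numeric vector of finite class scores.
#' @return probability vector summing to 1; named with [action_levels()] when
#'   `length(logits) == 3`.
#' @export
softmax_scores <- function(logits) {
  if (!is.numeric(logits) || !all(is.finite(logits))) {
    gait_error("gait_bad_param", "logits must be finite numbers")
  }
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  if (length(p) == 3L && is.null(names(p))) names(p) <- action_levels()
  p
}

#' Tiny VGG architecture configuration
#'
#' Three 3x3 stride-1 convolution blocks of 64, 128 and 256 channels, each
#' followed by a 2x2 stride-2 max pool, then two fully-connected layers
#' (`fc_size`, then `n_classes`) with ReLU activations and a softmax output.
#' For the 112x112 input the pooled spatial sizes are 56, 28 and 14, leaving
#' a 14x14x256 map before the classifier head.
#'
#' @param conv_channels channel counts of the three conv blocks.
#' @param fc_size width of the penultimate fully-connected layer.
#' @param n_classes number of output classes.
#' @param input_size input raster side length.
#' @return an object of class `tiny_vgg_config`.
#' @export
tiny_vgg_config <- function(conv_channels = c(64L, 128L, 256L), fc_size = 256L,
                            n_classes = 3L, input_size = 112L) {
  stopifnot(length(conv_channels) == 3L, all(conv_channels >= 1L),
            is_count(fc_size), is_count(n_classes), is_count(input_size, 8L))
  structure(list(conv_channels = as.integer(conv_channels),
                 fc_size = as.integer(fc_size),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size)),
            class = "tiny_vgg_config")
}

#' @rdname tiny_vgg_config
#' @param config a `tiny_vgg_config`.
#' @return `tiny_vgg_shapes()`: data frame tracing the output height/width
#'   and channels of every stage.
#' @export
tiny_vgg_shapes <- function(config = tiny_vgg_config()) {
  s <- config$input_size
  rows <- list()
  for (l in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("conv%d_3x3", l), out_h = s, out_w = s,
      channels = config$conv_channels[l])
    s <- s %/% 2L
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("maxpool%d_2x2", l), out_h = s, out_w = s,
      channels = config$conv_channels[l])
  }
  rows[[length(rows) + 1L]] <- data.frame(layer = "fc1", out_h = 1L, out_w = 1L,
                                          channels = config$fc_size)
  rows[[length(rows) + 1L]] <- data.frame(layer = "fc2", out_h = 1L, out_w = 1L,
                                          channels = config$n_classes)
  do.call(rbind, rows)
}

#' @rdname tiny_vgg_config
#' @return `tiny_vgg_param_count()`: total number of trainable parameters.
#' @export
tiny_vgg_param_count <- function(config = tiny_vgg_config()) {
  cc <- c(1L, config$conv_channels)
  n <- 0
  for (l in 1:3) n <- n + 9 * cc[l] * cc[l + 1] + cc[l + 1]
  s <- config$input_size %/% 8L
  flat <- s * s * config$conv_channels[3]
  n + flat * config$fc_size + config$fc_size +
    config$fc_size * config$n_classes + config$n_classes
}

#' @rdname tiny_vgg_config
#' @param input_size,n_classes dimensions for the reference VGG16 (13 conv
#'   layers of 64..512 channels, three fully-connected layers 4096/4096/K).
#' @return `vgg16_param_count()`: parameter count of a full VGG16 at the same
#'   input size, the reference the tiny network is measured against.
#' @export
vgg16_param_count <- function(input_size = 112L, n_classes = 1000L) {
  blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  cin <- 3; n <- 0; s <- input_size
  for (bl in blocks) {
    for (ch in bl) { n <- n + 9 * cin * ch + ch; cin <- ch }
    s <- s %/% 2L
  }
  n + (s * s * 512) * 4096 + 4096 + 4096 * 4096 + 4096 +
    4096 * n_classes + n_classes
}

# ---- training ------------------------------------------------------------

tvgg_init <- function(config) {
  cc <- c(1L, config$conv_channels)
  params <- list()
  for (l in 1:3) {
    fan_in <- 9 * cc[l]
    params[[paste0("Wc", l)]] <- matrix(stats::rnorm(cc[l + 1] * 9 * cc[l],
                                                     sd = sqrt(2 / fan_in)),
                                        cc[l + 1], 9 * cc[l])
    params[[paste0("bc", l)]] <- numeric(cc[l + 1])
  }
  s <- config$input_size %/% 8L
  flat <- s * s * config$conv_channels[3]
  params$W1 <- matrix(stats::rnorm(config$fc_size * flat, sd = sqrt(2 / flat)),
                      config$fc_size, flat)
  params$b1 <- numeric(config$fc_size)
  params$W2 <- matrix(stats::rnorm(config$n_classes * config$fc_size,
                                   sd = sqrt(2 / config$fc_size)),
                      config$n_classes, config$fc_size)
  params$b2 <- numeric(config$n_classes)
  params
}

# The full forward/backward/Adam step runs in compiled code
# (cpp_tvgg_train_step): with 100-200 MB intermediates per batch, R-level
# staging would spend most of its time in the garbage collector. The conv
# output is pooled before the (monotone) ReLU, which is algebraically
# identical to ReLU-then-pool for max pooling.

#' Fit the Tiny VGG outline classifier
#'
#' Minimizes softmax cross-entropy with Adam (learning rate 0.01 and 30
#' epochs by default). Gradients are
#' clipped to a global norm of 5 for stability at this learning rate. The
#' fit is bit-reproducible given the same data and seed.
#'
#' @param x list of `input_size` x `input_size` numeric matrices in `[0, 1]`
#'   (see [rasterize_outline()]).
#' @param labels action labels, one per image (every class must appear).
#' @param config a [tiny_vgg_config()].
#' @param epochs,lr,batch_size Adam training hyperparameters.
#' @param seed integer seed for initialization and batch shuffling.
#' @param verbose print per-epoch loss/accuracy.
#' @return an object of class `tiny_vgg`: list with `params`, `config`,
#'   `classes`, and a per-epoch training `log` (data frame with `epoch`,
#'   `loss`, `accuracy`).
#' @export
fit_tiny_vgg <- function(x, labels, config = tiny_vgg_config(), epochs = 30L,
                         lr = 0.01, batch_size = 8L, seed = 0L, verbose = FALSE) {
  labels <- action_factor_or_generic(labels, config$n_classes)
  if (length(x) != length(labels)) gait_error("gait_length_mismatch", "x and labels differ in length")
  if (any(tabulate(as.integer(labels), nbins = config$n_classes) == 0L)) {
    gait_error("gait_class_missing", "every class needs at least one training example")
  }
  S <- config$input_size
  ok <- vapply(x, function(im) is.matrix(im) && all(dim(im) == S), TRUE)
  if (!all(ok)) gait_error("gait_bad_param", sprintf("all images must be %d x %d", S, S))
  n <- length(x)
  yint <- as.integer(labels)
  with_seed(seed, {
    params <- tvgg_init(config)
    ms <- lapply(params, function(p) p * 0)
    vs <- lapply(params, function(p) p * 0)
    step <- 0L
    log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0L
      for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
        B <- length(bs)
        xb <- matrix(unlist(x[bs], use.names = FALSE), nrow = 1L)
        step <- step + 1L
        res <- cpp_tvgg_train_step(xb, yint[bs], params, ms, vs, S, B,
                                   lr, step, 5, 0.9, 0.999, 1e-8)
        tot_loss <- tot_loss + res$loss * B
        tot_correct <- tot_correct + res$correct
      }
      log <- rbind(log, data.frame(epoch = ep, loss = tot_loss / n,
                                   accuracy = tot_correct / n))
      if (verbose) message(sprintf("epoch %d: loss %.4f acc %.3f",
                                   ep, tot_loss / n, tot_correct / n))
    }
    structure(list(params = params, config = config,
                   classes = levels(labels), seed = as.integer(seed),
                   hyper = list(epochs = epochs, lr = lr, batch_size = batch_size),
                   log = log),
              class = "tiny_vgg")
  })
}

# Labels may be gait classes or generic factors (toy fixtures).
action_factor_or_generic <- function(labels, n_classes) {
  if (n_classes == 3L && (is.character(labels) || is.numeric(labels)) &&
      all(as.character(labels) %in% action_levels())) {
    return(action_factor(labels))
  }
  f <- as.factor(labels)
  if (nlevels(f) > n_classes) gait_error("gait_bad_label", "more label levels than classes")
  f
}

#' @export
print.tiny_vgg <- function(x, ...) {
  cat(sprintf("<tiny_vgg: %s params, input %dx%d, final loss %.4f>\n",
              format(tiny_vgg_param_count(x$config), big.mark = ","),
              x$config$input_size, x$config$input_size,
              utils::tail(x$log$loss, 1)))
  invisible(x)
}

#' Predict class scores for outline rasters
#'
#' @param object a fitted [fit_tiny_vgg()] model.
#' @param newdata list of input rasters.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return `n x n_classes` matrix of probabilities, rows summing to 1.
#' @export
predict.tiny_vgg <- function(object, newdata, batch_size = 16L, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  n <- length(newdata)
  if (n == 0L) gait_error("gait_empty_clip", "no frames to predict")
  out <- matrix(0, n, object$config$n_classes,
                dimnames = list(NULL, object$classes))
  for (bs in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    B <- length(bs)
    xb <- matrix(unlist(newdata[bs], use.names = FALSE), nrow = 1L)
    out[bs, ] <- t(cpp_tvgg_predict(xb, object$params, object$config$input_size, B))
  }
  out
}

#' Clip-level score from the outline stream
#'
#' Arithmetic mean of the per-frame score vectors — order-invariant and still
#' a probability vector.
#'
#' @param model a fitted [fit_tiny_vgg()] model.
#' @param frames list of outline rasters belonging to one clip.
#' @return named probability vector over the classes.
#' @export
predict_outline_clip <- function(model, frames) {
  if (length(frames) == 0L) gait_error("gait_empty_clip", "clip has no frames")
  colMeans(predict(model, frames))
}
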