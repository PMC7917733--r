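# Kinematic gait simulator. Stands in for the unavailable field video data:
# an articulated 2-D stick quadruped whose two visible legs' knee angles
# follow per-gait sinusoids, rendered to landmark sequences and silhouette
# masks. The programmed regimes reproduce the reported per-gait knee-angle
# ranges: standing confined to ~140-160 deg, galloping sweeping ~80-180 deg,
# ambling intermediate.

#' Per-gait oscillator parameters
#'
#' The knee bending angle of each visible leg follows
#' `theta(t) = mean_angle + amplitude * sin(2*pi*frequency*t + phi)`, with the
#' front leg lagging the hind leg by `phase_lag` radians. Defaults encode the
#' three gait regimes: standing mean 150 / amplitude 10 (range 140-160),
#' ambling mean 140 / amplitude 40, galloping mean 130 / amplitude 50 (range
#' 80-180) at double the stride frequency plus a constant horizontal body
#' translation.
#'
#' @param label one of `action_levels()`.
#' @param mean_angle,amplitude degrees; `mean_angle +/- amplitude` must stay
#'   inside (0, 180).
#' @param frequency stride cycles per second (> 0).
#' @param phase_lag front-vs-hind phase offset, radians.
#' @param jitter_sd landmark tracking noise, pixels (Gaussian, per coordinate).
#' @param invalid_prob per-frame probability that one random leg landmark is
#'   dropped (non-visible), in `[0, 0.3]`.
#' @param speed horizontal body translation, model units per second
#'   (body length = 2 model units); non-zero by default only for galloping.
#' @return an object of class `gait_params`.
#' @export
gait_params <- function(label,
                        mean_angle = NULL, amplitude = NULL, frequency = NULL,
                        phase_lag = pi, jitter_sd = 1, invalid_prob = 0.02,
                        speed = NULL) {
  label <- as.character(action_factor(label))
  def <- switch(label,
    standing  = list(mean = 150, amp = 10, freq = 0.5, speed = 0),
    ambling   = list(mean = 140, amp = 40, freq = 1.0, speed = 0),
    galloping = list(mean = 130, amp = 50, freq = 2.0, speed = 2.0))
  mean_angle <- if (is.null(mean_angle)) def$mean else mean_angle
  amplitude <- if (is.null(amplitude)) def$amp else amplitude
  frequency <- if (is.null(frequency)) def$freq else frequency
  speed <- if (is.null(speed)) def$speed else speed
  if (!(mean_angle - amplitude > 0 && mean_angle + amplitude <= 180)) {
    gait_error("gait_bad_param", "mean_angle +/- amplitude must stay inside (0, 180]")
  }
  if (!is.numeric(frequency) || frequency <= 0) {
    gait_error("gait_bad_param", "frequency must be > 0")
  }
  if (!is_prob(invalid_prob) || invalid_prob > 0.3) {
    gait_error("gait_bad_param", "invalid_prob must be in [0, 0.3]")
  }
  if (!is.numeric(jitter_sd) || jitter_sd < 0) {
    gait_error("gait_bad_param", "jitter_sd must be >= 0")
  }
  structure(list(label = label, mean_angle = mean_angle, amplitude = amplitude,
                 frequency = frequency, phase_lag = phase_lag,
                 jitter_sd = jitter_sd, invalid_prob = invalid_prob,
                 speed = speed),
            class = "gait_params")
}

#' @rdname gait_params
#' @param ... arguments forwarded to [gait_params()] for every class.
#' @export
default_gait_params <- function(...) {
  ps <- lapply(action_levels(), gait_params, ...)
  names(ps) <- action_levels()
  ps
}

# Static body-frame landmark positions (model units; x right, y DOWN, spine
# at y = 0 running from croup x = 0 to withers x = 2). Legs are generated
# kinematically and overwrite their entries.
body_template <- function() {
  m <- matrix(NA_real_, 18L, 2L)
  rownames(m) <- default_landmark_names()
  m["nose", ] <- c(2.90, -0.45); m["head_top", ] <- c(2.60, -0.60)
  m["neck", ] <- c(2.30, -0.30); m["withers", ] <- c(2.00, 0.00)
  m["spine_mid", ] <- c(1.00, 0.00); m["croup", ] <- c(0.00, 0.00)
  m["tail_base", ] <- c(-0.20, -0.10); m["tail_mid", ] <- c(-0.60, -0.35)
  m["tail_tip", ] <- c(-1.00, -0.55)
  m["front_hip", ] <- c(1.80, 0.10); m["hind_hip", ] <- c(0.20, 0.10)
  m["belly", ] <- c(1.00, 0.30)
  m
}

# Skeleton connectivity used by the silhouette renderer.
skeleton_edges <- function() {
  nm <- default_landmark_names()
  e <- rbind(
    c("nose", "head_top"), c("head_top", "neck"), c("neck", "withers"),
    c("withers", "spine_mid"), c("spine_mid", "croup"),
    c("croup", "tail_base"), c("tail_base", "tail_mid"), c("tail_mid", "tail_tip"),
    c("front_hip", "front_knee"), c("front_knee", "front_ankle"),
    c("front_ankle", "front_paw"),
    c("hind_hip", "hind_knee"), c("hind_knee", "hind_ankle"),
    c("hind_ankle", "hind_paw"),
    c("withers", "front_hip"), c("croup", "hind_hip"),
    c("withers", "belly"), c("croup", "belly")
  )
  cbind(match(e[, 1], nm), match(e[, 2], nm))
}

# One leg by forward kinematics. hip: length-2; beta: femur angle from
# vertical (radians); theta: interior knee angle (degrees); bend_sign: which
# way the knee folds. Femur and tibia are unit length, paw extends 0.25.
leg_fk <- function(hip, beta, theta, bend_sign, femur = 1, tibia = 1) {
  u <- c(sin(beta), cos(beta))                 # y down: beta = 0 -> straight down
  knee <- hip + femur * u
  delta <- bend_sign * (180 - theta) * pi / 180
  v <- c(cos(delta) * u[1] - sin(delta) * u[2],
         sin(delta) * u[1] + cos(delta) * u[2])
  ankle <- knee + tibia * v
  paw <- ankle + 0.25 * v
  rbind(knee, ankle, paw)
}

#' Simulate one labelled clip
#'
#' Builds an articulated stick quadruped: each visible leg's knee angle
#' follows the sinusoid programmed in `params` (front lagging hind by
#' `phase_lag`), limb coordinates derive from fixed segment lengths by
#' forward kinematics, Gaussian tracking jitter perturbs every landmark, and
#' frames occasionally lose one leg landmark (`invalid_prob`). Galloping adds
#' constant horizontal body translation. In the `"perpendicular"` view (spine
#' perpendicular to the image plane) the leg joints are exactly collinear, so
#' every knee angle degenerates to 180 degrees regardless of gait. Output is
#' deterministic given `(params, n_frames, fps, seed)`.
#'
#' @param params a [gait_params()].
#' @param n_frames number of frames (>= 2).
#' @param fps frames per second.
#' @param seed integer seed; all clip randomness derives from it.
#' @param canvas `(height, width)` of the rendered masks in pixels; landmark
#'   coordinates are autoscaled into this canvas once per clip.
#' @param view `"lateral"` (default) or `"perpendicular"`.
#' @param render_masks render per-frame silhouette masks (set `FALSE` to skip
#'   the rasterization cost when only landmarks are needed).
#' @param limb_width silhouette limb thickness in pixels.
#' @param clip_id identifier stored on the pose sequence (default derived
#'   from label and seed).
#' @param phase0 initial oscillator phase in radians; `NULL` (default) draws
#'   it uniformly from the clip's RNG. Fixing it makes the angle extrema land
#'   exactly on sampled frames, which the round-trip tests exploit.
#' @return an object of class `clip_bundle`: list with `pose`
#'   (a [pose_sequence()]), `masks` (list of 0/1 matrices or `NULL`), `label`,
#'   `seed`.
#' @export
simulate_clip <- function(params, n_frames = 120L, fps = 30, seed = 0L,
                          canvas = c(112L, 112L), view = c("lateral", "perpendicular"),
                          render_masks = TRUE, limb_width = 4,
                          clip_id = NULL, phase0 = NULL) {
  stopifnot(inherits(params, "gait_params"))
  view <- match.arg(view)
  if (!is_count(n_frames, min = 2L)) gait_error("gait_bad_param", "n_frames must be >= 2")
  if (is.null(clip_id)) clip_id <- sprintf("%s_seed%d", params$label, as.integer(seed))
  tmpl <- body_template()
  fr_tri <- c(10L, 11L, 12L); hd_tri <- c(14L, 15L, 16L)
  with_seed(seed, {
    phi0 <- if (is.null(phase0)) stats::runif(1, 0, 2 * pi) else phase0
    tt <- (seq_len(n_frames) - 1L) / fps
    coords <- array(NA_real_, c(n_frames, 18L, 2L))
    swing_amp <- 0.35 * params$amplitude / 50    # radians; scales with gait vigour
    for (f in seq_len(n_frames)) {
      m <- tmpl
      ph_h <- 2 * pi * params$frequency * tt[f] + phi0
      ph_f <- ph_h + params$phase_lag
      if (view == "perpendicular") {
        # spine points at the camera: legs project to exactly vertical lines
        for (leg in list(list(tri = fr_tri, hip = tmpl["front_hip", ]),
                         list(tri = hd_tri, hip = tmpl["hind_hip", ]))) {
          knee <- leg$hip + c(0, 1)
          ankle <- knee + c(0, 1)
          m[leg$tri[2], ] <- knee; m[leg$tri[3], ] <- ankle
          m[leg$tri[3] + 1L, ] <- ankle + c(0, 0.25)
          m[leg$tri[1], ] <- leg$hip
        }
      } else {
        th_f <- params$mean_angle + params$amplitude * sin(ph_f)
        th_h <- params$mean_angle + params$amplitude * sin(ph_h)
        m[fr_tri[2]:(fr_tri[3] + 1L), ] <-
          leg_fk(tmpl["front_hip", ], swing_amp * sin(ph_f), th_f, bend_sign = -1)
        m[hd_tri[2]:(hd_tri[3] + 1L), ] <-
          leg_fk(tmpl["hind_hip", ], swing_amp * sin(ph_h), th_h, bend_sign = 1)
      }
      m[, 1] <- m[, 1] + params$speed * tt[f]   # gallop translation
      coords[f, , ] <- m
    }
    # one affine map (uniform scale + translation) per clip into the canvas
    h <- canvas[1]; w <- canvas[2]
    rngx <- range(coords[, , 1]); rngy <- range(coords[, , 2])
    s <- 0.9 * min((w - 1) / max(diff(rngx), 1e-9), (h - 1) / max(diff(rngy), 1e-9))
    offx <- (w - s * diff(rngx)) / 2 - s * rngx[1]
    offy <- (h - s * diff(rngy)) / 2 - s * rngy[1]
    coords[, , 1] <- coords[, , 1] * s + offx
    coords[, , 2] <- coords[, , 2] * s + offy
    if (params$jitter_sd > 0) {
      coords <- coords + stats::rnorm(length(coords), sd = params$jitter_sd)
    }
    visible <- matrix(TRUE, n_frames, 18L)
    if (params$invalid_prob > 0) {
      drop_frame <- stats::runif(n_frames) < params$invalid_prob
      leg_pts <- c(fr_tri, hd_tri)
      for (f in which(drop_frame)) {
        visible[f, sample(leg_pts, 1L)] <- FALSE
      }
    }
    pose <- pose_sequence(clip_id, coords, visible, fps = fps, label = params$label)
    masks <- NULL
    if (render_masks) {
      masks <- lapply(seq_len(n_frames), function(f) {
        render_silhouette(matrix(coords[f, , ], 18L, 2L), visible[f, ],
                          limb_width = limb_width, canvas = canvas,
                          autoscale = FALSE)
      })
    }
    structure(list(pose = pose, masks = masks, label = params$label,
                   seed = as.integer(seed)),
              class = "clip_bundle")
  })
}

#' @export
print.clip_bundle <- function(x, ...) {
  cat(sprintf("<clip_bundle '%s': %d frames, label=%s, masks=%s, seed=%d>\n",
              x$pose$clip_id, dim(x$pose$coords)[1], x$label,
              if (is.null(x$masks)) "none" else "rendered", x$seed))
  invisible(x)
}

#' Render a stick-figure silhouette mask
#'
#' Rasterizes the body and limbs as filled capsules (thick segments) around
#' the skeleton, producing the binary instance mask that an upstream
#' segmentation network would supply for real footage. Edges with a
#' non-visible endpoint are skipped (occlusion corrupts landmarks, not the
#' mask, which keeps the two streams' noise models independent).
#'
#' @param coords 18 x 2 matrix of landmark `(x, y)` positions.
#' @param visible logical vector of length 18 (default all visible).
#' @param limb_width stroke thickness in pixels; the torso is drawn 3x wider.
#' @param canvas `(height, width)` in pixels.
#' @param autoscale if `TRUE`, rescale coordinates to fit the canvas with a
#'   5% margin; disable when coordinates are already in canvas pixels.
#' @return an integer 0/1 matrix of dimension `canvas`.
#' @export
render_silhouette <- function(coords, visible = NULL, limb_width = 4,
                              canvas = c(112L, 112L), autoscale = TRUE) {
  stopifnot(is.matrix(coords), nrow(coords) == 18L, ncol(coords) == 2L)
  if (is.null(visible)) visible <- rep(TRUE, 18L)
  if (sum(visible & is.finite(coords[, 1]) & is.finite(coords[, 2])) < 2L) {
    gait_error("gait_empty_pose", "need at least 2 visible landmarks to render")
  }
  h <- canvas[1]; w <- canvas[2]
  if (autoscale) {
    vc <- coords[visible, , drop = FALSE]
    rngx <- range(vc[, 1]); rngy <- range(vc[, 2])
    s <- 0.9 * min((w - 1) / max(diff(rngx), 1e-9), (h - 1) / max(diff(rngy), 1e-9))
    coords[, 1] <- coords[, 1] * s + (w - s * diff(rngx)) / 2 - s * rngx[1]
    coords[, 2] <- coords[, 2] * s + (h - s * diff(rngy)) / 2 - s * rngy[1]
  }
  px <- rep(seq_len(w), each = h)   # column-major pixel coords: x = column
  py <- rep(seq_len(h), times = w)  # y = row
  covered <- rep(FALSE, h * w)
  edges <- skeleton_edges()
  torso <- c(4L, 5L, 6L)  # withers - spine_mid - croup drawn thick
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (!visible[a] || !visible[b]) next
    p1 <- coords[a, ]; p2 <- coords[b, ]
    if (!all(is.finite(c(p1, p2)))) next
    wd <- if (a %in% torso && b %in% torso) 3 * limb_width else limb_width
    d <- p2 - p1
    L2 <- sum(d * d)
    tpar <- if (L2 < 1e-12) rep(0, h * w) else
      clamp(((px - p1[1]) * d[1] + (py - p1[2]) * d[2]) / L2, 0, 1)
    dx <- px - (p1[1] + tpar * d[1]); dy <- py - (p1[2] + tpar * d[2])
    covered <- covered | (dx * dx + dy * dy <= (wd / 2)^2)
  }
  matrix(as.integer(covered), h, w)
}

#' Simulate a balanced, split synthetic dataset
#'
#' Generates `n_per_class` clips for each gait, with per-clip frame counts
#' drawn uniformly from `frame_range` (default 60-240 frames, i.e. 2-8 s at
#' 30 FPS) and per-clip seeds derived from `seed`, then randomly splits each
#' class into disjoint train/test sets (counts per split differ by at most
#' one between classes).
#'
#' @param n_per_class clips per gait class (>= 2).
#' @param split fraction of each class assigned to the training set.
#' @param seed master seed; clip seeds and the split derive from it.
#' @param params_list named list of [gait_params()], one per class.
#' @param frame_range `(min, max)` frames per clip.
#' @inheritParams simulate_clip
#' @return list with elements `train` and `test`, each a list of
#'   [simulate_clip()] bundles.
#' @export
make_gait_dataset <- function(n_per_class = 10L, split = 0.5, seed = 0L,
                              params_list = default_gait_params(),
                              frame_range = c(60L, 240L), fps = 30,
                              canvas = c(112L, 112L), render_masks = TRUE,
                              limb_width = 4) {
  if (!is_count(n_per_class, min = 2L)) gait_error("gait_bad_param", "n_per_class must be >= 2")
  if (!is_prob(split) || split <= 0 || split >= 1) {
    gait_error("gait_bad_param", "split must be in (0, 1)")
  }
  stopifnot(all(action_levels() %in% names(params_list)))
  plan <- with_seed(seed, {
    lapply(action_levels(), function(lbl) {
      nf <- sample(seq(frame_range[1], frame_range[2]), n_per_class, replace = TRUE)
      sd <- sample.int(.Machine$integer.max - 1L, n_per_class)
      ord <- sample.int(n_per_class)
      list(label = lbl, n_frames = nf, seeds = sd, order = ord)
    })
  })
  train <- list(); test <- list()
  n_train <- round(n_per_class * split)
  for (pl in plan) {
    for (i in seq_len(n_per_class)) {
      j <- pl$order[i]
      cb <- simulate_clip(params_list[[pl$label]], n_frames = pl$n_frames[j],
                          fps = fps, seed = pl$seeds[j], canvas = canvas,
                          render_masks = render_masks, limb_width = limb_width,
                          clip_id = sprintf("%s_%03d", pl$label, j))
      if (i <= n_train) train[[length(train) + 1L]] <- cb
      else test[[length(test) + 1L]] <- cb
    }
  }
  list(train = train, test = test)
}
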