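# Shared domain types: action labels, the 18-landmark skeleton schema, pose
# sequences, and the knee bending-angle primitive used by the temporal stream.

#' Gait class labels
#'
#' The three upright actions recognised by the pipeline, in their stable
#' order. `action_levels()` returns the character levels; `action_factor()`
#' coerces labels (character or integer codes 1..3) to a factor with those
#' levels.
#'
#' @return `action_levels()`: character vector
#'   `c("standing", "ambling", "galloping")`.
#' @export
action_levels <- function() c("standing", "ambling", "galloping")

#' @rdname action_levels
#' @param x character vector of labels or integer codes in 1..3.
#' @export
action_factor <- function(x) {
  lv <- action_levels()
  if (is.numeric(x)) {
    if (any(!x %in% seq_along(lv))) gait_error("gait_bad_label", "integer labels must be in 1..3")
    return(factor(lv[x], levels = lv))
  }
  x <- as.character(x)
  if (any(!x %in% lv)) {
    gait_error("gait_bad_label", sprintf(
      "unknown action label(s): %s (expected %s)",
      paste(unique(setdiff(x, lv)), collapse = ", "), paste(lv, collapse = "/")
    ))
  }
  factor(x, levels = lv)
}

#' Skeleton schema: 18 landmarks and the two knee triples
#'
#' Eighteen tracked body points describe the head, body, tail and the two
#' visible (outer-side) legs. Each visible leg contributes a
#' (hip, knee, ankle) triple whose middle element is the knee — the vertex of
#' the bending angle. Indices are 1-based; the default hind triple
#' `(14, 15, 16)` carries the same numbers used in field labelling guides for
#' the hind limb (knee = 16th landmark's predecessor, i.e. index 15). The
#' front triple is configurable because labelling conventions differ.
#'
#' @param landmark_names character vector of length 18.
#' @param front_triple,hind_triple integer triples `(hip, knee, ankle)`,
#'   1-based indices into `landmark_names`, all six distinct.
#' @return an object of class `skeleton_schema`.
#' @export
skeleton_schema <- function(landmark_names = default_landmark_names(),
                            front_triple = c(10L, 11L, 12L),
                            hind_triple = c(14L, 15L, 16L)) {
  front_triple <- as.integer(front_triple)
  hind_triple <- as.integer(hind_triple)
  if (length(landmark_names) != 18L) {
    gait_error("gait_schema_mismatch", "schema must name exactly 18 landmarks")
  }
  idx <- c(front_triple, hind_triple)
  if (length(idx) != 6L || anyDuplicated(idx) || any(idx < 1L) || any(idx > 18L)) {
    gait_error("gait_schema_mismatch",
               "knee triples must contain 6 distinct indices in 1..18")
  }
  structure(list(landmark_names = as.character(landmark_names),
                 front_triple = front_triple,
                 hind_triple = hind_triple),
            class = "skeleton_schema")
}

#' @rdname skeleton_schema
#' @export
default_landmark_names <- function() {
  c("nose", "head_top", "neck", "withers", "spine_mid", "croup",
    "tail_base", "tail_mid", "tail_tip",
    "front_hip", "front_knee", "front_ankle", "front_paw",
    "hind_hip", "hind_knee", "hind_ankle", "hind_paw",
    "belly")
}

#' Pose sequence for one clip
#'
#' Per-frame 2-D image coordinates (origin top-left, y increases downward) of
#' the 18 landmarks, with a per-landmark visibility flag. Non-visible
#' landmarks never enter angle computation.
#'
#' @param clip_id character scalar.
#' @param coords numeric array `T x 18 x 2` (frames, landmarks, x/y) in pixels.
#' @param visible logical matrix `T x 18`; defaults to all visible.
#' @param fps frames per second (> 0; clips are conventionally 30 FPS).
#' @param label optional action label (see [action_levels()]).
#' @return an object of class `pose_sequence`.
#' @export
pose_sequence <- function(clip_id, coords, visible = NULL, fps = 30, label = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L ||
      dim(coords)[2] != 18L || dim(coords)[3] != 2L) {
    gait_error("gait_schema_mismatch", sprintf(
      "coords must be a T x 18 x 2 array (got %s)", paste(dim(coords), collapse = " x ")))
  }
  n <- dim(coords)[1]
  if (n < 2L) gait_error("gait_too_short", "a pose sequence needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    gait_error("gait_bad_param", "fps must be a positive number")
  }
  if (is.null(visible)) visible <- matrix(TRUE, n, 18L)
  if (!is.matrix(visible) || !identical(dim(visible), c(n, 18L)) &&
      !identical(dim(visible), as.integer(c(n, 18L)))) {
    gait_error("gait_schema_mismatch", "visible must be a T x 18 logical matrix")
  }
  if (!is.null(label)) label <- as.character(action_factor(label))
  structure(list(clip_id = as.character(clip_id), coords = coords,
                 visible = visible, fps = fps, label = label),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence '%s': %d frames @ %g FPS%s>\n",
              x$clip_id, dim(x$coords)[1], x$fps,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1]

#' Knee bending angle (law of cosines)
#'
#' The interior angle at the knee between the femur (hip--knee) and tibia
#' (knee--ankle) segments:
#' `acos((L12^2 + L23^2 - L13^2) / (2 L12 L23))` in degrees, where
#' `L12 = |hip - knee|`, `L23 = |knee - ankle|`, `L13 = |hip - ankle|`.
#' The cosine argument is clamped to `[-1, 1]` so collinear joints return
#' exactly 180 even under floating-point rounding. The result is invariant to
#' rigid motion and uniform scaling, and symmetric in swapping hip and ankle.
#'
#' @param hip,knee,ankle numeric length-2 vectors `(x, y)` in pixels.
#' @param eps degenerate-segment threshold in pixels: if either leg segment is
#'   shorter than `eps` the joint is considered collapsed/occluded and a
#'   `gait_degenerate_geometry` error is signalled.
#' @return angle in degrees, in `(0, 180]`.
#' @export
#' @examples
#' bending_angle(c(0, 0), c(1, 0), c(2, 0))  # collinear -> 180
#' bending_angle(c(0, 0), c(1, 0), c(1, 1))  # perpendicular -> 90
bending_angle <- function(hip, knee, ankle, eps = 1e-9) {
  if (!all(is.finite(c(hip, knee, ankle)))) {
    gait_error("gait_degenerate_geometry", "landmarks must be finite")
  }
  d12 <- hip - knee; d23 <- ankle - knee; d13 <- hip - ankle
  L12 <- sqrt(sum(d12 * d12)); L23 <- sqrt(sum(d23 * d23))
  if (L12 <= eps || L23 <= eps) {
    gait_error("gait_degenerate_geometry",
               "leg segment collapsed below eps; treat frame as invalid")
  }
  L13 <- sqrt(sum(d13 * d13))
  arg <- (L12^2 + L23^2 - L13^2) / (2 * L12 * L23)
  acos(clamp(arg, -1, 1)) * 180 / pi
}

# Vectorised form over T frames: h, k, a are T x 2 matrices.
# Returns list(angle, ok) where ok flags non-degenerate geometry.
bending_angle_vec <- function(h, k, a, eps = 1e-9) {
  d12 <- h - k; d23 <- a - k; d13 <- h - a
  L12 <- sqrt(rowSums(d12 * d12)); L23 <- sqrt(rowSums(d23 * d23))
  L13sq <- rowSums(d13 * d13)
  ok <- is.finite(L12) & is.finite(L23) & is.finite(L13sq) & L12 > eps & L23 > eps
  arg <- (L12^2 + L23^2 - L13sq) / (2 * L12 * L23)
  ang <- acos(clamp(arg, -1, 1)) * 180 / pi
  ang[!ok] <- NA_real_
  list(angle = ang, ok = ok)
}

#' Per-clip knee bending-angle series
#'
#' Applies [bending_angle()] per frame to the front and hind knee triples of a
#' pose sequence. Frames where any triple landmark is non-visible, or where
#' the geometry is degenerate, are marked invalid; invalid interior frames are
#' filled by linear interpolation between the nearest valid neighbours, and
#' leading/trailing invalid frames copy the nearest valid value. A clip with
#' more than `max_invalid` fraction of invalid frames for either leg is
#' rejected as unusable.
#'
#' @param seq a [pose_sequence()].
#' @param schema a [skeleton_schema()].
#' @param max_invalid maximum tolerated invalid-frame fraction per leg
#'   (default 0.3).
#' @return an object of class `angle_series`: list with `front`, `hind`
#'   (degrees, length T), `valid` (logical, T), `clip_id`, `fps`, `label`.
#' @export
angle_series <- function(seq, schema = skeleton_schema(), max_invalid = 0.3) {
  stopifnot(inherits(seq, "pose_sequence"), inherits(schema, "skeleton_schema"))
  res <- lapply(list(schema$front_triple, schema$hind_triple), function(tri) {
    h <- seq$coords[, tri[1], , drop = FALSE]; dim(h) <- c(dim(seq$coords)[1], 2L)
    k <- seq$coords[, tri[2], , drop = FALSE]; dim(k) <- c(dim(seq$coords)[1], 2L)
    a <- seq$coords[, tri[3], , drop = FALSE]; dim(a) <- c(dim(seq$coords)[1], 2L)
    ba <- bending_angle_vec(h, k, a)
    vis <- seq$visible[, tri[1]] & seq$visible[, tri[2]] & seq$visible[, tri[3]]
    valid <- ba$ok & vis
    if (mean(!valid) > max_invalid) {
      gait_error("gait_clip_unusable", sprintf(
        "clip '%s': %.0f%% of frames invalid for one leg (max %.0f%%)",
        seq$clip_id, 100 * mean(!valid), 100 * max_invalid))
    }
    ang <- ba$angle
    ang[!vis] <- NA_real_
    idx <- which(valid)
    if (length(idx) < length(ang)) {
      # linear interpolation in angle space; rule = 2 extends ends by copy
      ang <- stats::approx(idx, ang[idx], xout = seq_along(ang), rule = 2)$y
    }
    list(angle = ang, valid = valid)
  })
  structure(list(front = res[[1]]$angle, hind = res[[2]]$angle,
                 valid = res[[1]]$valid & res[[2]]$valid,
                 clip_id = seq$clip_id, fps = seq$fps, label = seq$label),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series '%s': %d frames, %d valid, front %0.1f-%0.1f deg, hind %0.1f-%0.1f deg>\n",
              x$clip_id, length(x$front), sum(x$valid),
              min(x$front), max(x$front), min(x$hind), max(x$hind)))
  invisible(x)
}
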