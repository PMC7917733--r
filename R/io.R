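# Readers and writers. Wire formats:
#   * keypoint CSV: one row per frame — clip_id, frame_idx (0-based), label
#     (optional), then x0,y0,v0 ... x17,y17,v17 (0-based landmark names);
#   * keypoint JSON mirror of the same fields;
#   * HDF5 clip bundles: datasets coords [T x 18 x 2], visible [T x 18],
#     masks [T x H x W] (optional), attributes label, fps, seed;
#   * PNG for masks, CSV for angle series and training logs, JSON for
#     configs/reports/checkpoint sidecars.

keypoint_cols <- function() {
  as.vector(t(outer(0:17, c("x", "y", "v"), function(i, p) paste0(p, i))))
}

#' Write pose sequences to keypoint CSV or JSON
#'
#' @param seqs a [pose_sequence()] or list of them.
#' @param path output path; the extension (`.csv` or `.json`) picks the
#'   format.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(seqs, path) {
  if (inherits(seqs, "pose_sequence")) seqs <- list(seqs)
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "csv") {
    rows <- lapply(seqs, function(s) {
      Tn <- dim(s$coords)[1]
      wide <- matrix(0, Tn, 54L)
      wide[, seq(1L, 54L, by = 3L)] <- s$coords[, , 1]
      wide[, seq(2L, 54L, by = 3L)] <- s$coords[, , 2]
      wide[, seq(3L, 54L, by = 3L)] <- s$visible + 0L
      # 17 significant digits so doubles survive the text round trip bitwise
      wide <- matrix(formatC(wide, format = "g", digits = 17), Tn, 54L)
      df <- data.frame(clip_id = s$clip_id, frame_idx = seq_len(Tn) - 1L,
                       label = if (is.null(s$label)) "" else s$label)
      cbind(df, stats::setNames(as.data.frame(wide), keypoint_cols()))
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  } else if (fmt == "json") {
    out <- lapply(seqs, function(s) {
      list(clip_id = s$clip_id, fps = s$fps, label = s$label,
           x = s$coords[, , 1], y = s$coords[, , 2], visible = s$visible + 0L)
    })
    jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  } else {
    gait_usage_error(sprintf("unsupported keypoint format '%s'", fmt))
  }
  invisible(path)
}

#' Read pose sequences from keypoint CSV or JSON
#'
#' Validates the 18-landmark schema and reports malformed rows with their
#' line numbers.
#'
#' @param path input `.csv` or `.json` file written by [write_keypoints()]
#'   (or any file in the same dialect).
#' @param fps frames per second to stamp on clips (CSV carries no rate).
#' @return list of [pose_sequence()] objects.
#' @export
read_keypoints <- function(path, fps = 30) {
  if (!file.exists(path)) gait_error("gait_io_error", sprintf("no such file: %s", path))
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "json") {
    clips <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(clips, function(cl) {
      # matrices are serialized row-major: rebuild as t(18 x T)
      demat <- function(m) t(matrix(unlist(m), 18L, length(m)))
      xs <- demat(cl$x); ys <- demat(cl$y)
      coords <- array(NA_real_, c(nrow(xs), 18L, 2L))
      coords[, , 1] <- xs; coords[, , 2] <- ys
      vis <- demat(cl$visible) > 0
      lab <- cl$label
      if (is.null(lab) || identical(lab, "")) lab <- NULL
      pose_sequence(cl$clip_id, coords, vis,
                    fps = if (is.null(cl$fps)) fps else cl$fps, label = lab)
    }))
  }
  if (fmt != "csv") gait_usage_error(sprintf("unsupported keypoint format '%s'", fmt))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  want <- keypoint_cols()
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0L || !all(c("clip_id", "frame_idx") %in% names(df))) {
    gait_error("gait_schema_mismatch", sprintf(
      "keypoint CSV must carry clip_id, frame_idx and 18 landmarks (x0..v17); missing: %s",
      paste(utils::head(c(setdiff(c("clip_id", "frame_idx"), names(df)), missing_cols), 5L),
            collapse = ", ")))
  }
  num <- df[want]
  bad <- which(!stats::complete.cases(vapply(num, function(cl) {
    suppressWarnings(as.numeric(cl))
  }, numeric(nrow(df)))))
  if (length(bad) > 0L) {
    gait_error("gait_parse_error", sprintf(
      "malformed keypoint rows at line(s): %s",
      paste(utils::head(bad + 1L, 10L), collapse = ", ")))  # +1 for header
  }
  lapply(split(seq_len(nrow(df)), df$clip_id), function(rows) {
    rows <- rows[order(df$frame_idx[rows])]
    Tn <- length(rows)
    wide <- unname(as.matrix(df[rows, want]))
    coords <- array(NA_real_, c(Tn, 18L, 2L))
    coords[, , 1] <- wide[, seq(1L, 54L, by = 3L)]
    coords[, , 2] <- wide[, seq(2L, 54L, by = 3L)]
    vis <- unname(wide[, seq(3L, 54L, by = 3L)] > 0)
    lab <- if ("label" %in% names(df) && nzchar(df$label[rows[1]])) df$label[rows[1]] else NULL
    pose_sequence(df$clip_id[rows[1]], coords, vis, fps = fps, label = lab)
  })
}

#' Write or read a clip bundle as HDF5
#'
#' Datasets: `coords` (T x 18 x 2), `visible` (T x 18, 0/1), `masks`
#' (T x H x W, optional); attributes on `coords`: `label`, `fps`, `seed`,
#' `clip_id`.
#'
#' @param bundle a [simulate_clip()] bundle.
#' @param path `.h5` file path (overwritten).
#' @return `path` / the reconstructed bundle.
#' @export
write_clip_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "clip_bundle"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(bundle$pose$coords, path, "coords")
  rhdf5::h5write(bundle$pose$visible + 0L, path, "visible")
  if (!is.null(bundle$masks)) {
    Tn <- length(bundle$masks)
    hw <- dim(bundle$masks[[1]])
    arr <- array(0L, c(Tn, hw[1], hw[2]))
    for (f in seq_len(Tn)) arr[f, , ] <- bundle$masks[[f]]
    rhdf5::h5write(arr, path, "masks")
  }
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  did <- rhdf5::H5Dopen(fid, "coords")
  rhdf5::h5writeAttribute(bundle$label, did, "label")
  rhdf5::h5writeAttribute(bundle$pose$fps, did, "fps")
  rhdf5::h5writeAttribute(bundle$seed, did, "seed")
  rhdf5::h5writeAttribute(bundle$pose$clip_id, did, "clip_id")
  rhdf5::H5Dclose(did)
  invisible(path)
}

#' @rdname write_clip_bundle
#' @export
read_clip_bundle <- function(path) {
  if (!file.exists(path)) gait_error("gait_io_error", sprintf("no such file: %s", path))
  coords <- rhdf5::h5read(path, "coords")
  visible <- rhdf5::h5read(path, "visible") > 0
  contents <- rhdf5::h5ls(path)$name
  masks <- NULL
  if ("masks" %in% contents) {
    arr <- rhdf5::h5read(path, "masks")
    masks <- lapply(seq_len(dim(arr)[1]), function(f) matrix(arr[f, , ], dim(arr)[2], dim(arr)[3]))
  }
  at <- rhdf5::h5readAttributes(path, "coords")
  pose <- pose_sequence(as.character(at$clip_id), coords, visible,
                        fps = as.numeric(at$fps), label = as.character(at$label))
  structure(list(pose = pose, masks = masks, label = as.character(at$label),
                 seed = as.integer(at$seed)),
            class = "clip_bundle")
}

#' PNG mask I/O
#'
#' Masks are stored as 8-bit grayscale PNG; reading thresholds at 0.5.
#'
#' @param mask 0/1 matrix.
#' @param path `.png` file path.
#' @return `path` / the 0/1 integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / max(1, max(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) gait_error("gait_io_error", sprintf("no such file: %s", path))
  im <- png::readPNG(path)
  if (length(dim(im)) == 3L) im <- im[, , 1]
  matrix(as.integer(im > 0.5), nrow(im), ncol(im))
}

#' Angle series CSV I/O
#'
#' Columns: clip_id, frame_idx (0-based), front_deg, hind_deg, valid.
#'
#' @param series an [angle_series()] or list of them.
#' @param path `.csv` file path.
#' @return `path` / list of `angle_series` objects.
#' @export
write_angle_series <- function(series, path) {
  if (inherits(series, "angle_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(clip_id = s$clip_id, frame_idx = seq_along(s$front) - 1L,
               front_deg = s$front, hind_deg = s$hind, valid = s$valid + 0L,
               label = if (is.null(s$label)) "" else s$label)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angle_series
#' @export
read_angle_series <- function(path) {
  if (!file.exists(path)) gait_error("gait_io_error", sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  lapply(split(df, df$clip_id), function(d) {
    d <- d[order(d$frame_idx), ]
    lab <- if ("label" %in% names(d) && nzchar(d$label[1])) d$label[1] else NULL
    structure(list(front = d$front_deg, hind = d$hind_deg, valid = d$valid > 0,
                   clip_id = d$clip_id[1], fps = 30, label = lab),
              class = "angle_series")
  })
}

#' Model checkpoint I/O
#'
#' Weights are serialized with `saveRDS`; a JSON sidecar (`<path>.json`)
#' records the architecture configuration, seed and training
#' hyperparameters.
#'
#' @param model a fitted `tiny_vgg` or `lstm_model`.
#' @param path checkpoint path (e.g. `model.rds`).
#' @return `path` / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tiny_vgg") || inherits(model, "lstm_model"))
  saveRDS(model, path)
  sidecar <- list(class = class(model)[1],
                  config = unclass(model$config),
                  seed = model$seed, hyper = model$hyper,
                  classes = model$classes,
                  package_version = as.character(utils::packageVersion("gaitstream")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) gait_error("gait_io_error", sprintf("no such file: %s", path))
  readRDS(path)
}
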