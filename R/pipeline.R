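# End-to-end two-stream pipeline over clip bundles: train both streams,
# select the fusion weight, evaluate.

bundle_labels <- function(bundles) vapply(bundles, function(b) b$label, "")

#' Outline rasters for a set of clip bundles
#'
#' Picks `frames_per_clip` evenly spaced frames from each clip, renders the
#' silhouette for frames without a stored mask, extracts the outline and
#' rasterizes it to the network input size.
#'
#' @param bundles list of [simulate_clip()] bundles.
#' @param frames_per_clip frames sampled per clip (evenly spaced).
#' @param out_size network input side length.
#' @param fill rasterize filled silhouettes instead of hollow contours.
#' @param limb_width renderer limb width for bundles without stored masks.
#' @return list with `images` (list of rasters), `labels` (character, one
#'   per image), and `clip` (integer clip index per image).
#' @export
outline_frames <- function(bundles, frames_per_clip = 1L, out_size = 112L,
                           fill = FALSE, limb_width = 4) {
  images <- list(); labels <- character(); clip <- integer()
  for (ci in seq_along(bundles)) {
    b <- bundles[[ci]]
    Tn <- dim(b$pose$coords)[1]
    idx <- unique(round(seq(1, Tn, length.out = frames_per_clip + 2L)[
      seq_len(frames_per_clip) + 1L]))
    for (f in idx) {
      mask <- if (!is.null(b$masks)) b$masks[[f]] else
        render_silhouette(matrix(b$pose$coords[f, , ], 18L, 2L),
                          b$pose$visible[f, ], limb_width = limb_width,
                          canvas = c(out_size, out_size), autoscale = FALSE)
      poly <- extract_outline(mask)
      images[[length(images) + 1L]] <-
        rasterize_outline(poly, dim(mask), out_size = out_size, fill = fill)
      labels <- c(labels, b$label)
      clip <- c(clip, ci)
    }
  }
  list(images = images, labels = labels, clip = clip)
}

#' Clip-level scores from each stream for a set of bundles
#'
#' @param model fitted `tiny_vgg` / `lstm_model`.
#' @param bundles list of clip bundles.
#' @inheritParams outline_frames
#' @return `n_clips x 3` probability matrix.
#' @export
predict_outline_bundles <- function(model, bundles, frames_per_clip = 1L,
                                    fill = FALSE, limb_width = 4) {
  fr <- outline_frames(bundles, frames_per_clip,
                       out_size = model$config$input_size, fill = fill,
                       limb_width = limb_width)
  scores <- predict(model, fr$images)
  t(vapply(seq_along(bundles), function(ci) {
    colMeans(scores[fr$clip == ci, , drop = FALSE])
  }, numeric(ncol(scores))))
}

#' @rdname predict_outline_bundles
#' @param schema skeleton schema for angle extraction.
#' @export
predict_skeleton_bundles <- function(model, bundles, schema = skeleton_schema()) {
  t(vapply(bundles, function(b) {
    predict_skeleton_clip(model, angle_series(b$pose, schema))
  }, numeric(model$config$n_classes)))
}

#' Train and evaluate the full two-stream recognizer
#'
#' Trains the skeleton LSTM on windowed bending-angle series and the Tiny VGG
#' on outline rasters of the same training clips, selects the fusion weight
#' by validation grid search, and reports per-class accuracy and confusion
#' matrices for the outline-only, skeleton-only and fused recognizers on the
#' held-out test clips.
#'
#' @param train,test lists of labelled clip bundles
#'   (see [make_gait_dataset()]).
#' @param lstm_cfg,vgg_cfg stream configurations.
#' @param skeleton_epochs,outline_epochs,skeleton_lr,outline_lr training
#'   hyperparameters per stream.
#' @param frames_per_clip outline frames sampled per clip.
#' @param val_frac fraction of training clips (stratified, deterministic)
#'   used as the validation set for fusion-weight selection.
#' @param grid candidate fusion weights.
#' @param seed seed for both stream fits.
#' @param fill use filled silhouettes rather than hollow outlines.
#' @param verbose print training progress.
#' @return list with `outline_model`, `skeleton_model`, `weight`, and
#'   `reports` (eval_report objects `outline`, `skeleton`, `fused`).
#' @export
two_stream_pipeline <- function(train, test,
                                lstm_cfg = lstm_config(),
                                vgg_cfg = tiny_vgg_config(),
                                skeleton_epochs = 150L, outline_epochs = 5L,
                                skeleton_lr = 0.01, outline_lr = 0.01,
                                frames_per_clip = 1L, val_frac = 0.2,
                                grid = seq(0.1, 0.9, by = 0.1),
                                seed = 0L, fill = FALSE, verbose = FALSE) {
  # temporal stream
  train_samples <- unlist(lapply(train, function(b) {
    prepare_sequences(angle_series(b$pose), lstm_cfg)
  }), recursive = FALSE)
  skeleton_model <- fit_lstm(train_samples, lstm_cfg, epochs = skeleton_epochs,
                             lr = skeleton_lr, seed = seed, verbose = verbose)
  # spatial stream
  fr <- outline_frames(train, frames_per_clip,
                       out_size = vgg_cfg$input_size, fill = fill)
  outline_model <- fit_tiny_vgg(fr$images, fr$labels, vgg_cfg,
                                epochs = outline_epochs, lr = outline_lr,
                                seed = seed, verbose = verbose)
  # fusion weight on a stratified validation subset of the training clips
  lab_train <- bundle_labels(train)
  val_idx <- unlist(lapply(action_levels(), function(lv) {
    ix <- which(lab_train == lv)
    utils::tail(ix, max(1L, ceiling(val_frac * length(ix))))
  }))
  yp_val <- predict_outline_bundles(outline_model, train[val_idx],
                                    frames_per_clip, fill = fill)
  ys_val <- predict_skeleton_bundles(skeleton_model, train[val_idx])
  weight <- select_fusion_weight(yp_val, ys_val, lab_train[val_idx], grid)
  # test-set evaluation
  yp <- predict_outline_bundles(outline_model, test, frames_per_clip, fill = fill)
  ys <- predict_skeleton_bundles(skeleton_model, test)
  lab_test <- bundle_labels(test)
  reports <- list(outline = evaluate_predictions(yp, lab_test),
                  skeleton = evaluate_predictions(ys, lab_test),
                  fused = evaluate_predictions(fuse_scores(yp, ys, weight), lab_test))
  list(outline_model = outline_model, skeleton_model = skeleton_model,
       weight = weight, scores = list(outline = yp, skeleton = ys),
       reports = reports)
}
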