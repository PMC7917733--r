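# Score fusion and the evaluation surface (per-class accuracy, confusion
# matrix).

check_score_vector <- function(p, what = "score vector") {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p)) ||
      any(p < -1e-9) || any(p > 1 + 1e-9) || abs(sum(p) - 1) > 1e-6) {
    gait_error("gait_bad_score", sprintf(
      "%s must be 3 probabilities in [0, 1] summing to 1", what))
  }
  invisible(p)
}

#' Fuse the two stream scores
#'
#' Weighted average `y = w * yp + (1 - w) * ys` of the outline-stream score
#' `yp` and skeleton-stream score `ys`, with the relative weight `w` in the
#' open interval (0, 1). The output is a convex combination, hence again a
#' probability vector.
#'
#' @param yp,ys probability vectors of length 3 (or `n x 3` matrices of
#'   clip scores, fused row-wise).
#' @param w fusion weight in (0, 1); the outline stream's share.
#' @return fused scores with the same shape as the inputs.
#' @export
fuse_scores <- function(yp, ys, w) {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0 || w >= 1) {
    gait_error("gait_weight_range", "fusion weight must lie in the open interval (0, 1)")
  }
  if (is.matrix(yp) || is.matrix(ys)) {
    stopifnot(is.matrix(yp), is.matrix(ys), all(dim(yp) == dim(ys)))
    apply(yp, 1L, check_score_vector); apply(ys, 1L, check_score_vector)
  } else {
    check_score_vector(yp, "yp"); check_score_vector(ys, "ys")
  }
  w * yp + (1 - w) * ys
}

#' Select the fusion weight on a validation set
#'
#' Grid search: for every candidate weight, fuse the paired stream scores and
#' compute the average per-class accuracy; the maximizing weight is returned,
#' with ties broken toward 0.5 (then toward the smaller weight).
#'
#' @param yp,ys `n x 3` matrices of paired validation scores from the outline
#'   and skeleton streams.
#' @param labels true action labels, length n.
#' @param grid candidate weights, all inside (0, 1).
#' @return the selected weight (numeric scalar).
#' @export
select_fusion_weight <- function(yp, ys, labels,
                                 grid = seq(0.1, 0.9, by = 0.1)) {
  if (length(grid) == 0L) gait_error("gait_empty_grid", "weight grid is empty")
  if (any(grid <= 0 | grid >= 1)) {
    gait_error("gait_weight_range", "all grid weights must be in (0, 1)")
  }
  if (nrow(yp) == 0L) gait_error("gait_bad_param", "validation set is empty")
  acc <- vapply(grid, function(w) {
    evaluate_predictions(fuse_scores(yp, ys, w), labels)$average_accuracy
  }, 0)
  best <- which(acc > max(acc) - 1e-12)
  best <- best[order(abs(grid[best] - 0.5), grid[best])][1]
  grid[best]
}

#' Evaluate clip-level predictions
#'
#' Decision rule: argmax of the score vector, ties broken toward the lowest
#' class index. `confusion[i, j]` counts clips of true class i predicted as
#' class j; per-class accuracy is the diagonal over the row sum, and the
#' average accuracy is the unweighted mean over classes (equal to overall
#' accuracy when classes are balanced).
#'
#' @param scores `n x 3` matrix of class scores (rows sum to 1).
#' @param labels true action labels, length n.
#' @return an object of class `eval_report`: list with `confusion` (3 x 3),
#'   `per_class_accuracy`, `average_accuracy`, `n_clips`.
#' @export
evaluate_predictions <- function(scores, labels) {
  if (is.numeric(scores) && is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  labels <- action_factor(labels)
  if (nrow(scores) != length(labels)) {
    gait_error("gait_length_mismatch", "scores and labels differ in length")
  }
  pred <- max.col(scores, ties.method = "first")
  lv <- action_levels()
  confusion <- table(factor(lv[as.integer(labels)], levels = lv),
                     factor(lv[pred], levels = lv))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  rs <- rowSums(confusion)
  per_class <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  structure(list(confusion = confusion,
                 per_class_accuracy = per_class,
                 average_accuracy = mean(per_class, na.rm = TRUE),
                 n_clips = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d clips\n", x$n_clips))
  print(x$confusion)
  acc <- sprintf("%s: %.1f%%", names(x$per_class_accuracy),
                 100 * x$per_class_accuracy)
  cat("Per-class accuracy:", paste(acc, collapse = ", "), "\n")
  cat(sprintf("Average accuracy: %.1f%%\n", 100 * x$average_accuracy))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [evaluate_predictions()] report.
#' @param path output file path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(confusion = lapply(seq_len(nrow(report$confusion)),
                                 function(i) unname(report$confusion[i, ])),
              classes = action_levels(),
              per_class_accuracy = as.list(report$per_class_accuracy),
              average_accuracy = report$average_accuracy,
              n_clips = report$n_clips)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
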