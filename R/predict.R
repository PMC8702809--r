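#' Segment a full fundus image
#'
#' Runs the complete inference chain: preprocessing, padding, 64x64 patch
#' extraction at step 16, batched network forward (main output only; the
#' supervision heads are a training aid), overlap-averaged stitching, crop
#' back to the original size, and thresholding.
#'
#' @param model a `retseg_model` or path to a checkpoint file.
#' @param img a [fundus_image()] (preprocessed internally) or a numeric
#'   matrix in `[0, 1]` treated as already preprocessed.
#' @param threshold binarization threshold on the stitched probabilities.
#' @param step sliding step at inference (default 16, the training grid).
#' @param batch_patches patches per forward batch.
#' @return List with `prob` (probability matrix in `[0,1]`, original size)
#'   and `seg` (binary matrix).
#' @export
predict_image <- function(model, img, threshold = 0.5, step = 16L,
                          batch_patches = 64L) {
  if (is.character(model)) model <- load_checkpoint(model)
  window <- model$spec$window
  pre <- if (inherits(img, "fundus_image")) preprocess_fundus(img)$values
         else if (inherits(img, "gray_image")) {
           if (img$convention == "integer") img$values / (img$L - 1) else img$values
         } else img
  ps <- extract_patches(pre, window = window, step = step)
  n <- dim(ps$inputs)[3]
  probs <- array(0, c(window, window, n))
  for (b0 in seq(1L, n, by = batch_patches)) {
    idx <- b0:min(b0 + batch_patches - 1L, n)
    x <- array(ps$inputs[, , idx], c(window, window, 1L, length(idx)))
    out <- model_forward(model, x, training = FALSE)
    probs[, , idx] <- out$main[, , 1L, ]
  }
  prob <- stitch_predictions(probs, ps$grid, ps$original_shape)
  list(prob = prob, seg = (prob >= threshold) + 0)
}

#' Evaluate a model over a dataset directory
#'
#' Expects the layout written by [generate_dataset()]: `images/`, `truths/`
#' and optionally `masks/`, with files pairing up after sorting. Metrics are
#' computed inside the FOV mask (estimated when absent), the field's
#' convention, since background pixels would trivially inflate accuracy and
#' specificity.
#'
#' @param model a `retseg_model` or checkpoint path.
#' @param dir dataset directory.
#' @param threshold binarization threshold.
#' @param report_path optional path (`.json` or `.csv`) for the report.
#' @return An object of class `eval_report`: `per_image` data frame with
#'   confusion counts and Acc/Se/Sp/AUC per image, and `means`.
#' @export
evaluate_dataset <- function(model, dir, threshold = 0.5, report_path = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  trus <- sort(list.files(file.path(dir, "truths"), full.names = TRUE))
  msks <- sort(list.files(file.path(dir, "masks"), full.names = TRUE))
  if (length(imgs) == 0 || length(trus) != length(imgs))
    stop_retseg("dataset must provide one truth per image", "retseg_data_error")
  rows <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    fi <- read_fundus(imgs[i],
                      mask_path = if (length(msks) == length(imgs)) msks[i] else NULL,
                      truth_path = trus[i])
    mask <- estimate_fov_mask(fi)
    pr <- predict_image(model, fi, threshold = threshold)
    cc <- confusion_counts(pr$seg, fi$truth, mask)
    met <- acc_se_sp(cc)
    auc <- roc_auc(pr$prob, fi$truth, mask)$auc
    rows[[i]] <- data.frame(image = basename(imgs[i]), tp = cc$tp, tn = cc$tn,
                            fp = cc$fp, fn = cc$fn, accuracy = met$accuracy,
                            sensitivity = met$sensitivity,
                            specificity = met$specificity, auc = auc)
  }
  per_image <- do.call(rbind, rows)
  means <- list(accuracy = mean(per_image$accuracy),
                sensitivity = mean(per_image$sensitivity),
                specificity = mean(per_image$specificity),
                auc = mean(per_image$auc))
  rep <- structure(list(per_image = per_image, means = means,
                        threshold = threshold), class = "eval_report")
  if (!is.null(report_path)) write_eval_report(rep, report_path)
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %d images, mean Acc %.4f Se %.4f Sp %.4f AUC %.4f>\n",
              nrow(x$per_image), x$means$accuracy, x$means$sensitivity,
              x$means$specificity, x$means$auc))
  invisible(x)
}

#' Write an evaluation report to JSON or CSV
#'
#' @param report an `eval_report`.
#' @param path output path ending in `.json` or `.csv`.
#' @export
write_eval_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_image = report$per_image,
                              means = report$means,
                              threshold = report$threshold),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report$per_image, path, row.names = FALSE)
  }
  invisible(path)
}
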