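#' Class balance of a binary target
#'
#' Vessel pixels are a small minority of a fundus patch, so the training loss
#' weights the two classes by their frequencies: `alpha = X- / m` (background
#' fraction) multiplies the vessel term and `1 - alpha = X+ / m` the
#' background term.
#'
#' @param y binary array or vector of targets.
#' @return List with `m` (total pixels), `x_plus` (vessel count), `x_minus`
#'   (background count) and `alpha`.
#' @export
class_balance <- function(y) {
  if (!is_binary(y)) stop_retseg("targets must be binary", "retseg_range_error")
  m <- length(y)
  xp <- sum(y)
  list(m = m, x_plus = xp, x_minus = m - xp, alpha = (m - xp) / m)
}

#' Class-weighted binary cross-entropy
#'
#' `-(1/m) * sum(alpha * y * log(p) + (1 - alpha) * (1 - y) * log(1 - p))`
#' with natural logarithms, `p` the predictions clamped to
#' `[eps, 1 - eps]`, and `alpha` the background fraction of `y` (see
#' [class_balance()]). Zero only in the perfect-prediction limit.
#'
#' @param y binary target array.
#' @param yhat prediction array with values in `(0, 1)`, same shape as `y`.
#' @param balance optional precomputed [class_balance()]; defaults to the
#'   balance of `y`.
#' @param eps clamping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
weighted_bce <- function(y, yhat, balance = NULL, eps = 1e-7) {
  if (!identical(dim2(y), dim2(yhat)))
    stop_retseg("target and prediction shapes must match", "retseg_shape_error")
  if (is.null(balance)) balance <- class_balance(y)
  p <- clamp(yhat, eps, 1 - eps)
  a <- balance$alpha
  -(1 / balance$m) * sum(a * y * log(p) + (1 - a) * (1 - y) * log(1 - p))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Deep-supervision loss schedule
#'
#' The auxiliary heads' weight decays linearly over training:
#' `beta = 1 - epoch / total_epochs`, from 1 at epoch 0 to 0 at the final
#' epoch.
#'
#' @param epoch current iteration index (0-based).
#' @param total_epochs total number of iterations (default 500).
#' @return An object of class `loss_schedule`.
#' @export
loss_schedule <- function(epoch, total_epochs = 500L) {
  if (epoch < 0 || epoch > total_epochs)
    stop_retseg("epoch must lie in [0, total_epochs]", "retseg_parameter_error")
  structure(list(epoch = epoch, total_epochs = total_epochs,
                 beta = 1 - epoch / total_epochs), class = "loss_schedule")
}

#' @rdname loss_schedule
#' @param sched a `loss_schedule`.
#' @export
beta_weight <- function(sched) sched$beta

#' Combine supervision and main losses
#'
#' Default mode: `beta * (l1 + l2 + l3) + l4`, so the auxiliary supervision
#' fades out while the main-output loss always trains. `"strict"` mode
#' multiplies all four components by `beta` (the literal printed formula;
#' it drives the total to zero at the final epoch).
#'
#' @param l1,l2,l3 deep-supervision losses (non-negative).
#' @param l4 main-output loss (non-negative).
#' @param beta schedule weight in `[0, 1]`.
#' @param mode `"default"` or `"strict"`.
#' @return Scalar total loss.
#' @export
total_loss <- function(l1, l2, l3, l4, beta, mode = c("default", "strict")) {
  mode <- match.arg(mode)
  if (any(c(l1, l2, l3, l4) < 0))
    stop_retseg("loss components must be non-negative", "retseg_domain_error")
  if (mode == "default") beta * (l1 + l2 + l3) + l4
  else beta * (l1 + l2 + l3 + l4)
}

#' Pixel confusion counts within a mask
#'
#' @param pred binary prediction image.
#' @param truth binary reference image.
#' @param mask binary evaluation mask (typically the FOV); only `mask == 1`
#'   pixels are counted.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim2(pred))
  if (!identical(dim2(pred), dim2(truth)) || !identical(dim2(pred), dim2(mask)))
    stop_retseg("pred/truth/mask shapes must match", "retseg_shape_error")
  sel <- mask == 1
  if (!any(sel)) stop_retseg("empty evaluation mask", "retseg_degenerate_error")
  p <- pred[sel]; t <- truth[sel]
  structure(list(tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
                 fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity
#'
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`.
#' A metric whose denominator is zero is reported as `NA` (absent), never 0.
#'
#' @param cc a [confusion_counts()].
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
acc_se_sp <- function(cc) {
  tot <- cc$tp + cc$tn + cc$fp + cc$fn
  list(
    accuracy = if (tot > 0) (cc$tp + cc$tn) / tot else NA_real_,
    sensitivity = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_,
    specificity = if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold, plotting true-positive rate
#' (sensitivity) against false-positive rate (1 - specificity), and
#' integrates the curve with the trapezoidal rule. The result equals the
#' pairwise concordance statistic with ties counted as one half.
#'
#' @param scores numeric probability image or vector.
#' @param truth binary reference of the same shape.
#' @param mask optional binary evaluation mask.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim2(scores))
  sel <- mask == 1
  s <- scores[sel]; y <- truth[sel]
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0)
    stop_retseg("both classes must be present for a ROC curve", "retseg_degenerate_error")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  # group tied scores: each distinct value is one threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  tpr <- c(0, tp / P, 1)
  fpr <- c(0, fp / N, 1)
  thr <- c(Inf, s[last], -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
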