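#' Sliding-window patch grid
#'
#' Enumerates all top-left origins of a `window x window` sliding window at
#' the given step over a padded image, left to right then top to bottom.
#' Origins are 1-based.
#'
#' @param padded_shape integer vector `(height, width)`; both must close the
#'   grid exactly: `(dim - window) %% step == 0`.
#' @param window window side length (default 64).
#' @param step slide step in pixels (default 16); must satisfy
#'   `1 <= step <= window` so no pixel is skipped.
#' @return An object of class `patch_grid` with fields `window`, `step`,
#'   `padded_shape` and `origins` (an `n x 2` matrix of `(row, col)`).
#' @export
patch_grid <- function(padded_shape, window = 64L, step = 16L) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || step > window)
    stop_retseg("step must satisfy 1 <= step <= window", "retseg_parameter_error")
  H <- padded_shape[1]; W <- padded_shape[2]
  if (window > min(H, W))
    stop_retseg("window larger than image", "retseg_parameter_error")
  if ((H - window) %% step != 0L || (W - window) %% step != 0L)
    stop_retseg("grid does not close: (dim - window) must be a multiple of step",
                "retseg_grid_error")
  rows <- seq(1L, H - window + 1L, by = step)
  cols <- seq(1L, W - window + 1L, by = step)
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  structure(list(window = window, step = step,
                 padded_shape = c(H, W), origins = origins),
            class = "patch_grid")
}

#' Number of patches a grid yields
#'
#' `((H - window)/step + 1) * ((W - window)/step + 1)` for a closed grid.
#'
#' @inheritParams patch_grid
#' @return Integer patch count.
#' @export
patch_count <- function(padded_shape, window = 64L, step = 16L) {
  H <- padded_shape[1]; W <- padded_shape[2]
  as.integer(((H - window) / step + 1) * ((W - window) / step + 1))
}

#' Pad an image so the sliding-window grid closes
#'
#' Appends zero-valued rows/columns at the bottom and right so that both
#' dimensions become multiples of `multiple` and, additionally,
#' `(dim - window) %% step == 0` so the window grid covers the image exactly.
#' With the defaults (multiple 64, window 64, step 16) the second condition
#' is implied by the first.
#'
#' @param g a [gray_image()] or plain matrix.
#' @param multiple pad target (default 64).
#' @param window,step grid parameters used for the closing condition.
#' @return List with `image` (padded, same convention) and `grid`
#'   (a [patch_grid()]).
#' @export
pad_to_multiple <- function(g, multiple = 64L, window = 64L, step = 16L) {
  if (multiple < 1L) stop_retseg("multiple must be >= 1", "retseg_parameter_error")
  m <- if (inherits(g, "gray_image")) g$values else g
  target <- function(d) {
    D <- max(as.integer(ceiling(d / multiple) * multiple), window)
    while ((D - window) %% step != 0L || D %% multiple != 0L) D <- D + multiple
    D
  }
  Hp <- target(nrow(m)); Wp <- target(ncol(m))
  out <- matrix(0, Hp, Wp)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  img <- if (inherits(g, "gray_image")) gray_image(out, g$convention, g$L) else out
  list(image = img, grid = patch_grid(c(Hp, Wp), window, step))
}

#' Extract sliding-window patches (and matching label patches)
#'
#' Pads the image with zeros so the grid closes, then cuts every
#' `window x window` patch at the given step, top-left first, rows before
#' columns. Twenty 584x584 images yield 27,380 patches (1,369 each); ten
#' 605x700 images yield 15,170 (1,517 each).
#'
#' @param g a [gray_image()] or matrix.
#' @param truth optional binary matrix of the same (unpadded) shape.
#' @param window,step grid parameters.
#' @param source_id identifier carried along for stitching/bookkeeping.
#' @return An object of class `patch_set`: `inputs` (`window x window x n`
#'   array), `labels` (same, or `NULL`), `grid`, `original_shape`,
#'   `source_id`.
#' @export
extract_patches <- function(g, truth = NULL, window = 64L, step = 16L,
                            source_id = "image") {
  m <- if (inherits(g, "gray_image")) g$values else g
  orig <- dim(m)
  padded <- pad_to_multiple(m, multiple = window, window = window, step = step)
  grid <- padded$grid
  mp <- padded$image
  tp <- NULL
  if (!is.null(truth)) {
    if (!identical(dim(truth), orig))
      stop_retseg("truth shape must match the image", "retseg_shape_error")
    tp <- matrix(0, nrow(mp), ncol(mp))
    tp[seq_len(orig[1]), seq_len(orig[2])] <- truth
  }
  n <- nrow(grid$origins)
  w <- grid$window
  inputs <- array(0, c(w, w, n))
  labels <- if (!is.null(tp)) array(0, c(w, w, n)) else NULL
  for (i in seq_len(n)) {
    r <- grid$origins[i, 1]; cc <- grid$origins[i, 2]
    inputs[, , i] <- mp[r:(r + w - 1L), cc:(cc + w - 1L)]
    if (!is.null(tp)) labels[, , i] <- tp[r:(r + w - 1L), cc:(cc + w - 1L)]
  }
  structure(list(inputs = inputs, labels = labels, grid = grid,
                 original_shape = orig, source_id = source_id),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set %d patches of %d x %d (step %d) from '%s'%s>\n",
              dim(x$inputs)[3], x$grid$window, x$grid$window, x$grid$step,
              x$source_id, if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

# bilinear resize of a matrix to out_h x out_w (used by the crop augmentation)
bilinear_resize <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  if (H == out_h && W == out_w) return(m)
  ys <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  y0 <- clamp(floor(ys), 1, H); y1 <- clamp(y0 + 1, 1, H)
  x0 <- clamp(floor(xs), 1, W); x1 <- clamp(x0 + 1, 1, W)
  wy <- clamp(ys - y0, 0, 1); wx <- clamp(xs - x0, 0, 1)
  a <- m[y0, x0, drop = FALSE] * ((1 - wy) %o% (1 - wx)) +
       m[y1, x0, drop = FALSE] * (wy %o% (1 - wx)) +
       m[y0, x1, drop = FALSE] * ((1 - wy) %o% wx) +
       m[y1, x1, drop = FALSE] * (wy %o% wx)
  a
}

rot90k <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE][, , drop = FALSE]
  m
}

#' Randomly augment one input/label patch pair
#'
#' Applies, with seeded randomness, an independent 50% horizontal flip, 50%
#' vertical flip, a rotation by a random multiple of 90 degrees, and a random
#' crop (side fraction at least `crop_min_frac`) resized back to the window
#' size. The same geometric transform hits the input and the label; the label
#' is re-binarized after interpolation.
#'
#' @param patch numeric `window x window` matrix.
#' @param label binary matrix of the same shape.
#' @param seed integer; the same seed reproduces the same pair.
#' @param crop_min_frac minimum crop side as a fraction of the window.
#' @param flip,rot90,crop logical toggles for the individual transforms.
#' @return List with elements `patch` and `label`.
#' @export
augment_patch <- function(patch, label, seed, crop_min_frac = 0.8,
                          flip = TRUE, rot90 = TRUE, crop = TRUE) {
  if (!identical(dim(patch), dim(label)))
    stop_retseg("patch and label shapes must match", "retseg_shape_error")
  w <- nrow(patch)
  with_local_seed(seed, {
    if (flip && runif(1) < 0.5) { patch <- patch[w:1, ]; label <- label[w:1, ] }
    if (flip && runif(1) < 0.5) { patch <- patch[, w:1]; label <- label[, w:1] }
    if (rot90) {
      k <- sample(0:3, 1)
      patch <- rot90k(patch, k); label <- rot90k(label, k)
    }
    if (crop) {
      frac <- runif(1, crop_min_frac, 1)
      s <- max(8L, round(frac * w))
      if (s < w) {
        r0 <- sample.int(w - s + 1L, 1L)
        c0 <- sample.int(w - s + 1L, 1L)
        patch <- bilinear_resize(patch[r0:(r0 + s - 1L), c0:(c0 + s - 1L)], w, w)
        label <- (bilinear_resize(label[r0:(r0 + s - 1L), c0:(c0 + s - 1L)], w, w) >= 0.5) + 0
      }
    }
  })
  list(patch = patch, label = label)
}

#' Stitch patch predictions back into a full-resolution probability map
#'
#' Each output pixel is the mean of all patch predictions covering it
#' (overlap averaging suppresses patch-border seams); the zero padding is
#' then cropped away.
#'
#' @param patch_probs `window x window x n` array (or list of matrices) of
#'   per-patch probabilities in `[0,1]`.
#' @param grid the [patch_grid()] the patches were cut with.
#' @param original_shape `(height, width)` of the unpadded image.
#' @return Probability matrix of size `original_shape` with values in `[0,1]`.
#' @export
stitch_predictions <- function(patch_probs, grid, original_shape) {
  if (is.list(patch_probs))
    patch_probs <- array(unlist(patch_probs),
                         c(grid$window, grid$window, length(patch_probs)))
  n <- dim(patch_probs)[3]
  if (n != nrow(grid$origins))
    stop_retseg("patch count does not match the grid", "retseg_grid_error")
  if (!all(dim(patch_probs)[1:2] == grid$window))
    stop_retseg("patch size does not match the grid", "retseg_grid_error")
  H <- grid$padded_shape[1]; W <- grid$padded_shape[2]
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  w <- grid$window
  for (i in seq_len(n)) {
    r <- grid$origins[i, 1]; cc <- grid$origins[i, 2]
    rs <- r:(r + w - 1L); cs <- cc:(cc + w - 1L)
    acc[rs, cs] <- acc[rs, cs] + patch_probs[, , i]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  out <- acc / pmax(cnt, 1)
  out[seq_len(original_shape[1]), seq_len(original_shape[2]), drop = FALSE]
}
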