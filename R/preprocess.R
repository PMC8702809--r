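#' Extract the green channel of a fundus image
#'
#' Fundus vessels show the strongest contrast in the green channel, which is
#' used as the single-channel input for all later stages; the red and blue
#' channels are discarded. No rescaling is applied.
#'
#' @param img a [fundus_image()].
#' @return An integer-convention [gray_image()] with `L = 256`.
#' @export
extract_green_channel <- function(img) {
  if (!inherits(img, "fundus_image")) {
    d <- dim(img)
    if (is.null(d) || length(d) != 3L || d[3] != 3L)
      stop_retseg("input must have exactly three channels", "retseg_channel_error")
    img <- fundus_image(img)
  }
  gray_image(img$pixels[, , 2], "integer", 256L)
}

#' Estimate or pass through the field-of-view mask
#'
#' If the image carries a mask (as the DRIVE release does) it is returned
#' unchanged. Otherwise the eyeball disc is estimated by Otsu thresholding of
#' the mean channel, keeping the largest connected component and filling its
#' holes (the STARE release ships no masks).
#'
#' @param img a [fundus_image()].
#' @return Binary matrix, 1 inside the field of view.
#' @export
estimate_fov_mask <- function(img) {
  if (!is.null(img$fov_mask)) return(img$fov_mask)
  avg <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3 / 255
  th <- tryCatch(EBImage::otsu(EBImage::Image(avg), range = c(0, 1)),
                 error = function(e) NA_real_)
  # half the Otsu cut keeps the shaded disc rim and dark vessels with the
  # eyeball while still excluding the near-black camera background
  bw <- if (is.na(th)) avg > 0 else avg > th / 2
  if (!any(bw)) stop_retseg("no foreground found: degenerate image", "retseg_degenerate_error")
  lab <- EBImage::bwlabel(EBImage::Image(bw + 0))
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(tab)
  mask <- EBImage::fillHull(EBImage::Image((lab == keep) + 0))
  mask <- EBImage::closing(mask, EBImage::makeBrush(7L, "disc"))
  mask <- EBImage::fillHull(mask)
  mask <- matrix(as.numeric(mask > 0), nrow(avg), ncol(avg))
  if (!any(mask == 1)) stop_retseg("empty mask: degenerate image", "retseg_degenerate_error")
  mask
}

#' Gaussian denoising
#'
#' Smooths an integer-convention gray image with a normalized Gaussian kernel
#' using reflective borders, then rounds back to integer levels. The default
#' 3x3, sigma 1 kernel is the smallest standard choice and preserves thin
#' vessels.
#'
#' @param g integer-convention [gray_image()].
#' @param kernel odd kernel side length.
#' @param sigma Gaussian standard deviation in pixels; must be positive.
#' @return Smoothed integer-convention [gray_image()].
#' @export
gaussian_denoise <- function(g, kernel = 3L, sigma = 1.0) {
  if (sigma <= 0) stop_retseg("sigma must be positive", "retseg_parameter_error")
  if (kernel < 1L || kernel %% 2L == 0L)
    stop_retseg("kernel must be a positive odd integer", "retseg_parameter_error")
  if (g$convention != "integer")
    stop_retseg("gaussian_denoise expects an integer-convention image", "retseg_parameter_error")
  r <- (kernel - 1L) / 2L
  ax <- seq(-r, r)
  k1 <- exp(-ax^2 / (2 * sigma^2))
  K <- outer(k1, k1)
  K <- K / sum(K)
  v <- g$values
  H <- nrow(v); W <- ncol(v)
  # reflective padding (edge rows/cols mirrored without repeating the edge
  # when possible; for r >= dim fall back to clamping)
  refl <- function(n, r) {
    idx <- c(rev(seq_len(min(r, n - 1)) + 1), seq_len(n),
             n - seq_len(min(r, n - 1)))
    idx <- clamp(idx, 1, n)
    if (length(idx) < n + 2 * r) idx <- clamp(c(rep(1, n + 2 * r - length(idx)), idx), 1, n)
    idx
  }
  vp <- v[refl(H, r), refl(W, r), drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(kernel)) {
    for (j in seq_len(kernel)) {
      out <- out + K[i, j] * vp[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
    }
  }
  gray_image(clamp(round_half_up(out), 0, g$L - 1), "integer", g$L)
}

#' Gray-level histogram over masked pixels
#'
#' Counts pixels at each gray level `0..L-1`, restricted to `mask == 1`.
#'
#' @param g integer-convention [gray_image()].
#' @param mask binary matrix of matching shape.
#' @return An object of class `gray_histogram` with fields `counts` (length
#'   `L`), `n` (masked pixel total) and `p` (relative frequencies).
#' @export
compute_histogram <- function(g, mask = NULL) {
  if (g$convention != "integer")
    stop_retseg("histograms are defined on integer-convention images", "retseg_parameter_error")
  if (is.null(mask)) mask <- matrix(1, nrow(g$values), ncol(g$values))
  if (!identical(dim(mask), dim(g$values)))
    stop_retseg("mask shape must match the image", "retseg_shape_error")
  vals <- g$values[mask == 1]
  if (length(vals) == 0)
    stop_retseg("empty mask: degenerate image", "retseg_degenerate_error")
  counts <- tabulate(vals + 1L, nbins = g$L)
  structure(list(counts = counts, n = length(vals), p = counts / length(vals),
                 L = g$L), class = "gray_histogram")
}

#' FOV-restricted histogram equalization
#'
#' Each masked pixel at level r_k maps to
#' `s_k = round((L-1) * sum_{j<=k} n_j / n)` where the level counts n_j are
#' taken over masked pixels only; the mapping is monotone non-decreasing.
#' Pixels outside the mask are set to 0, so camera background stays black
#' and does not leak contrast into the eyeball region.
#'
#' @param g integer-convention [gray_image()].
#' @param mask binary matrix; must select at least one pixel.
#' @return Equalized integer-convention [gray_image()].
#' @export
masked_hist_equalize <- function(g, mask) {
  h <- compute_histogram(g, mask)
  cdf <- cumsum(h$counts) / h$n
  lut <- round_half_up((g$L - 1) * cdf)  # lut[k+1] = s_k
  out <- matrix(0, nrow(g$values), ncol(g$values))
  sel <- mask == 1
  out[sel] <- lut[g$values[sel] + 1L]
  gray_image(out, "integer", g$L)
}

#' Gamma (power-law) transform
#'
#' Applies `s = c * r^gamma` pointwise on intensities normalized to `[0,1]`.
#' `gamma > 1` darkens midtones, `gamma < 1` brightens them; endpoints are
#' fixed for `c = 1`. The pipeline default `gamma = 1.3` gives the strongest
#' vessel contrast after equalization.
#'
#' @param g a [gray_image()]; integer-convention input is first divided by
#'   `L - 1`.
#' @param gamma positive exponent.
#' @param c gray-scale coefficient (default 1).
#' @return Normalized-convention [gray_image()].
#' @export
gamma_transform <- function(g, gamma = 1.3, c = 1) {
  if (gamma <= 0) stop_retseg("gamma must be positive", "retseg_parameter_error")
  if (c <= 0) stop_retseg("c must be positive", "retseg_parameter_error")
  r <- if (g$convention == "integer") g$values / (g$L - 1) else g$values
  s <- c * r^gamma
  gray_image(clamp(s, 0, 1), "normalized", g$L)
}

#' Full preprocessing chain
#'
#' green channel -> Gaussian denoise -> FOV-masked histogram equalization ->
#' gamma transform. The result is the normalized single-channel image the
#' segmentation network consumes.
#'
#' @param img a [fundus_image()].
#' @param kernel,sigma Gaussian denoising parameters.
#' @param gamma,c gamma-transform parameters.
#' @param mask optional binary FOV mask; defaults to [estimate_fov_mask()].
#' @return Normalized-convention [gray_image()] with values in `[0,1]`.
#' @export
preprocess_fundus <- function(img, kernel = 3L, sigma = 1.0, gamma = 1.3,
                              c = 1, mask = NULL) {
  if (is.null(mask)) mask <- estimate_fov_mask(img)
  g <- extract_green_channel(img)
  g <- gaussian_denoise(g, kernel = kernel, sigma = sigma)
  g <- masked_hist_equalize(g, mask)
  gamma_transform(g, gamma = gamma, c = c)
}
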