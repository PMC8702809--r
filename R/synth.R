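#' Specification for a synthetic fundus image
#'
#' The generator emulates the gross appearance of DRIVE/STARE-style fundus
#' photographs: a bright disc-shaped field of view on a near-black camera
#' background, green-dominant tissue with radial shading and gentle texture,
#' and a recursively branching tree of smooth curvilinear vessels whose
#' stroke width decays towards the periphery (roots about 5-6 px wide down
#' to about 1 px). Vessels are rendered 30-60% darker than the surrounding
#' tissue in the green channel, which is why the green channel carries the
#' segmentation signal. Exact rasterized strokes form the ground truth.
#'
#' @param height,width image size in pixels (>= 64).
#' @param fov_radius_frac disc radius as a fraction of the minimum dimension.
#' @param n_roots number of vessel tree roots near the disc center.
#' @param branch_prob probability that a segment splits into two children.
#' @param max_depth maximum tree depth.
#' @param width_decay multiplicative stroke-width decay per generation.
#' @param noise_sd additive Gaussian pixel noise, 0-255 scale.
#' @param seed integer; fixes all randomness.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(height = 584L, width = 584L, fov_radius_frac = 0.46,
                       n_roots = 6L, branch_prob = 0.35, max_depth = 5L,
                       width_decay = 0.78, noise_sd = 3, seed = 1L) {
  if (height < 64L || width < 64L)
    stop_retseg("synthetic images must be at least 64 x 64", "retseg_parameter_error")
  if (fov_radius_frac <= 0 || fov_radius_frac > 1)
    stop_retseg("fov_radius_frac must lie in (0, 1]", "retseg_parameter_error")
  structure(list(height = as.integer(height), width = as.integer(width),
                 fov_radius_frac = fov_radius_frac, n_roots = as.integer(n_roots),
                 branch_prob = branch_prob, max_depth = as.integer(max_depth),
                 width_decay = width_decay, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# stamp filled discs of radius `rad` (supersampled px) at points (py, px)
stamp_points <- function(canvas, py, px, rad, value) {
  H <- nrow(canvas); W <- ncol(canvas)
  for (i in seq_along(py)) {
    r <- rad[i]
    ri <- ceiling(r)
    y0 <- max(1L, floor(py[i] - ri)); y1 <- min(H, ceiling(py[i] + ri))
    x0 <- max(1L, floor(px[i] - ri)); x1 <- min(W, ceiling(px[i] + ri))
    if (y0 > y1 || x0 > x1) next
    ys <- y0:y1; xs <- x0:x1
    d2 <- outer((ys - py[i])^2, (xs - px[i])^2, `+`)
    hit <- d2 <= r^2
    blk <- canvas[ys, xs, drop = FALSE]
    blk[hit] <- pmax(blk[hit], value)
    canvas[ys, xs] <- blk
  }
  canvas
}

# average ss x ss blocks of a supersampled canvas
block_mean <- function(m, ss) {
  H <- nrow(m) / ss; W <- ncol(m) / ss
  a <- m[seq(1, nrow(m), by = ss), , drop = FALSE]
  for (k in 2:ss) a <- a + m[seq(k, nrow(m), by = ss), , drop = FALSE]
  b <- a[, seq(1, ncol(m), by = ss), drop = FALSE]
  for (k in 2:ss) b <- b + a[, seq(k, ncol(m), by = ss), drop = FALSE]
  b / ss^2
}

#' Generate a synthetic fundus image with mask and ground truth
#'
#' Deterministic for a given spec (including its seed): the same spec always
#' returns bit-identical pixels, mask and truth.
#'
#' @param spec a [synth_spec()].
#' @return A [fundus_image()] with `fov_mask` and `truth` set.
#' @export
generate_fundus <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop_retseg("need a synth_spec", "retseg_parameter_error")
  with_local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    R <- spec$fov_radius_frac * min(h, w)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
    mask <- (dist <= R) + 0

    # tissue: radially shaded green with low-frequency texture
    tex <- matrix(0, h, w)
    for (j in 1:3) {
      f <- runif(2, 0.5, 2.5) / min(h, w)
      tex <- tex + runif(1, 2, 5) *
        sin(2 * pi * (f[1] * xx + f[2] * yy) + runif(1, 0, 2 * pi))
    }
    tissue <- 150 * (1 - 0.35 * pmin(dist / R, 1)^2) + tex

    # vessel tree on a supersampled canvas
    ss <- 2L
    cov <- matrix(0, ss * h, ss * w)   # binary coverage
    dark <- matrix(0, ss * h, ss * w)  # darkening strength where covered
    queue <- list()
    for (r in seq_len(spec$n_roots)) {
      th <- runif(1, 0, 2 * pi)
      p0 <- c(cy + 0.12 * R * sin(th), cx + 0.12 * R * cos(th))
      dir <- th + runif(1, -0.4, 0.4)
      queue[[length(queue) + 1L]] <- list(p = p0, dir = dir,
                                          width = runif(1, 4.5, 6), depth = 1L,
                                          dark = runif(1, 0.35, 0.6))
    }
    while (length(queue) > 0) {
      seg <- queue[[1]]; queue <- queue[-1]
      if (seg$width < 0.8 || seg$depth > spec$max_depth) next
      len <- runif(1, 0.25, 0.45) * R
      ex <- c(sin(seg$dir), cos(seg$dir))
      pp <- c(-ex[2], ex[1])
      pmid <- seg$p + ex * len / 2 + pp * runif(1, -0.2, 0.2) * len
      pend <- seg$p + ex * len + pp * runif(1, -0.15, 0.15) * len
      npts <- max(8L, ceiling(len * ss / 0.7))
      t <- seq(0, 1, length.out = npts)
      by <- (1 - t)^2 * seg$p[1] + 2 * t * (1 - t) * pmid[1] + t^2 * pend[1]
      bx <- (1 - t)^2 * seg$p[2] + 2 * t * (1 - t) * pmid[2] + t^2 * pend[2]
      wid <- seg$width * (1 + (spec$width_decay - 1) * t)
      inside <- sqrt((by - cy)^2 + (bx - cx)^2) <= R - 1
      if (any(inside)) {
        cov <- stamp_points(cov, by[inside] * ss - 0.5, bx[inside] * ss - 0.5,
                            wid[inside] * ss / 2, 1)
        dark <- stamp_points(dark, by[inside] * ss - 0.5, bx[inside] * ss - 0.5,
                             wid[inside] * ss / 2, seg$dark)
      }
      wend <- seg$width * spec$width_decay
      out_of_disc <- sqrt((pend[1] - cy)^2 + (pend[2] - cx)^2) > 1.02 * R
      if (seg$depth < spec$max_depth && !out_of_disc) {
        end_dir <- atan2(pend[1] - seg$p[1], pend[2] - seg$p[2])
        if (runif(1) < spec$branch_prob) {
          split <- runif(1, 0.35, 0.9)
          for (sgn in c(-1, 1))
            queue[[length(queue) + 1L]] <-
              list(p = pend, dir = end_dir + sgn * split, width = wend,
                   depth = seg$depth + 1L, dark = seg$dark)
        } else {
          queue[[length(queue) + 1L]] <-
            list(p = pend, dir = end_dir + runif(1, -0.3, 0.3), width = wend,
                 depth = seg$depth + 1L, dark = seg$dark)
        }
      }
    }
    coverage <- block_mean(cov, ss)
    darkness <- block_mean(dark, ss)
    truth <- ((coverage >= 0.5) & (mask == 1)) + 0

    green <- tissue * (1 - pmin(darkness, 0.6))
    px <- array(0, c(h, w, 3L))
    px[, , 1] <- 0.55 * green
    px[, , 2] <- green
    px[, , 3] <- 0.22 * green
    bg <- 8
    for (c in 1:3) {
      ch <- px[, , c]
      ch[mask == 0] <- bg
      ch <- ch + rnorm(h * w, 0, spec$noise_sd)
      px[, , c] <- clamp(round_half_up(ch), 0, 255)
    }
    fundus_image(px, fov_mask = mask, truth = truth)
  })
}

#' Write a DRIVE-style synthetic dataset to disk
#'
#' Creates `images/`, `masks/` and `truths/` subdirectories with one PNG per
#' image, consumable by [evaluate_dataset()] and the command-line interface.
#' Image `i` uses a seed derived from `spec$seed` and `i`.
#'
#' @param spec a [synth_spec()] (its seed seeds the whole dataset).
#' @param n_images number of images (>= 1).
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
generate_dataset <- function(spec, n_images, out_dir) {
  if (n_images < 1L) stop_retseg("n_images must be >= 1", "retseg_parameter_error")
  for (d in c("images", "masks", "truths"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_images)) {
    si <- spec
    si$seed <- derive_seed(spec$seed, i)
    img <- generate_fundus(si)
    write_png(img$pixels / 255, file.path(out_dir, "images", sprintf("img_%03d.png", i)))
    write_png(img$fov_mask, file.path(out_dir, "masks", sprintf("mask_%03d.png", i)))
    write_png(img$truth, file.path(out_dir, "truths", sprintf("truth_%03d.png", i)))
  }
  invisible(out_dir)
}
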