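test_that("green-channel extraction projects the second channel unchanged", {
  px <- array(0, c(2, 2, 3))
  px[, , 1] <- 10; px[, , 2] <- 200; px[, , 3] <- 30
  g <- extract_green_channel(fundus_image(px))
  expect_true(all(g$values == 200))
  expect_identical(g$convention, "integer")
  expect_identical(g$L, 256L)

  red <- array(rep(c(255, 0, 0), each = 4), c(2, 2, 3))
  expect_true(all(extract_green_channel(fundus_image(red))$values == 0))
  green <- array(rep(c(0, 255, 0), each = 4), c(2, 2, 3))
  expect_true(all(extract_green_channel(fundus_image(green))$values == 255))

  expect_error(extract_green_channel(matrix(1, 4, 4)), class = "retseg_channel_error")
})

test_that("FOV mask is passed through when supplied, estimated otherwise", {
  im <- small_fundus(seed = 3L)
  expect_identical(estimate_fov_mask(im), im$fov_mask)

  # drop the mask: estimation must recover the generating disc almost exactly
  im2 <- fundus_image(im$pixels, truth = im$truth)
  est <- estimate_fov_mask(im2)
  inter <- sum(est == 1 & im$fov_mask == 1)
  uni <- sum(est == 1 | im$fov_mask == 1)
  expect_gt(inter / uni, 0.99)

  black <- fundus_image(array(0, c(64, 64, 3)))
  expect_error(estimate_fov_mask(black), class = "retseg_degenerate_error")
})

test_that("Gaussian denoising preserves constants and conserves mass", {
  const <- gray_image(matrix(100, 16, 16))
  expect_equal(gaussian_denoise(const)$values, const$values)

  # single bright pixel: compare against a direct convolution oracle
  m <- matrix(0, 9, 9)
  m[5, 5] <- 255
  ax <- -1:1
  K <- outer(exp(-ax^2 / 2), exp(-ax^2 / 2))
  K <- K / sum(K)
  sm <- gaussian_denoise(gray_image(m), kernel = 3L, sigma = 1)
  oracle <- conv2d_reflect_oracle(m, K)
  expect_true(all(abs(sm$values - oracle) <= 0.5 + 1e-9)) # rounding only
  expect_equal(sum(sm$values), sum(retseg:::round_half_up(oracle)))
  expect_true(all(sm$values[3:7, 3:7] == retseg:::round_half_up(oracle[3:7, 3:7])))

  expect_error(gaussian_denoise(const, sigma = 0), class = "retseg_parameter_error")
  expect_error(gaussian_denoise(const, sigma = -1), class = "retseg_parameter_error")
})

test_that("masked histograms count only masked pixels and normalize", {
  g <- gray_image(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE), L = 4L)
  h <- compute_histogram(g)
  expect_equal(h$counts, c(2, 1, 1, 0))
  expect_equal(h$n, 4)
  expect_equal(sum(h$p), 1)

  mask <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  h2 <- compute_histogram(g, mask)
  expect_equal(h2$counts, c(2, 0, 0, 0))
  expect_equal(h2$n, 2)

  expect_error(compute_histogram(g, matrix(0, 2, 2)), class = "retseg_degenerate_error")
})

test_that("masked equalization matches the worked 4-level example", {
  # 4 masked pixels at levels 0, 63, 127, 255: cumulative frequencies
  # 0.25/0.5/0.75/1 scale to 63.75, 127.5, 191.25, 255 and round half-up
  # to 64, 128, 191, 255
  g <- gray_image(matrix(c(0, 63, 127, 255), 2, 2))
  eq <- masked_hist_equalize(g, matrix(1, 2, 2))
  expect_equal(sort(as.vector(eq$values)), c(64, 128, 191, 255))

  # any constant masked region maps to L-1
  g2 <- gray_image(matrix(17, 3, 3))
  expect_true(all(masked_hist_equalize(g2, matrix(1, 3, 3))$values == 255))

  # pixels outside the mask are forced to 0
  mask <- matrix(0, 2, 2); mask[1, ] <- 1
  eq3 <- masked_hist_equalize(g, mask)
  expect_true(all(eq3$values[2, ] == 0))
})

test_that("equalization is monotone and spreads the masked histogram", {
  set.seed(42)
  # cluster levels in a narrow band so there is room to stretch
  v <- matrix(pmin(pmax(round(rnorm(40 * 40, 100, 12)), 0), 255), 40, 40)
  g <- gray_image(v)
  mask <- matrix(1, 40, 40)
  eq <- masked_hist_equalize(g, mask)
  # monotone: order of gray levels preserved
  o <- order(as.vector(v))
  expect_true(all(diff(as.vector(eq$values)[o]) >= 0))
  # output CDF closer to uniform than the input's
  dev_from_uniform <- function(vals) {
    cdf <- cumsum(tabulate(vals + 1L, 256L)) / length(vals)
    max(abs(cdf - (1:256) / 256))
  }
  expect_lte(dev_from_uniform(eq$values[mask == 1]),
             dev_from_uniform(v[mask == 1]))
})

test_that("gamma transform fixes endpoints, is identity at gamma 1, darkens for gamma > 1", {
  g <- gray_image(matrix(c(0, 0.25, 0.5, 1), 2, 2), "normalized")
  out <- gamma_transform(g, gamma = 1.3)
  expect_equal(out$values[1, 1], 0)
  expect_equal(out$values[2, 2], 1)
  expect_equal(out$values[c(2, 3)], c(0.25, 0.5)^1.3)
  expect_equal(gamma_transform(g, gamma = 1)$values, g$values)
  expect_equal(gamma_transform(gray_image(matrix(0.5, 1, 1), "normalized"),
                               gamma = 1.3)$values[1, 1],
               0.5^1.3, tolerance = 1e-12)

  # pointwise darkening/brightening on (0,1)
  mid <- gray_image(matrix(seq(0.05, 0.95, length.out = 16), 4, 4), "normalized")
  expect_true(all(gamma_transform(mid, 1.5)$values <= mid$values))
  expect_true(all(gamma_transform(mid, 0.7)$values >= mid$values))

  expect_error(gamma_transform(g, gamma = 0), class = "retseg_parameter_error")
})

test_that("full preprocessing is deterministic, in range and contrast-stretching", {
  im <- small_fundus(seed = 5L)
  p1 <- preprocess_fundus(im)
  p2 <- preprocess_fundus(im)
  expect_identical(p1$values, p2$values)
  expect_identical(p1$convention, "normalized")
  expect_identical(dim(p1$values), dim(im$pixels)[1:2])
  expect_true(all(p1$values >= 0 & p1$values <= 1))

  # contrast inside the FOV does not decrease relative to the raw green channel
  sel <- im$fov_mask == 1
  raw <- im$pixels[, , 2] / 255
  expect_gte(stats::sd(p1$values[sel]), stats::sd(raw[sel]))
})
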