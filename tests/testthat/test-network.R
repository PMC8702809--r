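test_that("autograd gradients match central finite differences", {
  set.seed(17)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- (array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2)) > 0.8) + 0
  w1 <- retseg:::tg_param(array(rnorm(3 * 3 * 3 * 4, sd = 0.3), c(3, 3, 3, 4)))
  b1 <- retseg:::tg_param(rnorm(4))
  gam <- retseg:::tg_param(runif(4, 0.5, 1.5))
  bet <- retseg:::tg_param(rnorm(4))
  st <- new.env(); st$rmean <- rep(0, 4); st$rvar <- rep(1, 4)
  wt <- retseg:::tg_param(array(rnorm(2 * 2 * 4 * 2, sd = 0.3), c(2, 2, 4, 2)))
  bt <- retseg:::tg_param(rnorm(2))
  wo <- retseg:::tg_param(array(rnorm(1 * 1 * 2 * 1, sd = 0.3), c(1, 1, 2, 1)))
  bo <- retseg:::tg_param(rnorm(1))
  params <- list(w1 = w1, b1 = b1, gam = gam, bet = bet, wt = wt, bt = bt,
                 wo = wo, bo = bo)
  # dilated conv -> BN -> ReLU -> pool -> transposed conv -> 1x1 -> sigmoid
  make_loss <- function() {
    retseg:::tg_zero_grad(params)
    h <- retseg:::tg_conv(retseg:::tg_const(x), w1, b1, 2L)
    h <- retseg:::tg_bn(h, gam, bet, st, TRUE)
    h <- retseg:::tg_relu(h)
    h <- retseg:::tg_pool(h)
    h <- retseg:::tg_convt(h, wt, bt)
    o <- retseg:::tg_sigmoid(retseg:::tg_conv(h, wo, bo, 1L))
    retseg:::tg_wbce(o, y)
  }
  loss <- make_loss()
  retseg:::tg_backward(loss)
  grads <- lapply(params, function(p) p$grad)
  eps <- 1e-5
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in sample(length(p$value), min(3, length(p$value)))) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps; lp <- make_loss()$value
      p$value[i] <- v0 - eps; lm <- make_loss()$value
      p$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][i]) / max(1e-6, abs(num) + abs(grads[[nm]][i])),
                1e-5)
    }
  }
})

test_that("residual block preserves spatial dims and reduces to the projection when F = 0", {
  set.seed(2)
  out <- residual_block(array(runif(64 * 64 * 1), c(64, 64, 1)), 64L, seed = 1L)
  expect_identical(dim(out), c(64L, 64L, 64L, 1L))
  out2 <- residual_block(array(runif(24 * 40 * 3), c(24, 40, 3)), 5L, seed = 1L)
  expect_identical(dim(out2)[1:3], c(24L, 40L, 5L))

  # zero the residual path by hand: H(x) must equal the 1x1 projection g(x)
  ctx <- new.env(); ctx$params <- list(); ctx$states <- list()
  retseg:::with_local_seed(8L, retseg:::reg_res(ctx, "blk", 2L, 3L))
  for (nm in c("blk.f1.conv.w", "blk.f1.conv.b", "blk.f2.conv.w", "blk.f2.conv.b"))
    ctx$params[[nm]]$value[] <- 0
  m <- list(params = ctx$params, states = ctx$states)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  h <- retseg:::f_res(m, "blk", retseg:::tg_const(x), TRUE, 0)
  g <- retseg:::f_conv(m, "blk.proj", retseg:::tg_const(x))
  expect_equal(h$value, g$value, tolerance = 1e-12)
})

test_that("ASPP concatenates its branches into rates x kernels channels", {
  x <- array(runif(8 * 8 * 16), c(8, 8, 16))
  out <- aspp_block(x, seed = 1L)
  expect_identical(dim(out), c(8L, 8L, 512L, 1L)) # 4 branches x 128 kernels
  out2 <- aspp_block(array(runif(32 * 32 * 3), c(32, 32, 3)),
                     rates = c(1L, 2L), kernels_per_branch = 6L, seed = 1L)
  expect_identical(dim(out2), c(32L, 32L, 12L, 1L))
  expect_error(aspp_block(x, rates = c(0L, 1L)), class = "retseg_parameter_error")
})

test_that("dilated convolution sees exactly its enlarged receptive field", {
  # a 3x3 kernel of ones at dilation r responds to a centered point source
  # over a (2r+1)-extent cross pattern: taps sit r pixels apart
  for (r in 1:3) {
    x <- array(0, c(15, 15, 1, 1))
    x[8, 8, 1, 1] <- 1
    w <- array(1, c(3, 3, 1, 1))
    y <- retseg:::cpp_conv2d_fwd(x, w, 0, as.integer(r))
    hit <- which(y[, , 1, 1] > 0, arr.ind = TRUE)
    expect_identical(max(hit) - min(hit), 2L * r) # extent 2r+1
    expect_identical(nrow(hit), 9L)
  }
})

test_that("residual attention gates the trunk multiplicatively within (T, 2T)", {
  set.seed(4)
  x <- array(runif(16 * 16 * 6), c(16, 16, 6))
  out <- residual_attention_block(x, seed = 2L)
  expect_identical(dim(out), c(16L, 16L, 6L, 1L))

  # H = (1 + M) T with sigmoid M: direct check on controlled tensors
  Tv <- retseg:::tg_const(array(abs(rnorm(4 * 4 * 2 * 1)), c(4, 4, 2, 1)))
  Mv <- retseg:::tg_const(array(0.5, c(4, 4, 2, 1)))
  H <- retseg:::tg_mul(retseg:::tg_add_const(Mv, 1), Tv)
  expect_equal(H$value, 1.5 * Tv$value)
  zeroT <- retseg:::tg_mul(retseg:::tg_add_const(Mv, 1),
                           retseg:::tg_const(array(0, c(4, 4, 2, 1))))
  expect_true(all(zeroT$value == 0))

  expect_error(residual_attention_block(array(runif(6 * 6 * 2), c(6, 6, 2))),
               class = "retseg_shape_error")
})

test_that("supervision heads upsample to the target and stay strictly in (0,1)", {
  h <- deep_supervision_head(array(rnorm(16 * 16 * 8), c(16, 16, 8)), 64L, seed = 1L)
  expect_identical(dim(h), c(64L, 64L, 1L, 1L))
  expect_true(all(h > 0 & h < 1))
  h2 <- deep_supervision_head(array(rnorm(32 * 32 * 4), c(32, 32, 4)), 64L, seed = 1L)
  expect_identical(dim(h2)[1:2], c(64L, 64L))
  expect_equal(1 / (1 + exp(0)), 0.5) # sigmoid fixes 0 at one half
  expect_error(deep_supervision_head(array(rnorm(8 * 8 * 2), c(8, 8, 2)), 64L),
               class = "retseg_shape_error")
})

test_that("full forward obeys the published shape contracts", {
  m <- build_model(model_spec(), seed = 1L)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  set.seed(1)
  out <- model_forward(m, x, training = TRUE) # batch statistics at init
  expect_identical(dim(out$main), c(64L, 64L, 1L, 1L))
  expect_length(out$heads, 3L)
  for (h in out$heads) expect_identical(dim(h), c(64L, 64L, 1L, 1L))
  expect_true(all(out$main > 0 & out$main < 1))
  expect_true(all(sapply(out$heads, function(h) all(h > 0 & h < 1))))
  # decoder hands a 64 x 64 x 64 feature map to the output stage
  expect_identical(out$pre_head_dim, c(64L, 64L, 64L, 1L))
})

test_that("shape contracts hold for other windows divisible by 8", {
  for (w in c(16L, 32L)) {
    m <- build_model(tiny_model_spec(window = w), seed = 1L)
    out <- model_forward(m, array(runif(w * w), c(w, w, 1, 1)))
    expect_identical(dim(out$main), c(w, w, 1L, 1L))
    expect_identical(out$pre_head_dim[1:3], c(w, w, 8L))
  }
})

test_that("every parameter receives gradient at initialization", {
  set.seed(9)
  m <- build_model(tiny_model_spec(window = 16L), seed = 3L)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  y <- (array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2)) > 0.85) + 0
  g <- retseg:::model_graph(m, retseg:::tg_const(x), TRUE)
  ls <- c(lapply(g$heads, retseg:::tg_wbce, y = y),
          list(retseg:::tg_wbce(g$main, y)))
  retseg:::tg_backward(retseg:::tg_wsum(ls, rep(1, 4)))
  dead <- names(m$params)[sapply(m$params, function(p)
    is.null(p$grad) || all(p$grad == 0))]
  expect_identical(dead, character(0))
})

test_that("batch decomposition does not change eval-mode outputs", {
  m <- build_model(tiny_model_spec(window = 16L), seed = 5L)
  x <- array(runif(16 * 16 * 1 * 4), c(16, 16, 1, 4))
  joint <- model_forward(m, x)$main
  singles <- sapply(1:4, function(i)
    model_forward(m, array(x[, , 1, i], c(16, 16, 1, 1)))$main)
  expect_equal(as.vector(joint), as.vector(singles), tolerance = 1e-12)
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 4, 2)
  permuted <- model_forward(m, x[, , , perm, drop = FALSE])$main
  expect_equal(permuted, joint[, , , perm, drop = FALSE], tolerance = 1e-12)
})
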