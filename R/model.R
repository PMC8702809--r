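#' Architecture description of the segmentation network
#'
#' The network is a three-stage encoder-decoder over `window x window`
#' single-channel patches. Every stage is built from residual blocks; a
#' residual attention module gates the middle encoder stage and an atrous
#' spatial pyramid pooling (ASPP) block widens the deepest stage. Three
#' deep-supervision heads tap the encoder stages. Defaults follow the
#' published configuration: stage widths 64/128/256 (so the decoder lands at
#' a 64 x 64 x 64 feature map), ASPP dilation rates 1/2/3/4 with 128 kernels
#' per branch, dropout 0.2 and L2 weight decay 1e-4.
#'
#' @param in_channels input channels (1: the preprocessed green channel).
#' @param stage_channels encoder channel widths, one per stage.
#' @param aspp_rates dilation rates; must contain 1 (the ordinary 1x1 branch).
#' @param aspp_kernels_per_branch convolution kernels per ASPP branch.
#' @param dropout_rate dropout inside residual blocks, in `[0, 1)`.
#' @param l2_coeff L2 regularization strength applied to convolution kernels.
#' @param n_supervision number of deep-supervision heads (3).
#' @param window training patch side; must be divisible by 8.
#' @param attention_stage,aspp_stage encoder stages hosting the attention and
#'   ASPP blocks (defaults: middle and deepest).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(in_channels = 1L, stage_channels = c(64L, 128L, 256L),
                       aspp_rates = c(1L, 2L, 3L, 4L),
                       aspp_kernels_per_branch = 128L, dropout_rate = 0.2,
                       l2_coeff = 1e-4, n_supervision = 3L, window = 64L,
                       attention_stage = 2L, aspp_stage = 3L) {
  if (length(stage_channels) != 3L)
    stop_retseg("stage_channels must list three encoder stages", "retseg_construction_error")
  if (!1L %in% aspp_rates)
    stop_retseg("aspp_rates must contain 1", "retseg_construction_error")
  if (any(aspp_rates < 1L))
    stop_retseg("dilation rates must be >= 1", "retseg_parameter_error")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_retseg("dropout_rate must lie in [0, 1)", "retseg_construction_error")
  if (window %% 8L != 0L)
    stop_retseg("window must be divisible by 8 (three halvings)", "retseg_construction_error")
  structure(list(in_channels = as.integer(in_channels),
                 stage_channels = as.integer(stage_channels),
                 aspp_rates = as.integer(aspp_rates),
                 aspp_kernels_per_branch = as.integer(aspp_kernels_per_branch),
                 dropout_rate = dropout_rate, l2_coeff = l2_coeff,
                 n_supervision = as.integer(n_supervision),
                 window = as.integer(window),
                 attention_stage = as.integer(attention_stage),
                 aspp_stage = as.integer(aspp_stage)),
            class = "model_spec")
}

#' Reduced architecture for desk-scale experiments
#'
#' Stage widths 8/16/32 with 8 ASPP kernels per branch; used by the training
#' sanity checks and examples.
#'
#' @param ... overrides passed to [model_spec()].
#' @export
tiny_model_spec <- function(...) {
  args <- utils::modifyList(list(stage_channels = c(8L, 16L, 32L),
                                 aspp_kernels_per_branch = 8L), list(...))
  do.call(model_spec, args)
}

# ---- parameter registration -----------------------------------------------

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

reg_conv <- function(ctx, name, k, cin, cout) {
  ctx$params[[paste0(name, ".w")]] <- tg_param(he_init(k, cin, cout))
  ctx$params[[paste0(name, ".b")]] <- tg_param(rep(0, cout))
}

reg_convt <- function(ctx, name, cin, cout) {
  ctx$params[[paste0(name, ".w")]] <- tg_param(he_init(2L, cin, cout))
  ctx$params[[paste0(name, ".b")]] <- tg_param(rep(0, cout))
}

reg_bn <- function(ctx, name, c) {
  ctx$params[[paste0(name, ".gamma")]] <- tg_param(rep(1, c))
  ctx$params[[paste0(name, ".beta")]] <- tg_param(rep(0, c))
  st <- new.env(parent = emptyenv())
  st$rmean <- rep(0, c)
  st$rvar <- rep(1, c)
  ctx$states[[name]] <- st
}

reg_cbr <- function(ctx, name, k, cin, cout) {
  reg_conv(ctx, paste0(name, ".conv"), k, cin, cout)
  reg_bn(ctx, paste0(name, ".bn"), cout)
}

reg_res <- function(ctx, name, cin, cout) {
  reg_cbr(ctx, paste0(name, ".f1"), 3L, cin, cout)
  reg_cbr(ctx, paste0(name, ".f2"), 3L, cout, cout)
  reg_conv(ctx, paste0(name, ".proj"), 1L, cin, cout)
}

reg_att <- function(ctx, name, c) {
  reg_cbr(ctx, paste0(name, ".t1"), 3L, c, c)
  reg_cbr(ctx, paste0(name, ".t2"), 3L, c, c)
  reg_cbr(ctx, paste0(name, ".m1"), 3L, c, c)
  reg_cbr(ctx, paste0(name, ".m2"), 3L, c, c)
  reg_convt(ctx, paste0(name, ".u1"), c, c)
  reg_cbr(ctx, paste0(name, ".m3"), 3L, c, c)
  reg_convt(ctx, paste0(name, ".u2"), c, c)
  reg_conv(ctx, paste0(name, ".mo"), 1L, c, c)
}

reg_aspp <- function(ctx, name, cin, rates, kpb) {
  for (r in rates) {
    k <- if (r == 1L) 1L else 3L
    reg_cbr(ctx, paste0(name, ".r", r), k, cin, kpb)
  }
}

# deep-supervision head: one transposed-conv (+ReLU) per halving, 1x1 conv out
reg_head <- function(ctx, name, cin, n_up, mid) {
  c_prev <- cin
  for (i in seq_len(n_up)) {
    reg_convt(ctx, paste0(name, ".u", i), c_prev, mid[i])
    c_prev <- mid[i]
  }
  reg_conv(ctx, paste0(name, ".out"), 1L, c_prev, 1L)
}

# ---- forward helpers -------------------------------------------------------

pget <- function(model, name) {
  p <- model$params[[name]]
  if (is.null(p)) stop_retseg(paste0("unknown parameter ", name), "retseg_construction_error")
  p
}

f_conv <- function(model, name, x, dilation = 1L)
  tg_conv(x, pget(model, paste0(name, ".w")), pget(model, paste0(name, ".b")), dilation)

f_convt <- function(model, name, x)
  tg_convt(x, pget(model, paste0(name, ".w")), pget(model, paste0(name, ".b")))

f_bn <- function(model, name, x, training)
  tg_bn(x, pget(model, paste0(name, ".gamma")), pget(model, paste0(name, ".beta")),
        model$states[[name]], training)

f_cbr <- function(model, name, x, training, dilation = 1L) {
  tg_relu(f_bn(model, paste0(name, ".bn"),
               f_conv(model, paste0(name, ".conv"), x, dilation), training))
}

# residual block: H(x) = F(x) + g(x); F = conv-bn-relu, dropout, conv-bn-relu;
# g is the always-present 1x1 projection of the identity path
f_res <- function(model, name, x, training, dropout) {
  h <- f_cbr(model, paste0(name, ".f1"), x, training)
  h <- tg_dropout(h, dropout, training)
  h <- f_cbr(model, paste0(name, ".f2"), h, training)
  g <- f_conv(model, paste0(name, ".proj"), x)
  tg_add(h, g)
}

# residual attention: H = (1 + M) * T; trunk keeps a jump connection, the
# mask branch goes down twice and up twice and ends in a sigmoid
f_att <- function(model, name, x, training) {
  d <- dim(x$value)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop_retseg("attention input spatial dims must be divisible by 4", "retseg_shape_error")
  t <- f_cbr(model, paste0(name, ".t1"), x, training)
  t <- f_cbr(model, paste0(name, ".t2"), t, training)
  trunk <- tg_add(t, x)
  m <- tg_pool(x)
  m <- f_cbr(model, paste0(name, ".m1"), m, training)
  m <- tg_pool(m)
  m <- f_cbr(model, paste0(name, ".m2"), m, training)
  m <- f_convt(model, paste0(name, ".u1"), m)
  m <- f_cbr(model, paste0(name, ".m3"), m, training)
  m <- f_convt(model, paste0(name, ".u2"), m)
  mask <- tg_sigmoid(f_conv(model, paste0(name, ".mo"), m))
  tg_mul(tg_add_const(mask, 1), trunk)
}

# ASPP: parallel 1x1 (r = 1) and dilated 3x3 branches, channel-concatenated
f_aspp <- function(model, name, x, rates, training) {
  outs <- lapply(rates, function(r) {
    f_cbr(model, paste0(name, ".r", r), x, training,
          dilation = if (r == 1L) 1L else r)
  })
  out <- outs[[1]]
  for (i in seq_along(outs)[-1]) out <- tg_concat(out, outs[[i]])
  out
}

f_head <- function(model, name, x, n_up, training) {
  h <- x
  for (i in seq_len(n_up)) h <- tg_relu(f_convt(model, paste0(name, ".u", i), h))
  tg_sigmoid(f_conv(model, paste0(name, ".out"), h))
}

# ---- model -----------------------------------------------------------------

# channel width of each encoder stage output after its optional ASPP block
stage_out_channels <- function(spec) {
  out <- spec$stage_channels
  if (!is.na(spec$aspp_stage) && spec$aspp_stage >= 1L)
    out[spec$aspp_stage] <- length(spec$aspp_rates) * spec$aspp_kernels_per_branch
  out
}

#' Build the segmentation network
#'
#' Assembles the encoder (residual blocks with attention at the middle stage
#' and ASPP at the deepest, each followed by 2x2 max pooling), the decoder
#' (transposed-conv upsampling, skip concatenation, residual block per
#' stage), the final residual block + 1x1 convolution + sigmoid output, and
#' the three deep-supervision heads.
#'
#' @param spec a [model_spec()].
#' @param seed optional integer; fixes the weight initialization.
#' @return An object of class `retseg_model`.
#' @export
build_model <- function(spec, seed = NULL) {
  if (!inherits(spec, "model_spec")) stop_retseg("spec must be a model_spec", "retseg_construction_error")
  build <- function() {
    ctx <- new.env(parent = emptyenv())
    ctx$params <- list()
    ctx$states <- list()
    ch <- spec$stage_channels
    sout <- stage_out_channels(spec)
    cin <- spec$in_channels
    for (s in 1:3) {
      reg_res(ctx, paste0("enc", s), cin, ch[s])
      if (s == spec$attention_stage) reg_att(ctx, paste0("att", s), ch[s])
      if (s == spec$aspp_stage)
        reg_aspp(ctx, paste0("aspp", s), ch[s], spec$aspp_rates,
                 spec$aspp_kernels_per_branch)
      cin <- sout[s]
    }
    # decoder, deepest first
    reg_convt(ctx, "dec3.up", sout[3], ch[3])
    reg_res(ctx, "dec3.res", ch[3] + sout[3], ch[3])
    reg_convt(ctx, "dec2.up", ch[3], ch[2])
    reg_res(ctx, "dec2.res", ch[2] + sout[2], ch[2])
    reg_convt(ctx, "dec1.up", ch[2], ch[1])
    reg_res(ctx, "dec1.res", ch[1] + sout[1], ch[1])
    reg_res(ctx, "final.res", ch[1], ch[1])
    reg_conv(ctx, "final.out", 1L, ch[1], 1L)
    # supervision heads: taps at scales 1, 2, 4
    reg_head(ctx, "head1", sout[1], 0L, integer(0))
    reg_head(ctx, "head2", sout[2], 1L, ch[1])
    reg_head(ctx, "head3", sout[3], 2L, c(ch[2], ch[1]))
    structure(list(spec = spec, params = ctx$params, states = ctx$states),
              class = "retseg_model")
  }
  if (is.null(seed)) build() else with_local_seed(seed, build())
}

#' @export
print.retseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<retseg_model stages [%s], %s parameters>\n",
              paste(x$spec$stage_channels, collapse = ", "),
              format(np, big.mark = ",")))
  invisible(x)
}

# full forward pass on a tensor; returns tensors for training use
model_graph <- function(model, x, training = FALSE) {
  spec <- model$spec
  taps <- vector("list", 3L)
  h <- x
  for (s in 1:3) {
    h <- f_res(model, paste0("enc", s), h, training, spec$dropout_rate)
    if (s == spec$attention_stage) h <- f_att(model, paste0("att", s), h, training)
    if (s == spec$aspp_stage)
      h <- f_aspp(model, paste0("aspp", s), h, spec$aspp_rates, training)
    taps[[s]] <- h
    h <- tg_pool(h)
  }
  d <- f_convt(model, "dec3.up", h)
  d <- tg_concat(d, taps[[3]])
  d <- f_res(model, "dec3.res", d, training, spec$dropout_rate)
  d <- f_convt(model, "dec2.up", d)
  d <- tg_concat(d, taps[[2]])
  d <- f_res(model, "dec2.res", d, training, spec$dropout_rate)
  d <- f_convt(model, "dec1.up", d)
  d <- tg_concat(d, taps[[1]])
  pre_head <- f_res(model, "dec1.res", d, training, spec$dropout_rate)
  f <- f_res(model, "final.res", pre_head, training, spec$dropout_rate)
  main <- tg_sigmoid(f_conv(model, "final.out", f))
  heads <- list(
    f_head(model, "head1", taps[[1]], 0L, training),
    f_head(model, "head2", taps[[2]], 1L, training),
    f_head(model, "head3", taps[[3]], 2L, training)
  )
  list(main = main, heads = heads, pre_head = pre_head, taps = taps)
}

# coerce input to [H, W, C, N]
as_input4 <- function(x, in_channels = 1L) {
  d <- dim(x)
  if (is.null(d)) stop_retseg("input must be an array", "retseg_shape_error")
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, c(d[1], d[2], 1L, d[3]))
  if (dim(x)[3] != in_channels)
    stop_retseg("input channel mismatch", "retseg_shape_error")
  x
}

#' Run the network on a batch of patches
#'
#' @param model a [build_model()] result.
#' @param x patches: a `H x W` matrix, `H x W x n` array (stack of
#'   single-channel patches) or `H x W x C x n` array.
#' @param training logical; training mode uses batch statistics and dropout.
#' @return List with `main` (`H x W x 1 x n` probability array) and `heads`
#'   (list of three arrays of the same shape); all values in `(0, 1)`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  xt <- tg_const(as_input4(x, model$spec$in_channels))
  g <- model_graph(model, xt, training)
  list(main = g$main$value, heads = lapply(g$heads, function(h) h$value),
       pre_head_dim = dim(g$pre_head$value))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the architecture spec alongside the weights and
#' batch-norm running statistics, so the model is reconstructible from the
#' file alone.
#'
#' @param model a `retseg_model`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = unclass(model$spec),
               params = lapply(model$params, function(p) p$value),
               states = lapply(model$states, as.list)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  spec <- do.call(model_spec, ck$spec)
  model <- build_model(spec, seed = 1L)
  for (nm in names(ck$params)) model$params[[nm]]$value <- ck$params[[nm]]
  for (nm in names(ck$states)) {
    model$states[[nm]]$rmean <- ck$states[[nm]]$rmean
    model$states[[nm]]$rvar <- ck$states[[nm]]$rvar
  }
  model
}

# ---- standalone blocks (randomly initialized, for inspection/testing) ------

standalone <- function(reg, fwd, x, seed) {
  d <- dim(x)
  if (is.null(d)) stop_retseg("input must be a matrix or array", "retseg_shape_error")
  x4 <- if (length(d) == 2L) array(x, c(d, 1L, 1L))
        else array(x, c(d[1], d[2], d[3], 1L))
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list(); ctx$states <- list()
  run <- function() {
    reg(ctx, dim(x4)[3])
    model <- list(params = ctx$params, states = ctx$states)
    fwd(model, tg_const(x4))$value
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Standalone network blocks
#'
#' Randomly initialized single blocks applied to an array, mainly for
#' inspecting shape contracts: `residual_block` preserves spatial dims and
#' maps to `out_channels`; `aspp_block` concatenates its branches into
#' `length(rates) * kernels_per_branch` channels; the attention block
#' preserves shape; a supervision head upsamples to `target_size` and emits
#' one sigmoid channel.
#'
#' @param x input array `H x W x C` (a leading batch of 1 is implied).
#' @param out_channels output channels of the residual block.
#' @param seed optional initialization seed.
#' @return The block's output array `H x W x C' x 1`.
#' @export
residual_block <- function(x, out_channels, seed = NULL) {
  standalone(function(ctx, cin) reg_res(ctx, "blk", cin, out_channels),
             function(m, xt) f_res(m, "blk", xt, TRUE, 0.2), x, seed)
}

#' @rdname residual_block
#' @param rates ASPP dilation rates.
#' @param kernels_per_branch kernels per ASPP branch.
#' @export
aspp_block <- function(x, rates = c(1L, 2L, 3L, 4L), kernels_per_branch = 128L,
                       seed = NULL) {
  if (any(rates < 1L)) stop_retseg("dilation rates must be >= 1", "retseg_parameter_error")
  standalone(function(ctx, cin) reg_aspp(ctx, "blk", cin, rates, kernels_per_branch),
             function(m, xt) f_aspp(m, "blk", xt, rates, TRUE), x, seed)
}

#' @rdname residual_block
#' @export
residual_attention_block <- function(x, seed = NULL) {
  standalone(function(ctx, cin) reg_att(ctx, "blk", cin),
             function(m, xt) f_att(m, "blk", xt, TRUE), x, seed)
}

#' @rdname residual_block
#' @param target_size output side length; the input scale
#'   `target_size / nrow(x)` must be 1, 2 or 4.
#' @export
deep_supervision_head <- function(x, target_size, seed = NULL) {
  scale <- target_size / dim(x)[1]
  if (!scale %in% c(1, 2, 4))
    stop_retseg("input must be at scale 1, 2 or 4 of the target", "retseg_shape_error")
  n_up <- as.integer(log2(scale))
  mid <- rep(8L, n_up)
  standalone(function(ctx, cin) reg_head(ctx, "blk", cin, n_up, mid),
             function(m, xt) f_head(m, "blk", xt, n_up, TRUE), x, seed)
}
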