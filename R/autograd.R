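# Minimal reverse-mode automatic differentiation.
#
# Tensors are environments carrying a value, an accumulated gradient, the
# parent tensors and a backward closure. The network code builds a fresh
# graph per forward pass; parameters are long-lived leaf tensors whose
# gradients are read by the optimizer and zeroed between steps.

tg_env <- new.env(parent = emptyenv())
tg_env$counter <- 0

tg_new <- function(value, parents = list(), backward = NULL, is_param = FALSE) {
  e <- new.env(parent = emptyenv())
  tg_env$counter <- tg_env$counter + 1
  e$id <- tg_env$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$is_param <- is_param
  class(e) <- "tg_tensor"
  e
}

tg_param <- function(value) tg_new(value, is_param = TRUE)

tg_const <- function(value) tg_new(value)

# accumulate a gradient into tensor `t`
tg_acc <- function(t, g) {
  t$grad <- if (is.null(t$grad)) g else t$grad + g
  invisible(NULL)
}

tg_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# reverse-mode sweep from a scalar root
tg_backward <- function(root) {
  topo <- new.env(parent = emptyenv())
  topo$nodes <- vector("list", 64L)
  topo$n <- 0L
  seen <- new.env(parent = emptyenv())
  visit <- function(node) {
    key <- as.character(node$id)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    for (p in node$parents) visit(p)
    topo$n <- topo$n + 1L
    if (topo$n > length(topo$nodes))
      topo$nodes <- c(topo$nodes, vector("list", length(topo$nodes)))
    topo$nodes[[topo$n]] <- node
    invisible(NULL)
  }
  visit(root)
  root$grad <- array(1, dim = if (is.null(dim(root$value))) 1L else dim(root$value))
  for (i in rev(seq_len(topo$n))) {
    node <- topo$nodes[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node)
  }
  invisible(NULL)
}

# ---- ops -------------------------------------------------------------------

# dilated "same" convolution; x: [H,W,Cin,N], w: [k,k,Cin,Cout], b: [Cout]
tg_conv <- function(x, w, b, dilation = 1L) {
  v <- cpp_conv2d_fwd(x$value, w$value, b$value, as.integer(dilation))
  tg_new(v, list(x, w, b), function(node) {
    gr <- cpp_conv2d_bwd(x$value, w$value, node$grad, as.integer(dilation))
    tg_acc(x, gr$dx); tg_acc(w, gr$dw); tg_acc(b, gr$db)
  })
}

# transposed convolution, kernel 2, stride 2 (doubles H and W)
tg_convt <- function(x, w, b) {
  v <- cpp_convt2_fwd(x$value, w$value, b$value)
  tg_new(v, list(x, w, b), function(node) {
    gr <- cpp_convt2_bwd(x$value, w$value, node$grad)
    tg_acc(x, gr$dx); tg_acc(w, gr$dw); tg_acc(b, gr$db)
  })
}

# 2x2 max pooling, stride 2
tg_pool <- function(x) {
  fw <- cpp_maxpool2_fwd(x$value)
  xdim <- dim(x$value)
  tg_new(fw$y, list(x), function(node) {
    tg_acc(x, cpp_maxpool2_bwd(node$grad, fw$idx, as.integer(xdim)))
  })
}

tg_relu <- function(x) {
  keep <- x$value > 0
  tg_new(x$value * keep, list(x), function(node) tg_acc(x, node$grad * keep))
}

tg_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  tg_new(s, list(x), function(node) tg_acc(x, node$grad * s * (1 - s)))
}

# inverted dropout: scales kept activations by 1/(1-rate) during training
tg_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- (array(runif(length(x$value)), dim(x$value)) >= rate) / (1 - rate)
  tg_new(x$value * keep, list(x), function(node) tg_acc(x, node$grad * keep))
}

tg_add <- function(a, b) {
  tg_new(a$value + b$value, list(a, b), function(node) {
    tg_acc(a, node$grad); tg_acc(b, node$grad)
  })
}

tg_mul <- function(a, b) {
  tg_new(a$value * b$value, list(a, b), function(node) {
    tg_acc(a, node$grad * b$value); tg_acc(b, node$grad * a$value)
  })
}

tg_add_const <- function(x, k) {
  tg_new(x$value + k, list(x), function(node) tg_acc(x, node$grad))
}

# concatenate along the channel axis (3rd)
tg_concat <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  tg_new(v, list(a, b), function(node) {
    tg_acc(a, node$grad[, , seq_len(da[3]), , drop = FALSE])
    tg_acc(b, node$grad[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# spatial batch normalization over (H, W, N) per channel.
# `state` is an environment with running mean/var used at inference.
tg_bn <- function(x, gamma, beta, state, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    st <- cpp_bn_stats(x$value)
    mu <- st$mean
    v <- st$var
    state$rmean <- momentum * state$rmean + (1 - momentum) * mu
    state$rvar <- momentum * state$rvar + (1 - momentum) * v
  } else {
    mu <- state$rmean
    v <- state$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  y <- cpp_bn_fwd(x$value, gamma$value, beta$value, mu, invstd)
  tg_new(y, list(x, gamma, beta), function(node) {
    gr <- cpp_bn_bwd(x$value, node$grad, gamma$value, mu, invstd, training)
    tg_acc(x, gr$dx)
    tg_acc(gamma, gr$dgamma)
    tg_acc(beta, gr$dbeta)
  })
}

# class-weighted binary cross-entropy (scalar); weights come from the batch
# target itself: background weight 1 - alpha, vessel weight alpha = X- / m
tg_wbce <- function(yhat, y, eps = 1e-7) {
  bal <- class_balance(y)
  p <- clamp(yhat$value, eps, 1 - eps)
  inside <- yhat$value > eps & yhat$value < 1 - eps
  m <- bal$m
  a <- bal$alpha
  val <- -(1 / m) * sum(a * y * log(p) + (1 - a) * (1 - y) * log(1 - p))
  tg_new(val, list(yhat), function(node) {
    dL <- -(1 / m) * (a * y / p - (1 - a) * (1 - y) / (1 - p)) * inside
    tg_acc(yhat, as.numeric(node$grad) * dL)
  })
}

# weighted sum of scalar tensors: sum_i weights[i] * tensors[[i]]
tg_wsum <- function(tensors, weights) {
  val <- 0
  for (i in seq_along(tensors)) val <- val + weights[i] * tensors[[i]]$value
  tg_new(val, tensors, function(node) {
    for (i in seq_along(tensors))
      tg_acc(tensors[[i]], as.numeric(node$grad) * weights[i])
  })
}
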