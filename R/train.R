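#' Training configuration
#'
#' Defaults follow the published protocol: batch size 20, 500 epochs,
#' learning rate 0.001, Adam. The deep-supervision weight follows
#' `beta = 1 - epoch/epochs` (see [loss_schedule()]).
#'
#' @param batch_size patches per gradient step.
#' @param epochs total training epochs.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is provided.
#' @param seed integer; fixes initialization, shuffling, augmentation and
#'   dropout.
#' @param augment re-augment every patch each epoch.
#' @param loss_mode `"default"` (beta weights the supervision losses only) or
#'   `"strict"` (beta weights all four components).
#' @param val_fraction fraction of patches held out for per-epoch validation
#'   loss logging (0 disables the split; early stopping is never applied).
#' @param crop_min_frac augmentation crop bound, see [augment_patch()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 20L, epochs = 500L, learning_rate = 0.001,
                         optimizer = "adam", seed = 1L, augment = TRUE,
                         loss_mode = c("default", "strict"), val_fraction = 0.1,
                         crop_min_frac = 0.8) {
  loss_mode <- match.arg(loss_mode)
  if (batch_size < 1L || epochs < 1L || learning_rate <= 0)
    stop_retseg("invalid training configuration", "retseg_parameter_error")
  if (optimizer != "adam")
    stop_retseg("only the adam optimizer is provided", "retseg_parameter_error")
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), augment = augment,
                 loss_mode = loss_mode, val_fraction = val_fraction,
                 crop_min_frac = crop_min_frac),
            class = "train_config")
}

# Adam with optional L2 weight decay on convolution kernels (".w" entries)
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim2(p$value))),
       v = lapply(params, function(p) array(0, dim2(p$value))),
       t = 0L)
}

adam_step <- function(params, state, lr, l2 = 0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (l2 > 0 && endsWith(nm, ".w")) g <- g + 2 * l2 * p$value
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    p$value <- p$value - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  state
}

# gather selected patches into [H, W, 1, n] input and target arrays,
# re-augmenting per epoch when requested
make_batch <- function(inputs, labels, idx, aug_seeds = NULL, crop_min_frac = 0.8) {
  w <- dim(inputs)[1]
  x <- array(0, c(w, w, 1L, length(idx)))
  y <- array(0, c(w, w, 1L, length(idx)))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (!is.null(aug_seeds)) {
      a <- augment_patch(inputs[, , i], labels[, , i], seed = aug_seeds[i],
                         crop_min_frac = crop_min_frac)
      x[, , 1L, j] <- a$patch
      y[, , 1L, j] <- a$label
    } else {
      x[, , 1L, j] <- inputs[, , i]
      y[, , 1L, j] <- labels[, , i]
    }
  }
  list(x = x, y = y)
}

loss_weights <- function(beta, mode) {
  if (mode == "default") c(beta, beta, beta, 1) else rep(beta, 4)
}

#' Train the segmentation network
#'
#' Runs Adam over shuffled mini-batches of labeled patches. Each epoch the
#' patches are re-augmented (random flips, right-angle rotation, crop), the
#' per-batch loss is the scheduled combination of four class-weighted binary
#' cross-entropies (three supervision heads plus the main output), and the
#' whole run is deterministic given `cfg$seed`.
#'
#' @param spec a [model_spec()].
#' @param patches a `patch_set` with labels (see [extract_patches()]), a list
#'   of such sets, or a list with `inputs`/`labels` arrays.
#' @param cfg a [train_config()].
#' @param out_dir optional directory for `final.rds` / `best.rds` checkpoints
#'   and `run_log.csv`.
#' @param verbose print one line per epoch.
#' @return List with `model` (trained), `run_log` (one row per epoch: beta,
#'   the four loss components, the composed total, validation loss) and
#'   `best_epoch` (lowest main-output loss).
#' @export
train_model <- function(spec, patches, cfg = train_config(), out_dir = NULL,
                        verbose = FALSE) {
  pl <- collect_patches(patches)
  if (is.null(pl$labels))
    stop_retseg("training patches must carry labels", "retseg_data_error")
  n <- dim(pl$inputs)[3]
  set.seed(cfg$seed)
  model <- build_model(spec)
  opt <- adam_init(model$params)
  val_idx <- integer(0)
  if (cfg$val_fraction > 0 && n >= 10L)
    val_idx <- sample.int(n, max(1L, floor(cfg$val_fraction * n)))
  train_idx <- setdiff(seq_len(n), val_idx)
  log <- vector("list", cfg$epochs)
  best <- list(epoch = NA_integer_, loss = Inf, ck = NULL)
  for (epoch in seq_len(cfg$epochs)) {
    beta <- beta_weight(loss_schedule(epoch - 1L, cfg$epochs))
    wts <- loss_weights(beta, cfg$loss_mode)
    aug_seeds <- if (cfg$augment) sample.int(2^31 - 1, n) else NULL
    order_idx <- sample(train_idx)
    comps <- matrix(0, 0, 4)
    totals <- numeric(0)
    for (b0 in seq(1L, length(order_idx), by = cfg$batch_size)) {
      idx <- order_idx[b0:min(b0 + cfg$batch_size - 1L, length(order_idx))]
      bt <- make_batch(pl$inputs, pl$labels, idx, aug_seeds, cfg$crop_min_frac)
      g <- model_graph(model, tg_const(bt$x), training = TRUE)
      ls <- c(lapply(g$heads, tg_wbce, y = bt$y), list(tg_wbce(g$main, bt$y)))
      total <- tg_wsum(ls, wts)
      tg_backward(total)
      opt <- adam_step(model$params, opt, cfg$learning_rate, spec$l2_coeff)
      tg_zero_grad(model$params)
      comps <- rbind(comps, vapply(ls, function(l) l$value, numeric(1)))
      totals <- c(totals, total$value)
    }
    val_loss <- NA_real_
    if (length(val_idx) > 0) {
      bt <- make_batch(pl$inputs, pl$labels, val_idx)
      g <- model_graph(model, tg_const(bt$x), training = FALSE)
      val_loss <- weighted_bce(bt$y, g$main$value)
    }
    cm <- colMeans(comps)
    log[[epoch]] <- data.frame(epoch = epoch, beta = beta,
                               loss1 = cm[1], loss2 = cm[2], loss3 = cm[3],
                               loss4 = cm[4], total = mean(totals),
                               val_loss = val_loss)
    if (cm[4] < best$loss) {
      best$loss <- cm[4]
      best$epoch <- epoch
      best$ck <- list(params = lapply(model$params, function(p) p$value),
                      states = lapply(model$states, as.list))
    }
    if (verbose)
      message(sprintf("epoch %d/%d beta=%.3f loss4=%.4f total=%.4f",
                      epoch, cfg$epochs, beta, cm[4], mean(totals)))
  }
  run_log <- do.call(rbind, log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(model, file.path(out_dir, "final.rds"))
    bm <- restore_snapshot(spec, best$ck)
    save_checkpoint(bm, file.path(out_dir, "best.rds"))
    utils::write.csv(run_log, file.path(out_dir, "run_log.csv"), row.names = FALSE)
  }
  list(model = model, run_log = run_log, best_epoch = best$epoch,
       best_model = restore_snapshot(spec, best$ck))
}

restore_snapshot <- function(spec, ck) {
  model <- build_model(spec, seed = 1L)
  for (nm in names(ck$params)) model$params[[nm]]$value <- ck$params[[nm]]
  for (nm in names(ck$states)) {
    model$states[[nm]]$rmean <- ck$states[[nm]]$rmean
    model$states[[nm]]$rvar <- ck$states[[nm]]$rvar
  }
  model
}

# normalize the accepted patch inputs to a single inputs/labels pair
collect_patches <- function(patches) {
  if (inherits(patches, "patch_set"))
    return(list(inputs = patches$inputs, labels = patches$labels))
  if (is.list(patches) && !is.null(patches$inputs))
    return(list(inputs = patches$inputs, labels = patches$labels))
  if (is.list(patches) && all(vapply(patches, inherits, logical(1), "patch_set"))) {
    inputs <- do.call(abind3, lapply(patches, `[[`, "inputs"))
    labs <- lapply(patches, `[[`, "labels")
    labels <- if (any(vapply(labs, is.null, logical(1)))) NULL
              else do.call(abind3, labs)
    return(list(inputs = inputs, labels = labels))
  }
  stop_retseg("unrecognized patch collection", "retseg_data_error")
}

# bind 3-d arrays along the third axis
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], n))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[3]
    out[, , at + seq_len(k)] <- x
    at <- at + k
  }
  out
}
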