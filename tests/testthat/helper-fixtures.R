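# shared fixtures and independent oracles

# small synthetic fundus, cached per seed so several tests can reuse it
synth_cache <- new.env(parent = emptyenv())
small_fundus <- function(seed = 1L, height = 128L, width = 128L, n_roots = 3L) {
  key <- paste(seed, height, width, n_roots, sep = "_")
  if (is.null(synth_cache[[key]]))
    synth_cache[[key]] <- generate_fundus(
      synth_spec(height = height, width = width, n_roots = n_roots, seed = seed))
  synth_cache[[key]]
}

# brute-force AUC: fraction of concordant positive/negative pairs, ties 1/2
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# brute-force count of valid window placements along one dimension
placements_1d <- function(dim, window, step) {
  n <- 0L
  r <- 1L
  while (r + window - 1L <= dim) {
    n <- n + 1L
    r <- r + step
  }
  n
}

# direct dense convolution oracle (reflective borders), for tiny inputs only
conv2d_reflect_oracle <- function(m, K) {
  k <- nrow(K)
  r <- (k - 1) / 2
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      ii <- i + a - 1 - r
      jj <- j + b - 1 - r
      if (ii < 1) ii <- 2 - ii
      if (ii > H) ii <- 2 * H - ii
      if (jj < 1) jj <- 2 - jj
      if (jj > W) jj <- 2 * W - jj
      s <- s + K[a, b] * m[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# small labeled patch set cut from synthetic images
small_patch_set <- function(n_images = 2L, seed0 = 1L) {
  sets <- lapply(seq_len(n_images), function(i) {
    im <- small_fundus(seed = seed0 + i - 1L)
    g <- preprocess_fundus(im)
    extract_patches(g$values, truth = im$truth, source_id = paste0("im", i))
  })
  retseg:::collect_patches(sets)
}
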