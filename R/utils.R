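# shared internal helpers

# round half away from zero (values here are always >= 0); base round() uses
# banker's rounding, which would map 127.5 -> 128 but 62.5 -> 62
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derive a child seed below 2^31 from a base seed and stream labels
# (labels may be integers or short strings)
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(seed, ...), function(p) {
    if (is.character(p)) utf8ToInt(p) else as.numeric(p)
  }))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

is_binary <- function(x) all(x %in% c(0, 1))

stop_retseg <- function(msg, class) {
  stop(structure(class = c(class, "retseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
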