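# Shared internal helpers: error constructors, rounding, seed mixing.

stop_dermtex <- function(message, class) {
  rlang::abort(message, class = c(class, "dermtex_error"))
}

# Round half away from zero (base round() rounds half to even), then clip to
# [0, 255]. Deterministic integer planes make descriptor tests bit-exact.
round_clip_255 <- function(x) {
  r <- trunc(x + sign(x) * 0.5)
  r[r < 0] <- 0
  r[r > 255] <- 255
  r
}

# Mix a top-level seed with stream identifiers into a 32-bit-safe seed so
# every randomised stage is independently reproducible.
mix_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
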