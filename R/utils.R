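#' Derive a reproducible integer seed from a master seed and labels
#'
#' Hashes a master seed together with an arbitrary sequence of labels
#' (stage names, participant ids, trial indices, ...) into a 31-bit
#' integer suitable for `set.seed()`. The same inputs always map to the
#' same seed, so independent random streams can be carved out of one
#' master seed without consuming each other's draws.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "|")
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (code in utf8ToInt(labels)) {
    s <- (s * 31 + code) %% m
  }
  as.integer(s)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG state afterwards. seed = NULL runs under the ambient state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rms <- function(x) sqrt(mean(x^2))

# Half-open interval membership [lo, hi) on a numeric axis, robust to
# floating-point representation of regular time grids.
in_window <- function(t, window, eps = 1e-9) {
  t >= window[1] - eps & t < window[2] - eps
}
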