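# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed-splitting: one master seed yields `n` independent
# sub-seeds (all < 2^31) used by the stochastic stages in a fixed order.
seed_stream <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Trapezoid quadrature weights for a (possibly non-uniform) grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("grid needs at least 2 points", call. = FALSE)
  d <- diff(x)
  c(d[1L], d[-1L] + d[-(n - 1L)], d[n - 1L]) / 2
}

trapz <- function(x, y) sum(trapezoid_weights(x) * y)

`%||%` <- function(a, b) if (is.null(a)) b else a

format_p <- function(p) ifelse(p < 0.001, "<0.001", formatC(p, digits = 3, format = "f"))
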