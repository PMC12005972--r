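# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are reproducible without side effects.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# min-max scale a numeric vector to [0, 1]; constant vectors map to 0 by
# convention and are reported via the "degenerate" attribute.
minmax_scale <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single number >= %s", name, min), call. = FALSE)
  }
  invisible(TRUE)
}
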