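#' @keywords internal
"_PACKAGE"

# Run expr with a local RNG state; NULL seed leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one master seed into per-stage / per-iteration
# seeds, kept inside the 32-bit integer range.
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + as.double(k) * 9973 + 1) %% 2147483647)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a positive integer count", name), call. = FALSE)
  invisible(as.integer(x))
}
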