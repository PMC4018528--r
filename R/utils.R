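`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Logarithmically spaced fold grid
#'
#' Builds the default grid used by the parameter searches: `n` points spaced
#' evenly in log10 between the range limits, with any `include` values
#' injected as exact grid nodes so that reference optima are representable.
#'
#' @param lower,upper positive range limits (fold units).
#' @param n number of log-spaced points.
#' @param include numeric values inserted as additional nodes (values outside
#'   the range are dropped).
#' @return sorted vector of unique fold values.
#' @export
fold_grid <- function(lower, upper, n = 25, include = numeric()) {
  stopifnot(lower > 0, upper >= lower, n >= 2)
  g <- 10^seq(log10(lower), log10(upper), length.out = n)
  inc <- include[include >= lower & include <= upper]
  sort(unique(c(g, inc)))
}
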