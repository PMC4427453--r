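#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with sprintf formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# checks x is a single finite number
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# canonical unordered pair: i <= j columnwise
order_pairs <- function(i, j) {
  list(i = pmin(i, j), j = pmax(i, j))
}

# unique string key for an unordered id pair
pair_key <- function(i, j) {
  o <- order_pairs(i, j)
  paste(o$i, o$j, sep = "_")
}
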