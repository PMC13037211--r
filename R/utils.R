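#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with any number of integer tags into a new seed in
#' \code{[1, 2^31 - 2]}. Used throughout the package to give every
#' permutation, simulation and generator its own deterministic substream, so
#' results do not depend on the order in which components are evaluated and
#' extending a grid never changes draws already made.
#'
#' @param master integer master seed.
#' @param ... integer tags identifying the substream (e.g. a permutation
#'   index, an alpha-grid position).
#' @return a single integer seed.
#' @export
#' @examples
#' deriveSeed(1L, 5L) != deriveSeed(1L, 6L)
deriveSeed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(unlist(list(...), use.names = FALSE)))
  if (anyNA(parts)) stop("seed components must be non-missing numbers")
  s <- 0
  # multiplier small enough that s * 69069 + p stays exact in double precision
  for (p in parts) s <- (s * 69069 + abs(p)) %% 2147483629
  as.integer(s %% 2147483645 + 1)
}

# Run expr under a local RNG state seeded with `seed`; restores the caller's
# RNG stream afterwards so library calls never perturb user code.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Lightweight logging: diagnostics go to the message stream, never stdout.
hnpLog <- function(fmt, ...) message(sprintf(fmt, ...))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# symbols from a WeightedProteinSet or a plain character vector
.asSymbols <- function(x) {
  if (methods::is(x, "WeightedProteinSet")) proteins(x) else as.character(x)
}
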