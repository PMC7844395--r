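#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic component of the package draws its random numbers under a
#' sub-seed derived from the user's master seed and a string label (plus
#' optional integer counters). The derivation is a simple multiplicative hash
#' reduced modulo a Mersenne prime below 2^31, so sub-streams for different
#' components are decoupled: adding one more disease or permutation never
#' perturbs the draws of another.
#'
#' @param seed integer master seed.
#' @param ... labels: character scalars and/or integer counters, hashed in
#'   order.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  p <- 2147483629  # largest prime < 2^31 - 18
  h <- as.numeric(seed) %% p
  for (part in list(...)) {
    if (is.character(part)) {
      codes <- utf8ToInt(paste(part, collapse = "\r"))
    } else {
      codes <- as.numeric(part)
    }
    for (v in codes) {
      h <- (h * 131 + (v %% p) + 17) %% p
    }
  }
  as.integer(h)
}

# run expr under a derived seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
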