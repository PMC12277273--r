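#' Seed R's RNG locally
#'
#' Sets the RNG seed for the calling frame and restores the previous
#' RNG state when that frame exits, so seeded package functions do not
#' disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param envir Frame whose exit restores the state.
#' @return Invisibly, the seed.
#' @export
local_seed <- function(seed, envir = parent.frame()) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  restore <- function() {
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
  do.call(on.exit, list(substitute(restore(), list(restore = restore)),
                        add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}

# derive a named sub-seed below 2^31 from a base seed, so independent
# stages (mineralization, velocities, thermostat) use independent streams
derive_seed <- function(base_seed, stream) {
  x <- as.double(base_seed)
  for (ch in utf8ToInt(stream)) x <- (x * 69069 + ch) %% 2147483647
  as.integer(max(1, x))
}
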