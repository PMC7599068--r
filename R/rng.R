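#' Derive a reproducible sub-seed from a master seed
#'
#' Every generator and sampler in the package draws its randomness from a
#' sub-seed derived deterministically from a master seed and a text label, so
#' that one master seed reproduces an entire pipeline run while the stages
#' stay statistically independent of each other.
#'
#' @param seed Master seed (single integer).
#' @param label Character label naming the consumer (e.g. `"occupancy/wt"`).
#' @return A single integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' split_seed(1, "occupancy") != split_seed(1, "okr")
#' @export
split_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed), length(label) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# run expr with a local RNG state seeded from (seed, label); restores the
# caller's .Random.seed afterwards
with_subseed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(split_seed(seed, label))
  expr
}
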