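#' Derive reproducible child seeds from a master seed
#'
#' Expands one master seed into `n` independent integer seeds so that each
#' analysis stage gets its own deterministic random stream. The expansion is
#' itself seeded, so the whole cascade is reproducible from the master seed.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
seed_streams <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  withr::with_seed(as.integer(master),
                   sample.int(.Machine$integer.max - 1L, n))
}

# Run expr under a seed without disturbing the caller's RNG state.
# A NULL seed means "use the current stream as-is".
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
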