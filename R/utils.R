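#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded operations do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic sequence of sub-seeds from a master seed
#'
#' Used so every stochastic stage (cohort draws, CV folds, MCCV splits,
#' permutations) can be replayed in isolation from one master seed.
#'
#' @param master Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  with_seed(as.integer(master), sample.int(2147483645L, n, replace = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal integral on an ascending x grid
.trapz <- function(x, y) pracma::trapz(x, y)
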