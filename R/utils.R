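#' @keywords internal
"_PACKAGE"

# days per month used at the reporting layer
DAYS_PER_MONTH <- 30.4375

#' Spawn reproducible sub-seeds from a master seed
#'
#' Derives `n` independent substream seeds from one master seed so that
#' pipeline stages (cohort generation, exposure assignment, outcome
#' simulation, bootstrap, ...) can be re-run independently while the whole
#' run stays reproducible under a single `--seed`.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds to draw.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

invlogit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

# lognormal (meanlog, sdlog) matching a target arithmetic mean and SD
lognormal_from_moments <- function(mean, sd) {
  assert_positive(mean, "mean")
  stopifnot(sd >= 0)
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}
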