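#' Derive a stage seed from a master seed
#'
#' Counter-based seed fan-out: every stochastic stage of a pipeline draws its
#' own seed as a pure function of the master seed and a stage counter, so
#' that inserting a new stage never perturbs the random streams of earlier
#' stages.
#'
#' @param master Integer master seed.
#' @param counter Non-negative integer stage counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1,
            is.numeric(counter), length(counter) == 1, counter >= 0)
  # affine mix modulo the Mersenne prime 2^31 - 1, kept in double precision
  m <- 2147483647
  x <- (abs(master) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (counter %% m) * 69621) %% m
  x <- (x * 16807) %% m
  as.integer(x %% (m - 1) + 1)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.  `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
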