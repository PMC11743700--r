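`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Deterministically maps a master seed and a stream index to a new seed in
#' `[0, 2^31 - 2]`. Used so that every stochastic unit of work (a scan, a
#' k-means replicate, a permutation test) owns an independent seed derived
#' from the master seed, making results reproducible regardless of the order
#' in which units are generated. A fixed-multiplier congruential mix; not
#' cryptographic.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return a single integer seed.
#' @export
substream_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483629  # prime below 2^31
  s <- (as.double(master) %% m) * 48271 + (as.double(index) + 1) * 1299721
  as.integer(s %% m)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Unit-normalize the rows of a matrix; errors on zero rows.
normalize_rows <- function(x, what = "row") {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("zero-norm ", what, " cannot be normalized")
  x / nrm
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
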