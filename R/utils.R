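# internal helpers shared across modules

#' Round half away from zero at a fixed number of decimals
#'
#' Printed fixed-precision values (HRMS calcd m/z, LE, LLE, hit rates) use
#' conventional half-up rounding, not the IEEE round-half-even of [round()].
#'
#' @param x numeric vector
#' @param digits non-negative integer, decimals to keep
#' @return numeric vector rounded half-up (half away from zero for negatives)
#' @examples
#' round_half_up(0.5, 0)   # 1, where round(0.5) gives 0
#' round_half_up(2.345, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  # nudge by a relative epsilon so values that are exactly .5 at the printed
  # precision (up to binary representation) round up, not to even
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# deterministic sub-seed for a named random stream, < 2^31
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  (abs(as.integer(seed)) * 7919L + as.integer(h %% 104729)) %% 2147483647L
}

# evaluate expr with a temporary RNG state seeded from (seed, stream)
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# collapse a list of reason vectors into ";"-joined strings for reports
collapse_reasons <- function(reasons) {
  vapply(reasons, function(r) paste(r, collapse = ";"), character(1))
}
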