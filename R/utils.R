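#' @importFrom stats median p.adjust pchisq phyper runif rmultinom setNames
#' @importFrom utils read.delim write.table head
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed; stays below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Round half away from zero at a fixed number of decimals
#'
#' Base `round()` rounds half to even; printed tables in this field use
#' conventional half-up rounding, so percentages and ages are reported with
#' this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Length of the intersection of closed 1-based intervals [s1,e1] and [s2,e2].
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
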