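#' @keywords internal
"_PACKAGE"

# Argument checking helpers -------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop_invalid("`%s` must be a single integer >= %d (got %s)",
                 name, min, deparse(x))
  }
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop_invalid("`%s` must be a finite scalar in [%s, %s]",
                 name, format(lower), format(upper))
  }
  as.numeric(x)
}

#' Derive a stage seed from a base seed
#'
#' All randomness in the package flows through explicit seeds.  Stage seeds
#' are derived deterministically from a single base seed with a fixed offset
#' per stage so that no stage reads the global RNG state implicitly, and so
#' that derived seeds stay inside the 32-bit integer range.
#'
#' @param seed base integer seed.
#' @param offset non-negative integer offset identifying the stage.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset = 0L) {
  seed <- check_count(seed, "seed", min = 0L)
  as.integer((as.double(seed) * 7919 + 104729 * as.double(offset)) %%
               2147483647)
}

# Column-wise standardization with population (1/n) variance
scale_pop <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sd_pop <- sqrt(colMeans(xc^2))
  if (any(sd_pop == 0)) {
    bad <- which(sd_pop == 0)
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop_invalid("zero-variance column(s): %s", paste(nm, collapse = ", "))
  }
  sweep(xc, 2L, sd_pop, "/")
}
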