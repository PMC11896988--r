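# Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer tags
#' (case index, repeat index, spot index, ...) so that every random stage of
#' a study draws from an independent, reproducible stream. The result is
#' always a valid 32-bit seed in `[0, 2^31 - 1)`.
#'
#' @param master integer master seed.
#' @param ... integer tags, mixed in order.
#' @return a single integer seed.
#' @export
seed_chain <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- as.numeric(master) %% m
  for (tag in list(...)) {
    s <- (s * 48271 + as.numeric(tag) + 1) %% m
  }
  as.integer(s)
}

# stopifnot() with a formatted message
.check <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# coerce a point / set of points to an n x 3 matrix
.as_points <- function(p) {
  if (is.matrix(p)) {
    .check(ncol(p) == 3L, "points must have 3 columns, got %d", ncol(p))
    p
  } else {
    .check(length(p) == 3L, "a point must have 3 coordinates, got %d", length(p))
    matrix(as.numeric(p), nrow = 1L)
  }
}

# root-mean-square deviation about the mean (population form, as used for
# repeat variability throughout)
.rms <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
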