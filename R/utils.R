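# Shared internal helpers.

# Default seed used whenever a caller omits one; any fixed value works, it
# only has to be stable across runs.
.default_seed <- 20170912L

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moving away from zero
#' (the convention used in printed diet-composition tables), unlike
#' [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(2.345, 2)  # 2.35
#' round(2.345, 2)          # 2.34 on most platforms
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  z <- abs(x) * m
  # nudge by one part in 1e12 so values like 1.005 * 100, stored just below
  # the half boundary, still round up
  sign(x) * floor(z + 0.5 + z * 1e-12) / m
}

# Squash whitespace and case so free-text taxon labels compare reliably.
normalize_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

stopifnot_simplex <- function(p, tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > tol)
    stop("'p' must be a probability vector on the simplex (nonnegative, summing to 1)",
         call. = FALSE)
  invisible(TRUE)
}

# Dirichlet draw via normalized gammas; alpha recycled to length k.
rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = rep_len(alpha, k), rate = 1)
  if (sum(g) == 0) g <- rep(1, k)  # guard against underflow at tiny alpha
  g / sum(g)
}

# Central quantile interval of draws at the given coverage level.
central_interval <- function(x, level) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
}
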