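#' Wrap angles into (-pi, pi]
#'
#' Maps arbitrary angles onto the principal interval used throughout the
#' package. The right end is closed: `wrap_phase(pi)` and `wrap_phase(-pi)`
#' both return `pi`.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length, each value in (-pi, pi].
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
wrap_phase <- function(x) {
  r <- x %% (2 * pi)
  ifelse(r > pi, r - 2 * pi, r)
}

#' Circular mean of a set of angles
#'
#' Angle of the mean resultant vector. When the resultant length is below
#' `tol` (e.g. an antipodal pair) the mean direction is undefined and an
#' error is raised rather than returning an arbitrary angle.
#'
#' @param theta Angles in radians.
#' @param tol Minimum resultant length for a defined mean.
#' @return Angle in (-pi, pi].
#' @export
circ_mean <- function(theta, tol = 1e-9) {
  if (length(theta) == 0L) stop("circ_mean: empty input")
  z <- mean(exp(1i * theta))
  if (Mod(z) <= tol) stop("undefined circular mean: resultant length <= ", tol)
  wrap_phase(Arg(z))
}

#' Resultant length of a set of angles
#'
#' @param theta Angles in radians.
#' @return Value in [0, 1].
#' @export
resultant_length <- function(theta) {
  if (length(theta) == 0L) stop("resultant_length: empty input")
  Mod(mean(exp(1i * theta)))
}

#' Signed circular difference a - b wrapped into (-pi, pi]
#'
#' @param a,b Angles in radians.
#' @return Wrapped differences.
#' @export
circ_diff <- function(a, b) wrap_phase(a - b)

#' Circular correlation between two angle series
#'
#' Fisher-Lee T-linear association, computed in its pairwise (mean-free)
#' form `sum_{i<j} sin(a_i - a_j) sin(b_i - b_j)` normalized by the
#' corresponding sums of squares, via an O(n) factorization. Unlike
#' mean-centered variants this is well defined even when the marginal
#' phase distributions are nearly uniform (as hours of oscillation phase
#' are), and it is invariant under adding a constant to either series.
#'
#' @param a,b Equal-length angle vectors in radians.
#' @return Correlation in [-1, 1]; 1 when `b = a + const`.
#' @export
circ_corr <- function(a, b) {
  if (length(a) != length(b)) stop("circ_corr: length mismatch")
  n <- length(a)
  num <- 2 * (sum(sin(a) * sin(b)) * sum(cos(a) * cos(b)) -
                sum(sin(a) * cos(b)) * sum(cos(a) * sin(b)))
  den_a <- (n^2 - Mod(sum(exp(2i * a)))^2) / 2
  den_b <- (n^2 - Mod(sum(exp(2i * b)))^2) / 2
  if (den_a <= 0 || den_b <= 0)
    stop("circ_corr: degenerate (constant) phase series")
  num / sqrt(den_a * den_b)
}

# von Mises sampler (Best & Fisher 1979 rejection method); kappa = 0 draws
# uniformly on the circle. Used by the synthetic generator for partial phase
# resets at trial onsets.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("rvonmises: kappa must be >= 0")
  if (kappa == 0) return(wrap_phase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_phase(mu + out)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL runs the code on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
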