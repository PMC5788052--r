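#' Wrap angles to the half-open interval [-pi, pi)
#'
#' All feature values, responses and errors in retropop live on the circle
#' `[-pi, pi)`, with one full period of the native feature space (360 deg for
#' colour and motion direction, 180 deg for orientation) mapped onto it.
#' The boundary convention is half-open: `wrap_angle(pi)` returns `-pi`.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length, congruent to `x` modulo `2*pi`,
#'   in `[-pi, pi)`.
#' @examples
#' wrap_angle(3 * pi / 2)   # -pi/2
#' wrap_angle(pi)           # -pi (half-open boundary)
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric angles.", class = "retropop_invalid_angle")
  }
  x - 2 * pi * floor((x + pi) / (2 * pi))
}

#' Signed circular distance
#'
#' The angular deviation `a - b` wrapped to `[-pi, pi)`; the recall error of a
#' trial is `circ_dist(response, target)`.
#'
#' @param a,b Numeric vectors of angles in radians (recycled).
#' @return Signed deviations with magnitude at most `pi`.
#' @examples
#' circ_dist(pi / 4, -pi / 4)          # pi/2
#' circ_dist(-pi + 0.1, pi - 0.1)      # 0.2 (crosses the wrap point)
#' @export
circ_dist <- function(a, b) wrap_angle(a - b)

#' Circular mean direction and resultant length
#'
#' Direction of the (optionally weighted) resultant vector of a set of angles,
#' and the mean resultant length. Used by the maximum a posteriori decoder,
#' where spike counts act as weights on preferred values.
#'
#' @param angles Numeric vector of angles in radians (at least one).
#' @param weights Optional non-negative weights, not all zero.
#' @return A list with `direction` (radians in `[-pi, pi)`, `NA` if the
#'   resultant is degenerate), `resultant_length` (in `[0, 1]`), and
#'   `degenerate` (`TRUE` when the resultant length is numerically zero, e.g.
#'   for antipodal pairs, so the direction is undefined).
#' @examples
#' circ_mean(c(0, pi / 2))   # direction pi/4, length cos(pi/4)
#' circ_mean(c(0, pi))       # degenerate: antipodal cancellation
#' @export
circ_mean <- function(angles, weights = NULL) {
  if (length(angles) < 1L) abort("`angles` must contain at least one angle.")
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(weights) != length(angles) || any(weights < 0)) {
    abort("`weights` must be non-negative and match `angles` in length.")
  }
  tot <- sum(weights)
  if (tot <= 0) abort("`weights` must not all be zero.")
  C <- sum(weights * cos(angles))
  S <- sum(weights * sin(angles))
  r <- sqrt(C^2 + S^2) / tot
  degenerate <- r < 1e-12
  list(
    direction = if (degenerate) NA_real_ else wrap_angle(atan2(S, C)),
    resultant_length = r,
    degenerate = degenerate
  )
}

#' Von Mises density
#'
#' Density of the von Mises distribution VM(`mu`, `kappa`) evaluated at `x`,
#' computed with exponentially scaled Bessel functions so that large
#' concentrations do not overflow.
#'
#' @param x Numeric vector of angles (radians).
#' @param kappa Concentration parameter, `kappa >= 0` (`kappa = 0` is the
#'   circular uniform density `1/(2*pi)`).
#' @param mu Mean direction (radians), default 0.
#' @param log Return the log density?
#' @return Numeric vector of (log) densities.
#' @examples
#' vm_pdf(0, kappa = 0)    # 1/(2*pi)
#' vm_pdf(0, kappa = 2)    # exp(2) / (2*pi*besselI(2, 0))
#' @export
vm_pdf <- function(x, kappa, mu = 0, log = FALSE) {
  stopifnot(length(kappa) == 1L, kappa >= 0, is.finite(kappa))
  ld <- kappa * cos(x - mu) - log(2 * pi) - log_bessel_I0(kappa)
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. With `kappa = 0` draws are circular uniform.
#'
#' @param n Number of draws.
#' @param kappa Concentration (`>= 0`).
#' @param mu Mean direction (radians).
#' @return `n` angles in `[-pi, pi)`.
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  stopifnot(length(kappa) == 1L, kappa >= 0, is.finite(kappa))
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    k <- n - got
    u1 <- runif(k); u2 <- runif(k); u3 <- runif(k)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(ok)
    if (nk > 0L) {
      th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      out[(got + 1L):(got + nk)] <- th
      got <- got + nk
    }
  }
  wrap_angle(mu + out)
}

# ---- internal Bessel helpers (safe at large argument) ----------------------

log_bessel_I0 <- function(k) log(besselI(k, 0, expon.scaled = TRUE)) + k

# mean resultant length A(kappa) = I1/I0 of a von Mises distribution
vm_A <- function(k) {
  ifelse(k < 1e-8, k / 2,
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE))
}

# derivative A'(kappa) = 1 - A/kappa - A^2
vm_A_prime <- function(k) {
  a <- vm_A(k)
  ifelse(k < 1e-8, 0.5, 1 - a / k - a^2)
}

# inverse of A(): Newton iterations from the Fisher starting approximation
vm_A_inv <- function(r) {
  stopifnot(all(r >= 0), all(r < 1))
  k <- ifelse(r < 0.53, 2 * r + r^3 + 5 * r^5 / 6,
       ifelse(r < 0.85, -0.4 + 1.39 * r + 0.43 / (1 - r),
              1 / (r^3 - 4 * r^2 + 3 * r)))
  k <- pmax(k, 1e-9)
  for (i in 1:30) k <- pmax(k - (vm_A(k) - r) / vm_A_prime(k), 1e-12)
  k
}

# circular standard deviation of a density tabulated on an evenly spaced grid
grid_circ_sd <- function(grid, density) {
  w <- density / sum(density)
  r <- sqrt(sum(w * cos(grid))^2 + sum(w * sin(grid))^2)
  sqrt(-2 * log(r))
}
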