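# All angles are degrees in (-180, 180] at module boundaries; radians are used
# only transiently inside these kernels.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the principal interval
#'
#' Normalizes angles in degrees to the half-open interval (-180, 180], the
#' convention used throughout the package (a phase of exactly half a beat
#' period late is +180, never -180).
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each element in (-180, 180].
#' @examples
#' wrap_deg(c(-190, 540, 180, -180))
#' @export
wrap_deg <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Circular mean direction
#'
#' Argument of the mean resultant vector of unit vectors at each angle.
#'
#' @param phases_deg Numeric vector of angles in degrees (any range).
#' @return Mean direction in degrees, in (-180, 180].
#' @details Errors when the mean resultant length is below `1e-12`: the mean
#'   direction of a perfectly balanced sample (e.g. two antipodal angles) is
#'   undefined and silently returning a number would mask the degeneracy.
#' @seealso [vector_length()], [circ_sd_deg()]
#' @examples
#' circular_mean(c(170, -170)) # 180, not 0: the mean wraps
#' @export
circular_mean <- function(phases_deg) {
  stopifnot(is.numeric(phases_deg))
  if (length(phases_deg) < 1L) {
    stop("circular_mean() needs at least one phase", call. = FALSE)
  }
  th <- deg2rad(phases_deg)
  s <- mean(sin(th))
  c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < 1e-12) {
    stop("mean direction undefined: mean resultant length < 1e-12",
         call. = FALSE)
  }
  wrap_deg(rad2deg(atan2(s, c)))
}

#' Mean resultant vector length
#'
#' The modulus of the mean resultant vector, R-bar = |N^-1 sum exp(i theta)|,
#' a circular precision measure: 1 when all angles coincide, 0 under balanced
#' dispersion.
#'
#' @inheritParams circular_mean
#' @return Scalar in \[0, 1\].
#' @export
vector_length <- function(phases_deg) {
  stopifnot(is.numeric(phases_deg))
  if (length(phases_deg) < 1L) {
    stop("vector_length() needs at least one phase", call. = FALSE)
  }
  th <- deg2rad(phases_deg)
  r <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  min(r, 1) # guard against rounding spill above 1
}

#' Circular standard deviation
#'
#' `sqrt(-2 log R)` converted to degrees, the conventional dispersion measure
#' paired with the mean resultant length.
#'
#' @param r_bar Mean resultant length in (0, 1].
#' @return Circular SD in degrees (0 when `r_bar == 1`).
#' @export
circ_sd_deg <- function(r_bar) {
  stopifnot(is.numeric(r_bar), all(r_bar > 0), all(r_bar <= 1))
  rad2deg(sqrt(-2 * log(r_bar)))
}

# Bessel ratio A(kappa) = I1(kappa)/I0(kappa), the mean resultant length of a
# Von Mises with concentration kappa. Exponentially scaled Bessel functions
# keep this stable for large kappa.
bessel_ratio <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Maximum-likelihood Von Mises concentration
#'
#' Inverts the Bessel ratio A(kappa) = I1(kappa)/I0(kappa) at an observed mean
#' resultant length: the standard piecewise initial approximation (Fisher
#' 1993) followed by Newton refinement, so the round trip
#' `fit_kappa(bessel_ratio(kappa))` is accurate to well below 1e-6.
#'
#' @param r_bar Observed mean resultant length, in \[0, 1).
#' @param n Optional sample size. When supplied and `n <= 15`, the standard
#'   small-sample bias correction is applied to the ML estimate; the plain
#'   inversion is used otherwise (and always by internal callers such as the
#'   Watson-Williams correction and the trial simulator).
#' @return Concentration estimate `kappa >= 0`, capped at `1e5` (numerically
#'   indistinguishable from a point mass at that concentration).
#' @examples
#' fit_kappa(0)      # uniform: 0
#' fit_kappa(0.53)
#' @export
fit_kappa <- function(r_bar, n = NULL) {
  stopifnot(is.numeric(r_bar), length(r_bar) == 1L)
  if (r_bar < 0 || r_bar >= 1) {
    stop("r_bar must lie in [0, 1): r_bar = 1 implies infinite concentration",
         call. = FALSE)
  }
  if (r_bar == 0) return(0)
  kappa <- if (r_bar < 0.53) {
    2 * r_bar + r_bar^3 + 5 * r_bar^5 / 6
  } else if (r_bar < 0.85) {
    -0.4 + 1.39 * r_bar + 0.43 / (1 - r_bar)
  } else {
    1 / (r_bar^3 - 4 * r_bar^2 + 3 * r_bar)
  }
  kappa <- min(max(kappa, 1e-8), 1e5)
  # Newton steps on A(kappa) - r_bar; A'(kappa) = 1 - A/kappa - A^2
  for (i in 1:25) {
    a <- bessel_ratio(kappa)
    da <- 1 - a / kappa - a^2
    if (da <= 0) break
    step <- (a - r_bar) / da
    kappa_new <- min(max(kappa - step, 1e-10), 1e5)
    if (abs(kappa_new - kappa) < 1e-12 * (1 + kappa)) {
      kappa <- kappa_new
      break
    }
    kappa <- kappa_new
  }
  if (!is.null(n) && n <= 15) {
    kappa <- if (kappa < 2) max(kappa - 2 / (n * r_bar), 0)
             else kappa * (n - 1)^3 / (n^3 + n)
  }
  kappa
}

#' Von Mises random deviates
#'
#' Samples from the Von Mises distribution with mean direction `mu_deg`
#' (degrees) and concentration `kappa`, using the Best-Fisher (1979)
#' wrapped-Cauchy envelope rejection scheme; `kappa = 0` reduces to the
#' uniform distribution on the circle. Draws come from R's global RNG stream,
#' so results are reproducible under `set.seed()`.
#'
#' @param n Number of deviates.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration, `>= 0`.
#' @return Numeric vector of `n` angles in (-180, 180].
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0, is.finite(mu_deg))
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) {
    return(wrap_deg(stats::runif(n, -180, 180)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(ceiling((n - length(out)) * 1.3), 16L)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    f <- f[ok]
    if (length(f)) {
      u3 <- stats::runif(length(f))
      theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      out <- c(out, theta)
    }
  }
  wrap_deg(mu_deg + rad2deg(out[seq_len(n)]))
}

# Von Mises density ratio f(theta)/f(mu): the mode-normalized acceptance
# probability used by the trial simulator's rejection step. Equals 1
# everywhere when kappa = 0.
vm_accept_prob <- function(theta_deg, mu_deg, kappa) {
  exp(kappa * (cos(deg2rad(theta_deg - mu_deg)) - 1))
}
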