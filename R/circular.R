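#' Axial (180-degree periodic) circular statistics
#'
#' Nuclear orientations are axial data: an angle alpha and alpha + 180 degrees
#' describe the same orientation. All axial statistics here follow the standard
#' doubling construction: angles are doubled, analysed as ordinary circular
#' data, and mapped back to the axial scale.
#'
#' @param angle_deg numeric vector of angles in degrees.
#' @return `wrap_axial()` returns angles reduced to the canonical axial
#'   interval (-90, 90].
#' @examples
#' wrap_axial(c(95, -95, 180, 270))
#' @export
wrap_axial <- function(angle_deg) {
  r <- angle_deg %% 180
  ifelse(r > 90, r - 180, r)
}

#' @rdname wrap_axial
#' @return `axial_mean()` returns the axial circular mean in (-90, 90]
#'   (NA if the doubled resultant length is ~0, i.e. the mean is undefined).
#' @export
axial_mean <- function(angle_deg) {
  d <- 2 * angle_deg * pi / 180
  C <- mean(cos(d)); S <- mean(sin(d))
  if (sqrt(C^2 + S^2) < 1e-12) return(NA_real_)
  wrap_axial(0.5 * atan2(S, C) * 180 / pi)
}

#' @rdname wrap_axial
#' @return `axial_resultant()` returns the mean resultant length of the
#'   doubled angles, in [0, 1]; 1 means perfectly aligned, 0 axially uniform.
#' @export
axial_resultant <- function(angle_deg) {
  d <- 2 * angle_deg * pi / 180
  sqrt(mean(cos(d))^2 + mean(sin(d))^2)
}

#' Axial circular standard deviation
#'
#' Dispersion of axial angles: doubles the angles, computes the circular
#' standard deviation sqrt(-2 log Rbar) on the doubled scale, and halves it
#' back to the axial scale, in degrees. A perfectly (axially) uniform sample
#' has Rbar = 0 and infinite dispersion; this is returned as `Inf`.
#'
#' @param angle_deg numeric vector of angles in degrees (at least 2 values).
#' @return circular SD in degrees on the axial scale; `Inf` when undefined.
#' @examples
#' circular_sd(c(10, 10, 10))      # 0
#' circular_sd(c(45, -45))         # Inf: antipodal on the doubled circle
#' @export
circular_sd <- function(angle_deg) {
  if (length(angle_deg) < 2) stop("need at least 2 angles")
  rbar <- axial_resultant(angle_deg)
  if (rbar < 1e-12) return(Inf)
  sqrt(-2 * log(rbar)) / 2 * 180 / pi
}

# von Mises concentration giving a target axial circular SD.
# On the doubled scale the SD is s2 = 2 * sigma (radians), and the circular SD
# of a von Mises(kappa) is sqrt(-2 log A1(kappa)), A1 = I1/I0. Solve
# A1(kappa) = exp(-s2^2 / 2).
kappa_for_axial_sd <- function(sigma_deg) {
  if (sigma_deg < 0) stop("sigma_deg must be >= 0")
  if (sigma_deg == 0) return(Inf)
  if (!is.finite(sigma_deg)) return(0)
  s2 <- 2 * sigma_deg * pi / 180
  rbar <- exp(-s2^2 / 2)
  if (rbar < 1e-8) return(0)
  # beyond kappa ~ 1e4 the Bessel ratio loses accuracy; use the asymptotic
  # expansion A1(kappa) = 1 - 1/(2 kappa) - 1/(8 kappa^2) + O(kappa^-3)
  if (rbar > 1 - 6e-5) {
    d <- 1 - rbar
    return((1 + sqrt(1 + 2 * d)) / (4 * d))
  }
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  exp(stats::uniroot(function(t) a1(exp(t)) - rbar, c(-30, log(2e4)),
                     tol = 1e-12)$root)
}

# Von Mises sampler (Best & Fisher rejection scheme), vectorised in batches.
# kappa = 0 falls back to the uniform distribution on (-pi, pi].
rvonmises <- function(n, mu_rad, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi) + mu_rad)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, ceiling(1.2 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)))
  }
  mu_rad + out[seq_len(n)]
}

#' Sample axial angles from a wrapped distribution with given dispersion
#'
#' Draws orientations from an axial circular distribution with mean direction
#' `mu_deg` and axial circular SD `sigma_deg`. Internally a von Mises
#' distribution on the doubled angle 2*alpha is used, with concentration
#' chosen so that the axial circular SD of the samples equals `sigma_deg`;
#' the draws are halved and reduced to (-90, 90]. `sigma_deg = 0` returns
#' `mu_deg` exactly; `sigma_deg = Inf` gives axially uniform angles.
#'
#' @param n number of samples.
#' @param mu_deg mean orientation(s) in degrees, in (-90, 90]; recycled to
#'   length `n`.
#' @param sigma_deg target axial circular SD(s) in degrees (>= 0, may be
#'   `Inf`); recycled to length `n`.
#' @return numeric vector of `n` angles in (-90, 90].
#' @examples
#' set.seed(1)
#' circular_sd(sample_axial_angle(1e4, 0, 25))  # close to 25
#' @export
sample_axial_angle <- function(n, mu_deg, sigma_deg) {
  if (any(sigma_deg < 0)) stop("sigma_deg must be >= 0")
  if (length(mu_deg) > 1 || length(sigma_deg) > 1) {
    mu_deg <- rep_len(mu_deg, n); sigma_deg <- rep_len(sigma_deg, n)
    return(vapply(seq_len(n), function(i)
      sample_axial_angle(1, mu_deg[i], sigma_deg[i]), numeric(1)))
  }
  if (sigma_deg == 0) return(rep(wrap_axial(mu_deg), n))
  kappa <- kappa_for_axial_sd(sigma_deg)
  if (!is.finite(kappa)) return(rep(wrap_axial(mu_deg), n))
  th <- rvonmises(n, 2 * mu_deg * pi / 180, kappa)
  wrap_axial(th / 2 * 180 / pi)
}

# Closed-form axial von Mises density (per degree) used as a test oracle:
# f(alpha) = exp(kappa * cos(2 (alpha - mu))) / (180 I0(kappa)).
axial_vonmises_density <- function(angle_deg, mu_deg, sigma_deg) {
  kappa <- kappa_for_axial_sd(sigma_deg)
  if (!is.finite(kappa)) stop("degenerate distribution (sigma = 0)")
  d <- 2 * (angle_deg - mu_deg) * pi / 180
  exp(kappa * (cos(d) - 1)) / (180 * besselI(kappa, 0, expon.scaled = TRUE))
}
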