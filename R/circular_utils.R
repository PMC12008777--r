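# Shared circular helpers (degrees in [0, 360) at the interfaces,
# radians internally).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

wrap_deg <- function(x) {
  y <- x %% 360
  y[y < 0] <- y[y < 0] + 360
  y
}

# circular distance on the degree circle, in [0, 180]
circ_dist_deg <- function(a, b) {
  d <- abs(wrap_deg(a) - wrap_deg(b)) %% 360
  pmin(d, 360 - d)
}

# mean resultant: returns list(R, mean_deg)
circ_resultant <- function(phases_deg) {
  th <- deg2rad(phases_deg)
  C <- mean(cos(th))
  S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mean_deg <- wrap_deg(rad2deg(atan2(S, C)))
  list(R = R, mean_deg = mean_deg)
}

# ratio of modified Bessel functions I1/I0 (mean resultant length of a
# von Mises with concentration kappa)
vm_A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# invert A1: kappa such that I1(k)/I0(k) = r
vm_A1inv <- function(r) {
  if (r < 0 || r >= 1) stop("mean resultant length must be in [0, 1)")
  if (r < 1e-8) return(0)
  stats::uniroot(function(k) vm_A1(k) - r, c(1e-8, 1e4), tol = 1e-10)$root
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler from a wrapped Cauchy envelope. Draws are
#' reproducible under `set.seed()`.
#'
#' @param n Number of draws.
#' @param mu_deg Circular mean in degrees.
#' @param kappa Concentration (> 0; 0 gives the uniform circle).
#' @return Angles in degrees, in [0, 360).
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- stats::runif(1)
      theta <- mu + sign(u3 - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  wrap_deg(rad2deg(out))
}

# von Mises CDF on [0, 2*pi) with mean mu (radians), by series; vectorized.
pvonmises_rad <- function(theta, mu, kappa, tol = 1e-10) {
  # integrate density numerically on a fine grid (robust for all kappa)
  ng <- 4096L
  grid <- seq(0, 2 * pi, length.out = ng + 1L)
  dens <- exp(kappa * cos(grid - mu) - kappa) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  cw <- cumsum((dens[-1] + dens[-(ng + 1L)]) / 2 * diff(grid))
  cdf <- c(0, cw / cw[ng])
  stats::approx(grid, cdf, xout = theta, rule = 2)$y
}

# maximum-likelihood von Mises fit: list(mu_deg, kappa)
vm_fit <- function(phases_deg) {
  res <- circ_resultant(phases_deg)
  list(mu_deg = res$mean_deg, kappa = vm_A1inv(min(res$R, 1 - 1e-12)))
}
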