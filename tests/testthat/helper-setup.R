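# Shared fixtures: the bundled tables, the default source model, and the
# Klein-Nishina density used by quadrature oracles.

xs_tabs <- load_xs_tables()
default_model <- source_model()

kn_density <- function(cos_theta, energy) {
  k <- energy / 0.51099895
  r <- 1 / (1 + k * (1 - cos_theta))
  r^2 * (r + 1 / r - 1 + cos_theta^2)
}

# numerical CDF of cos(theta) under the Klein-Nishina density
kn_cdf <- function(cos_grid, energy) {
  pdf <- kn_density(cos_grid, energy)
  cdf <- c(0, cumsum((pdf[-1] + pdf[-length(pdf)]) / 2 * diff(cos_grid)))
  cdf / cdf[length(cdf)]
}

MEV_PER_G_TO_GY <- 1.602176634e-10

# oracle: G_L = (1/L) int_{-L/2}^{L/2} dl / |x - x(l)|^2 by Simpson rule
gl_numeric <- function(r, theta_deg, L = 0.35, n = 4000) {
  th <- theta_deg * pi / 180
  rho <- r * sin(th)
  z <- r * cos(th)
  l <- seq(-L / 2, L / 2, length.out = 2 * n + 1)
  f <- 1 / (rho^2 + (z - l)^2)
  h <- l[2] - l[1]
  w <- c(1, rep(c(4, 2), n - 1), 4, 1)
  sum(w * f) * h / 3 / L
}
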