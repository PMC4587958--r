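# The TG-43U1 formalism: line-source geometry factor, air kerma strength,
# dose rate constant, radial dose function, anisotropy function, and the
# forward dose-rate reconstruction
#   D(r, theta) = S_K Lambda [G_L(r,theta)/G_L(r0,theta0)] g_L(r) F(r,theta)
# with reference point r0 = 1 cm, theta0 = 90 deg.

R0_CM <- 1
THETA0_DEG <- 90
GY_PER_HIST_TO_LAMBDA <- 1e2 / 1e6  # cGy per Gy over uGy per Gy

#' Line-source geometry factor
#'
#' `G_L(r, theta) = beta / (L r sin(theta))` where beta is the angle
#' subtended by the active length L at the field point, computed from the
#' two endpoint angles with atan2 (numerically stable where the printed
#' subtraction-of-arctans form is ill-conditioned). On the source axis
#' (sin(theta) = 0) the analytic limit `1 / (r^2 - L^2/4)` is used.
#'
#' @param r_cm distance from the source centre, cm (> 0).
#' @param theta_deg polar angle from the source axis, degrees.
#' @param L_cm active length, cm (default 0.35).
#' @return Geometry factor, cm^-2. In the `L -> 0` limit this reduces to
#'   `1/r^2`.
#' @export
geometry_factor_line <- function(r_cm, theta_deg, L_cm = 0.35) {
  n <- max(length(r_cm), length(theta_deg))
  r <- rep_len(r_cm, n)
  th <- rep_len(theta_deg, n) * pi / 180
  rho <- r * sin(th)
  z <- r * cos(th)
  on_axis <- abs(rho) < 1e-12
  if (any(r <= 0)) stop("r must be positive")
  if (any(on_axis & abs(z) <= L_cm / 2))
    stop("field point lies on the active line segment")
  if (L_cm <= 0) return(1 / r^2)
  g <- numeric(n)
  beta <- atan2(rho, z - L_cm / 2) - atan2(rho, z + L_cm / 2)
  g[!on_axis] <- beta[!on_axis] / (L_cm * rho[!on_axis])
  g[on_axis] <- 1 / (r[on_axis]^2 - L_cm^2 / 4)
  g
}

#' Air kerma strength
#'
#' `S_K = K_air * d^2`: the air kerma rate at distance d on the transverse
#' axis times the squared distance. With K_air in uGy/h and d in m the
#' result is in U (1 U = 1 uGy m^2 h^-1); with K_air in Gy per history the
#' result is Gy m^2 per history, the form used in the Lambda ratio.
#'
#' @param k_air air kerma (rate or per history) at distance `d_m`.
#' @param d_m distance on the transverse axis, m.
#' @return Air kerma strength in `k_air` units times m^2.
#' @export
air_kerma_strength <- function(k_air, d_m = 1) {
  if (any(k_air <= 0) || any(d_m <= 0))
    stop("k_air and d must be positive")
  k_air * d_m^2
}

#' Dose rate constant
#'
#' `Lambda = D(r0, theta0) / S_K` with both quantities per history from
#' the same source model: the dose to water in the 0.1 mm voxel at 1 cm,
#' 90 deg divided by the air kerma strength, expressed in
#' cGy h^-1 U^-1.
#'
#' @param d_ref dose rate to water at the reference point, Gy per history.
#' @param s_k air kerma strength, Gy m^2 per history.
#' @param rel_unc_d,rel_unc_sk optional k = 1 relative uncertainties,
#'   combined in quadrature.
#' @return List with `lambda` (cGy h^-1 U^-1) and `rel_uncertainty_k1`.
#' @export
dose_rate_constant <- function(d_ref, s_k, rel_unc_d = 0,
                               rel_unc_sk = 0) {
  if (s_k <= 0) stop("S_K must be positive")
  list(lambda = d_ref / s_k * GY_PER_HIST_TO_LAMBDA,
       rel_uncertainty_k1 = sqrt(rel_unc_d^2 + rel_unc_sk^2))
}

#' Radial dose function from a transverse-axis dose table
#'
#' `g_L(r) = [D(r)/D(r0)] [G_L(r0, 90)/G_L(r, 90)]`, normalized to 1 at
#' r0 = 1 cm. Uncertainties of the two dose entries are propagated in
#' quadrature; neighbouring values share the D(r0) entry and are therefore
#' correlated.
#'
#' @param dose_table data frame with columns `r_cm`,
#'   `kerma_Gy_per_history` and optionally `rel_uncertainty_k1`.
#' @param L_cm active length, cm.
#' @return Data frame with `r_cm`, `g_L`, `rel_uncertainty_k1`.
#' @export
radial_dose_function <- function(dose_table, L_cm = 0.35) {
  i0 <- which(abs(dose_table$r_cm - R0_CM) < 1e-9)
  if (!length(i0))
    stop("dose table must contain the reference distance r0 = 1 cm")
  d0 <- dose_table$kerma_Gy_per_history[i0[1]]
  g0 <- geometry_factor_line(R0_CM, THETA0_DEG, L_cm)
  g <- dose_table$kerma_Gy_per_history / d0 *
    g0 / geometry_factor_line(dose_table$r_cm, THETA0_DEG, L_cm)
  u <- dose_table$rel_uncertainty_k1
  if (is.null(u)) u <- rep(0, nrow(dose_table))
  ur <- sqrt(u^2 + u[i0[1]]^2)
  ur[i0[1]] <- 0
  data.frame(r_cm = dose_table$r_cm, g_L = g, rel_uncertainty_k1 = ur)
}

#' Anisotropy function from a polar dose grid
#'
#' `F(r, theta) = [D(r,theta)/D(r,90)] [G_L(r,90)/G_L(r,theta)]`; equal to
#' 1 at theta0 = 90 deg by construction.
#'
#' @param dose_grid data frame with columns `r_cm`, `theta_deg`,
#'   `kerma_Gy_per_history`.
#' @param L_cm active length, cm.
#' @return Data frame with `r_cm`, `theta_deg`, `F`.
#' @export
anisotropy_function <- function(dose_grid, L_cm = 0.35) {
  out <- do.call(rbind, lapply(split(dose_grid, dose_grid$r_cm),
                               function(d) {
    i0 <- which(abs(d$theta_deg - THETA0_DEG) < 1e-9)
    if (!length(i0))
      stop("dose grid must contain theta0 = 90 deg at r = ", d$r_cm[1])
    gt0 <- geometry_factor_line(d$r_cm[1], THETA0_DEG, L_cm)
    f <- d$kerma_Gy_per_history / d$kerma_Gy_per_history[i0[1]] *
      gt0 / geometry_factor_line(d$r_cm, d$theta_deg, L_cm)
    data.frame(r_cm = d$r_cm, theta_deg = d$theta_deg, F = f)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble a TG-43 dataset
#'
#' @param s_k air kerma strength per history, Gy m^2.
#' @param lambda dose rate constant, cGy h^-1 U^-1.
#' @param g_L radial dose function table from [radial_dose_function()].
#' @param F_table optional anisotropy table from [anisotropy_function()].
#' @param L_cm active length, cm.
#' @param lambda_rel_unc k = 1 relative uncertainty of lambda.
#' @return An object of class `tg43_dataset`.
#' @export
tg43_dataset <- function(s_k, lambda, g_L, F_table = NULL, L_cm = 0.35,
                         lambda_rel_unc = NA_real_) {
  stopifnot(s_k > 0, lambda > 0)
  i0 <- which(abs(g_L$r_cm - R0_CM) < 1e-9)
  if (!length(i0) || abs(g_L$g_L[i0[1]] - 1) > 1e-12)
    stop("g_L must equal 1 at r0 = 1 cm")
  if (!is.null(F_table)) {
    f0 <- F_table$F[abs(F_table$theta_deg - THETA0_DEG) < 1e-9]
    if (any(abs(f0 - 1) > 1e-12))
      stop("F must equal 1 at theta0 = 90 deg")
  }
  structure(list(s_k = s_k, lambda = lambda,
                 lambda_rel_unc = lambda_rel_unc, g_L = g_L,
                 F_table = F_table, L_cm = L_cm, r0_cm = R0_CM,
                 theta0_deg = THETA0_DEG),
            class = "tg43_dataset")
}

#' @export
print.tg43_dataset <- function(x, ...) {
  cat("TG-43 dataset (line-source formalism, L =", x$L_cm, "cm)\n")
  cat(sprintf("  S_K per history: %.4e Gy m^2\n", x$s_k))
  cat(sprintf("  Lambda: %.4f cGy h^-1 U^-1 (rel. unc. k=1: %.2g)\n",
              x$lambda, x$lambda_rel_unc))
  cat(sprintf("  g_L tabulated at %d radii (%g-%g cm)%s\n",
              nrow(x$g_L), min(x$g_L$r_cm), max(x$g_L$r_cm),
              if (is.null(x$F_table)) "" else
                sprintf("; F at %d nodes", nrow(x$F_table))))
  invisible(x)
}

#' TG-43 forward dose-rate reconstruction
#'
#' Evaluates `D = S_K Lambda [G_L(r,theta)/G_L(r0,theta0)] g_L(r)
#' F(r,theta)` with linear interpolation in r for g_L and bilinear
#' interpolation for F. Points beyond the tabulated range are evaluated at
#' the nearest table edge and flagged.
#'
#' @param dataset a `tg43_dataset`.
#' @param r_cm,theta_deg evaluation point(s).
#' @return List with `dose_rate` (units of `S_K * Lambda`, i.e. cGy/h when
#'   S_K is in U) and logical `extrapolated`.
#' @export
dose_rate_tg43 <- function(dataset, r_cm, theta_deg = 90) {
  n <- max(length(r_cm), length(theta_deg))
  r <- rep_len(r_cm, n)
  th <- rep_len(theta_deg, n)
  gr <- dataset$g_L$r_cm
  extrap <- r < min(gr) | r > max(gr)
  gl <- approx(gr, dataset$g_L$g_L, xout = pmin(pmax(r, min(gr)), max(gr)),
               rule = 2)$y
  fv <- rep(1, n)
  if (!is.null(dataset$F_table)) {
    fv <- interp_bilinear(dataset$F_table, r, th)
    extrap <- extrap | th < min(dataset$F_table$theta_deg) |
      th > max(dataset$F_table$theta_deg)
  }
  gfac <- geometry_factor_line(r, th, dataset$L_cm) /
    geometry_factor_line(dataset$r0_cm, dataset$theta0_deg, dataset$L_cm)
  list(dose_rate = dataset$s_k * dataset$lambda * gfac * gl * fv,
       extrapolated = extrap)
}

interp_bilinear <- function(F_table, r, th) {
  rs <- sort(unique(F_table$r_cm))
  ts <- sort(unique(F_table$theta_deg))
  grid <- matrix(NA_real_, length(rs), length(ts))
  ij <- cbind(match(F_table$r_cm, rs), match(F_table$theta_deg, ts))
  grid[ij] <- F_table$F
  r <- pmin(pmax(r, rs[1]), rs[length(rs)])
  th <- pmin(pmax(th, ts[1]), ts[length(ts)])
  vapply(seq_along(r), function(i) {
    i1 <- max(which(rs <= r[i])); i2 <- min(i1 + 1, length(rs))
    j1 <- max(which(ts <= th[i])); j2 <- min(j1 + 1, length(ts))
    wr <- if (i2 > i1) (r[i] - rs[i1]) / (rs[i2] - rs[i1]) else 0
    wt <- if (j2 > j1) (th[i] - ts[j1]) / (ts[j2] - ts[j1]) else 0
    (1 - wr) * ((1 - wt) * grid[i1, j1] + wt * grid[i1, j2]) +
      wr * ((1 - wt) * grid[i2, j1] + wt * grid[i2, j2])
  }, 0)
}
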