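## Direct energy-minimization backend: discretize the profile as r(z) on a
## fixed height grid and minimize the interfacial energy at fixed volume.
## This is the brute-force counterpart of the shooting solver, in the spirit
## of gradient-descent surface minimizers, and is used as an independent
## cross-check of the ODE route.

# Energy, volume and analytic gradients for a profile r_0..r_n on the
# uniform grid z_i = i*h, with r_n pinned at 1 (reduced units).
# E = sum_i pi (r_i + r_{i+1}) sqrt(dr^2 + h^2) - cos(theta) pi r_0^2
# V = sum_i pi h (r_i^2 + r_i r_{i+1} + r_{i+1}^2) / 3
profile_energy <- function(r, h, costh) {
  n <- length(r) - 1L
  dr <- diff(r)
  seg <- sqrt(dr^2 + h^2)
  sum(pi * (r[-(n + 1)] + r[-1]) * seg) - costh * pi * r[1]^2
}
profile_volume <- function(r, h) {
  n <- length(r) - 1L
  sum(pi * h * (r[-(n + 1)]^2 + r[-(n + 1)] * r[-1] + r[-1]^2) / 3)
}
profile_energy_grad <- function(r, h, costh) {
  n <- length(r) - 1L
  dr <- diff(r)
  seg <- sqrt(dr^2 + h^2)
  g <- numeric(n + 1L)
  # d/dr_i of segment i-1 (between i-1 and i) and segment i (between i and i+1)
  a <- pi * seg                                  # d(sum (r_i+r_{i+1}) seg)/dr additive part
  b <- pi * (r[-(n + 1)] + r[-1]) * dr / seg     # via seg length
  g[1:n] <- g[1:n] + a + (-b)
  g[2:(n + 1)] <- g[2:(n + 1)] + a + b
  g[1] <- g[1] - 2 * costh * pi * r[1]
  g
}
profile_volume_grad <- function(r, h) {
  n <- length(r) - 1L
  g <- numeric(n + 1L)
  g[1:n] <- g[1:n] + pi * h * (2 * r[-(n + 1)] + r[-1]) / 3
  g[2:(n + 1)] <- g[2:(n + 1)] + pi * h * (r[-(n + 1)] + 2 * r[-1]) / 3
  g
}

# Augmented-Lagrangian minimization of the profile energy at fixed volume.
# Free variables r_0..r_{n-1}; r_n = 1 (pinned rim). Returns the profile,
# the volume multiplier (the negative reduced Laplace pressure) and energy.
minimize_profile <- function(gap, vol, theta_rad, n = 200L, r_init = NULL,
                             tol = 1e-10, outer_max = 40L) {
  h <- gap / n
  costh <- cos(theta_rad)
  if (is.null(r_init)) {
    rb0 <- max(sqrt(vol / (pi * gap)), 0.05)
    r_init <- seq(rb0, 1, length.out = n + 1L)
  }
  r <- r_init
  lam <- 0
  rho <- 10 / vol
  viol_prev <- Inf
  for (outer in seq_len(outer_max)) {
    fn <- function(rf) {
      rr <- c(rf, 1)
      if (any(rr <= 0)) return(1e10)
      v <- profile_volume(rr, h) - vol
      profile_energy(rr, h, costh) + lam * v + 0.5 * rho * v^2
    }
    gr <- function(rf) {
      rr <- c(rf, 1)
      if (any(rr <= 0)) return(rep(0, length(rf)))
      v <- profile_volume(rr, h) - vol
      g <- profile_energy_grad(rr, h, costh) +
        (lam + rho * v) * profile_volume_grad(rr, h)
      g[-length(rr)]
    }
    opt <- stats::optim(r[-(n + 1L)], fn, gr, method = "BFGS",
                        control = list(maxit = 1000L, reltol = 1e-15))
    r <- c(opt$par, 1)
    viol <- profile_volume(r, h) - vol
    lam <- lam + rho * viol
    if (abs(viol) < tol * vol) break
    if (abs(viol) > 0.5 * viol_prev) rho <- rho * 4
    viol_prev <- abs(viol)
  }
  list(r = r, z = seq(0, gap, length.out = n + 1L),
       energy = profile_energy(r, h, costh),
       volume = profile_volume(r, h),
       pressure = -lam,   # dE/dV along equilibria = -dP (reduced)
       converged = abs(profile_volume(r, h) - vol) < 1e-8 * vol)
}

#' Solve a pinned bridge by discrete energy minimization
#'
#' Independent backend for [solve_bridge()]: the profile `r(z)` is
#' discretized on a uniform height grid and the interfacial energy
#' `E = gamma A_lv - gamma cos(theta) A_bottom` is minimized at fixed
#' enclosed volume with an augmented-Lagrangian BFGS scheme. The contact
#' angle at the substrate is not imposed; it emerges from the wetted-area
#' energy term, and the volume multiplier converges to the (negative)
#' Laplace pressure. The force is obtained as `-dE/dd` by centered finite
#' differences of two neighbouring minimizations.
#'
#' @param spec A [bridge_spec()].
#' @param gap Separation (µm).
#' @param n_segments Number of profile segments (default 200).
#' @param fd_step Relative gap step for the energy-difference force.
#' @return A `bridge_state` (profile, pressure, energy, force); the
#'   `force_laplace`/`force_tension` split is evaluated from the minimizer's
#'   own pressure and bottom radius.
#' @export
solve_bridge_energy <- function(spec, gap, n_segments = 200L,
                                fd_step = 1e-3) {
  stopifnot(inherits(spec, "bridge_spec"), gap > 0)
  R <- spec$pin_radius
  gam <- spec$tension
  th <- deg2rad(spec$contact_angle)
  ghat <- gap / R
  vhat <- spec$volume / R^3
  n <- as.integer(n_segments)
  m0 <- minimize_profile(ghat, vhat, th, n)
  if (!m0$converged)
    stop("energy minimization did not converge", call. = FALSE)
  dg <- fd_step * ghat
  mp <- minimize_profile(ghat + dg, vhat, th, n, r_init = m0$r)
  mm <- minimize_profile(ghat - dg, vhat, th, n, r_init = m0$r)
  f_hat <- -(mp$energy - mm$energy) / (2 * dg)
  rb <- m0$r[1]
  p <- m0$pressure
  uN <- gam * R * 1e-3
  structure(
    list(gap = gap,
         profile = data.frame(r_um = m0$r * R, z_um = m0$z * R),
         laplace_pressure = p * gam / R,
         bottom_radius = rb * R,
         bottom_area = pi * rb^2 * R^2,
         lv_area = frustum_area_cpp(m0$r, m0$z) * R^2,
         energy = m0$energy * gam * R^2,        # fJ
         force = f_hat * uN,
         force_laplace = p * pi * rb^2 * uN,
         force_tension = -2 * pi * rb * sin(th) * uN,
         reduced = list(p = p, rb = rb, gap = ghat, vol = vhat, n = n),
         spec = spec),
    class = "bridge_state")
}
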