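## Shooting solver for the axisymmetric Young-Laplace equation.
##
## All work is done in reduced units: lengths / pin_radius, pressures *
## pin_radius / tension, forces / (tension * pin_radius), energies /
## (tension * pin_radius^2). Capillarity without gravity has no intrinsic
## length, so the reduced problem depends only on (theta, reduced gap,
## reduced volume); physical results are recovered by rescaling.

# Residual of the two-point boundary problem. Unknowns x = (p, rb, S):
# reduced Laplace pressure, bottom contact radius, total profile arclength.
# Conditions: profile ends on the rim (r = 1) at height z = gap, and the
# enclosed volume matches. Returns NULL when the integration left the
# admissible region (r <= 0 or non-finite).
yl_residual <- function(x, gap, vol, theta_rad, n) {
  if (x[2] <= 0 || x[3] <= 0) return(NULL)
  sh <- yl_shoot_cpp(x[1], x[2], x[3], theta_rad, n)
  if (!sh$ok) return(NULL)
  c(sh$r - 1, (sh$z - gap) / max(gap, 1), (sh$V - vol) / vol)
}

# Damped Newton with forward-difference Jacobian on the shooting residual.
yl_newton <- function(x0, gap, vol, theta_rad, n, tol = 1e-10, maxit = 60L) {
  x <- x0
  Fx <- yl_residual(x, gap, vol, theta_rad, n)
  if (is.null(Fx)) return(NULL)
  for (it in seq_len(maxit)) {
    nf <- sqrt(sum(Fx^2))
    if (nf < tol) return(list(x = x, resid = nf, iter = it))
    J <- matrix(NA_real_, 3, 3)
    for (j in 1:3) {
      h <- 1e-7 * max(abs(x[j]), 1e-3)
      xp <- x; xp[j] <- xp[j] + h
      Fp <- yl_residual(xp, gap, vol, theta_rad, n)
      if (is.null(Fp)) { xp[j] <- x[j] - h; Fp <- yl_residual(xp, gap, vol, theta_rad, n); h <- -h }
      if (is.null(Fp)) return(NULL)
      J[, j] <- (Fp - Fx) / h
    }
    dx <- tryCatch(solve(J, -Fx), error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) return(NULL)
    # keep rb and S positive; damp into the admissible region
    t <- 1
    repeat {
      xn <- x + t * dx
      if (xn[2] > 0 && xn[3] > 0) {
        Fn <- yl_residual(xn, gap, vol, theta_rad, n)
        if (!is.null(Fn) && sqrt(sum(Fn^2)) < (1 - 1e-4 * t) * nf) break
      }
      t <- t / 2
      if (t < 1e-6) return(NULL)
    }
    x <- xn; Fx <- Fn
  }
  nf <- sqrt(sum(Fx^2))
  if (nf < 1e2 * tol) list(x = x, resid = nf, iter = maxit) else NULL
}

# Default starting point: a cylinder-ish column of the right volume.
yl_init_guess <- function(gap, vol, theta_rad) {
  rb <- sqrt(vol / (pi * gap))
  rbar <- (rb + 1) / 2
  # mean curvature of a cylinder of radius rbar plus an axial term of the
  # sign suggested by the contact angle
  p <- 1 / rbar - 2 * cos(theta_rad) / gap
  S <- 1.2 * sqrt(gap^2 + (rb - 1)^2) + 0.1 * gap
  c(p, rb, S)
}

# Solve the reduced problem, optionally warm-started; falls back to a small
# multistart and then to continuation in gap from 1/8 of the target.
yl_solve_reduced <- function(gap, vol, theta_rad, n = 200L, init = NULL) {
  tries <- list()
  if (!is.null(init)) tries <- c(tries, list(init))
  g0 <- yl_init_guess(gap, vol, theta_rad)
  tries <- c(tries, list(g0, c(0, g0[2], g0[3]), c(-g0[1], g0[2], g0[3])))
  for (x0 in tries) {
    sol <- yl_newton(x0, gap, vol, theta_rad, n)
    if (!is.null(sol)) return(sol)
  }
  # continuation from a squat gap where the cylinder guess is reliable
  gseq <- seq(gap / 8, gap, length.out = 12L)
  sol <- NULL
  for (g in gseq) {
    x0 <- if (is.null(sol)) yl_init_guess(g, vol, theta_rad) else sol$x
    sol <- yl_newton(x0, g, vol, theta_rad, n)
    if (is.null(sol)) return(NULL)
  }
  sol
}

# Assemble a bridge_state (physical units) from a converged reduced solution.
yl_state <- function(sol, spec, gap, n) {
  R <- spec$pin_radius
  gam <- spec$tension
  th <- deg2rad(spec$contact_angle)
  sh <- yl_shoot_cpp(sol$x[1], sol$x[2], sol$x[3], th, n, keep_profile = TRUE)
  prof <- sh$profile
  rb <- sol$x[2]
  p <- sol$x[1]
  a_lv <- frustum_area_cpp(prof[, 1], prof[, 2])
  a_bot <- pi * rb^2
  # energy relative to the detached pendant configuration is reported up to a
  # constant; we report E = gamma*A_lv - gamma*cos(theta)*A_bottom
  e_hat <- a_lv - cos(th) * a_bot
  f_lap <- p * a_bot
  f_ten <- -2 * pi * rb * sin(th)
  # reentrant shapes (tangent angle leaving (0, pi)) cannot be written as
  # r(z); flagged because they may also intersect the hair flank
  overhang <- any(prof[, 3] <= 0) || any(prof[, 3] >= pi)
  # unit conversions: mN/m * um = nN; report uN
  uN <- gam * R * 1e-3
  structure(
    list(gap = gap,
         profile = data.frame(r_um = prof[, 1] * R, z_um = prof[, 2] * R),
         laplace_pressure = p * gam / R,        # kPa
         bottom_radius = rb * R,                # um
         bottom_area = a_bot * R^2,             # um^2
         lv_area = a_lv * R^2,                  # um^2
         energy = e_hat * gam * R^2,            # fJ (mN/m * um^2)
         force = (f_lap + f_ten) * uN,          # uN, negative = attraction
         force_laplace = f_lap * uN,
         force_tension = f_ten * uN,
         overhang = overhang,
         reduced = list(p = p, rb = rb, S = sol$x[3], gap = gap / R,
                        vol = spec$volume / R^3, resid = sol$resid, n = n),
         spec = spec),
    class = "bridge_state")
}

#' Solve the equilibrium shape of a pinned capillary bridge
#'
#' Finds the constant-mean-curvature axisymmetric surface pinned at
#' `(pin_radius, gap)`, meeting the substrate at the spec's contact angle and
#' enclosing the spec's volume. The default backend shoots the Young-Laplace
#' equation in arc-length form from the substrate, solving for the Laplace
#' pressure, bottom contact radius and profile length with a damped Newton
#' method; continuation from smaller gaps keeps the solution on the branch
#' connected to contact. The `"energy"` backend minimizes the interfacial
#' energy of a discretized profile at fixed volume (see
#' [solve_bridge_energy()]) and serves as an independent cross-check.
#'
#' @param spec A [bridge_spec()].
#' @param gap Separation `d` between substrate and pinning plane (µm).
#' @param method `"shooting"` (default) or `"energy"`.
#' @param n_segments Profile resolution; doubled until the force changes by
#'   less than `refine_tol` (relative), up to 8 times the initial value.
#' @param refine_tol Relative force tolerance for resolution refinement.
#' @param init Optional warm start `c(p, rb, S)` in reduced units.
#' @return A `bridge_state`: profile, Laplace pressure (kPa), bottom contact
#'   radius/area, surface area, interfacial energy (fJ), and the vertical
#'   force on the substrate (µN, negative = attraction) with its Laplace and
#'   surface-tension components.
#' @seealso [bridge_force()], [force_curve()]
#' @examples
#' sp <- bridge_spec(1, phi = 2, contact_angle = 60, tension = 1)
#' st <- solve_bridge(sp, gap = 0.8)
#' st$force
#' @export
solve_bridge <- function(spec, gap, method = c("shooting", "energy"),
                         n_segments = 200L, refine_tol = 0.002, init = NULL) {
  stopifnot(inherits(spec, "bridge_spec"), gap > 0)
  method <- match.arg(method)
  if (method == "energy")
    return(solve_bridge_energy(spec, gap, n_segments = n_segments))
  R <- spec$pin_radius
  ghat <- gap / R
  vhat <- spec$volume / R^3
  th <- deg2rad(spec$contact_angle)
  n <- as.integer(n_segments)
  sol <- yl_solve_reduced(ghat, vhat, th, n, init = init)
  if (is.null(sol)) signal_rupture(spec, gap)
  st <- yl_state(sol, spec, gap, n)
  # double the resolution until the force is converged
  for (k in 1:3) {
    n2 <- 2L * st$reduced$n
    sol2 <- yl_newton(sol$x, ghat, vhat, th, n2)
    if (is.null(sol2)) break
    st2 <- yl_state(sol2, spec, gap, n2)
    done <- abs(st2$force - st$force) <=
      refine_tol * max(abs(st2$force), 1e-12)
    sol <- sol2; st <- st2
    if (done) break
  }
  st
}

signal_rupture <- function(spec, gap) {
  stop(structure(
    class = c("capibridge_ruptured", "error", "condition"),
    list(message = sprintf(
      "no equilibrium bridge at gap %.4g um (volume %.4g fl): ruptured",
      gap, spec$volume),
      call = NULL, spec = spec, gap = gap)))
}

#' Vertical capillary force of a solved bridge
#'
#' The force on the substrate is the sum of the Laplace-pressure contribution
#' over the wetted patch and the vertical pull of the surface tension at the
#' contact line:
#' `f = dP * A_bottom - 2 pi R_bottom * gamma * sin(theta)`.
#' Attraction is negative: a negative Laplace pressure over the wetted area
#' pulls the substrate toward the bridge, and the tension term always pulls
#' toward the liquid.
#'
#' @param state A converged `bridge_state`.
#' @param tension Interfacial tension (mN/m); defaults to the spec's.
#' @param contact_angle Contact angle (deg); defaults to the spec's.
#' @return Named list with `total`, `laplace` and `tension` components (µN).
#' @export
bridge_force <- function(state, tension = state$spec$tension,
                         contact_angle = state$spec$contact_angle) {
  stopifnot(inherits(state, "bridge_state"))
  th <- deg2rad(contact_angle)
  f_lap <- state$laplace_pressure * state$bottom_area * 1e-3   # kPa*um^2 = nN
  f_ten <- -2 * pi * state$bottom_radius * tension * sin(th) * 1e-3
  list(total = f_lap + f_ten, laplace = f_lap, tension = f_ten)
}

#' Force-distance curve of a pinned bridge
#'
#' Solves the bridge over an increasing grid of gaps by continuation
#' (warm-starting each gap from the previous solution). The first failed
#' continuation marks rupture; the rupture gap is then refined by bisection
#' to `1e-3` relative. Forces beyond rupture are zero and flagged.
#'
#' @param spec A [bridge_spec()].
#' @param gap_grid Increasing, positive gaps (µm).
#' @param n_segments Profile resolution per solve.
#' @return A `force_curve`: data frame of `gap`, `force`, `force_laplace`,
#'   `force_tension`, `ruptured`, plus attributes `adhesion_force`,
#'   `adhesion_gap` (parabolic refinement of the minimum) and `rupture_gap`.
#' @examples
#' sp <- bridge_spec(1, phi = 2, contact_angle = 30, tension = 1)
#' fc <- force_curve(sp, seq(0.1, 1.4, length.out = 40))
#' attr(fc, "adhesion_force")
#' @export
force_curve <- function(spec, gap_grid, n_segments = 200L) {
  stopifnot(inherits(spec, "bridge_spec"), length(gap_grid) > 0,
            all(gap_grid > 0), all(diff(gap_grid) > 0))
  R <- spec$pin_radius
  vhat <- spec$volume / R^3
  th <- deg2rad(spec$contact_angle)
  n <- as.integer(n_segments)
  m <- length(gap_grid)
  force <- f_lap <- f_ten <- rb <- dp <- numeric(m)
  ruptured <- logical(m)
  states <- vector("list", m)
  init <- NULL
  last_ok <- 0L
  for (i in seq_len(m)) {
    ghat <- gap_grid[i] / R
    sol <- if (is.null(init)) yl_solve_reduced(ghat, vhat, th, n)
           else yl_newton(init, ghat, vhat, th, n)
    if (is.null(sol) && !is.null(init))
      sol <- yl_solve_reduced(ghat, vhat, th, n, init = init)
    if (is.null(sol)) { ruptured[i:m] <- TRUE; break }
    st <- yl_state(sol, spec, gap_grid[i], n)
    states[[i]] <- st
    force[i] <- st$force; f_lap[i] <- st$force_laplace
    f_ten[i] <- st$force_tension; rb[i] <- st$bottom_radius
    dp[i] <- st$laplace_pressure
    init <- sol$x
    last_ok <- i
  }
  rupture_gap <- if (last_ok == 0L) {
    NA_real_
  } else if (last_ok == m) {
    Inf   # no rupture inside the grid; true rupture lies beyond it
  } else {
    g_lo <- gap_grid[last_ok] / R
    g_hi <- gap_grid[last_ok + 1L] / R
    x_lo <- states[[last_ok]]$reduced
    init_lo <- c(x_lo$p, x_lo$rb, x_lo$S)
    while ((g_hi - g_lo) > 1e-3 * g_hi) {
      g_mid <- (g_lo + g_hi) / 2
      sol <- yl_newton(init_lo, g_mid, vhat, th, n)
      if (is.null(sol)) g_hi <- g_mid
      else { g_lo <- g_mid; init_lo <- sol$x }
    }
    g_lo * R
  }
  out <- data.frame(gap = gap_grid, force = force, force_laplace = f_lap,
                    force_tension = f_ten, bottom_radius = rb,
                    laplace_pressure = dp, ruptured = ruptured)
  adh <- curve_minimum(gap_grid[!ruptured], force[!ruptured])
  structure(out, class = c("force_curve", "data.frame"),
            adhesion_force = adh$force, adhesion_gap = adh$gap,
            rupture_gap = rupture_gap, spec = spec, states = states)
}

# Minimum of a sampled curve with parabolic refinement through the three
# points bracketing the grid minimum.
curve_minimum <- function(x, y) {
  if (length(x) == 0L) return(list(force = 0, gap = NA_real_))
  i <- which.min(y)
  if (i == 1L || i == length(y))
    return(list(force = y[i], gap = x[i]))
  x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  co <- solve(cbind(1, x3, x3^2), y3)
  if (co[3] <= 0) return(list(force = y[i], gap = x[i]))
  xv <- -co[2] / (2 * co[3])
  if (xv < x3[1] || xv > x3[3]) return(list(force = y[i], gap = x[i]))
  list(force = unname(co[1] + co[2] * xv + co[3] * xv^2), gap = unname(xv))
}

#' Adhesion force of a force curve
#'
#' @param curve A `force_curve` (or any data frame with `gap` and `force`).
#' @return List with `force` (the minimum, µN) and `gap` (its location, µm),
#'   refined by a parabola through the three bracketing grid points.
#' @export
adhesion_from_curve <- function(curve) {
  keep <- if ("ruptured" %in% names(curve)) !curve$ruptured else TRUE
  curve_minimum(curve$gap[keep], curve$force[keep])
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve> %d gaps in [%.4g, %.4g] um; adhesion %.4g uN at %.4g um; rupture at %s um\n",
    nrow(x), min(x$gap), max(x$gap), attr(x, "adhesion_force"),
    attr(x, "adhesion_gap"), format(attr(x, "rupture_gap"), digits = 4)))
  invisible(x)
}

#' Plot a force-distance curve
#'
#' @param x A `force_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.force_curve <- function(x, ...) {
  graphics::plot(x$gap, x$force, type = "l", xlab = "gap (um)",
                 ylab = "force (uN)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
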