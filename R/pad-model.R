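#' Geometry of a rigid hairy adhesive pad
#'
#' An array of `n_hairs` rigid cylindrical hairs of length `hair_length` and
#' tip diameter `hair_diameter` on a flat circular pad of diameter
#' `pad_diameter`; each hair tip carries an adhesive-fluid bridge of volume
#' `fluid_volume` pinned to the tip rim. All hairs share one gap `d` to the
#' substrate (rigid pad, simultaneous detachment).
#'
#' @param pad_diameter Pad diameter `D_p` (µm).
#' @param hair_diameter Hair tip diameter `D_h` (µm).
#' @param hair_length Hair length `L` (µm).
#' @param n_hairs Number of hairs `N` (non-negative integer).
#' @param fluid_volume Fluid volume per hair `V_f` (fl = µm³); alternatively
#'   give `phi_f`.
#' @param phi_f Fluid size parameter `D_h / (2 s_f)`.
#' @return An object of class `pad_geometry`.
#' @examples
#' pad_geometry(200, 2, 50, 2000, phi_f = 2)
#' @export
pad_geometry <- function(pad_diameter, hair_diameter, hair_length, n_hairs,
                         fluid_volume = NULL, phi_f = NULL) {
  stopifnot(pad_diameter > 0, hair_diameter > 0, hair_length > 0,
            n_hairs >= 0, n_hairs == round(n_hairs))
  if (n_hairs * (hair_diameter / 2)^2 > (pad_diameter / 2)^2)
    stop("hairs do not fit on the pad: N (D_h/2)^2 > (D_p/2)^2", call. = FALSE)
  if (is.null(fluid_volume) + is.null(phi_f) != 1L)
    stop("give exactly one of `fluid_volume` or `phi_f`", call. = FALSE)
  if (is.null(fluid_volume))
    fluid_volume <- 4 / 3 * pi * (hair_diameter / 2 / phi_f)^3
  structure(list(pad_diameter = pad_diameter, hair_diameter = hair_diameter,
                 hair_length = hair_length, n_hairs = as.integer(n_hairs),
                 fluid_volume = fluid_volume),
            class = "pad_geometry")
}

#' Trapped air bubble (plastron) pinned at the pad rim
#'
#' In the Cassie state a bubble of volume `volume` is trapped between the
#' hairs, pinned to the pad circumference, and spans from the pad plane to
#' the substrate (a gas bridge of height `d + L`).
#'
#' @param volume Bubble volume `V_b` (µm³); alternatively give `phi_b`, which
#'   is resolved against the pad diameter when the bubble is used.
#' @param phi_b Bubble size parameter `D_p / (2 s_b)`.
#' @return An object of class `bubble_spec`.
#' @export
bubble_spec <- function(volume = NULL, phi_b = NULL) {
  if (is.null(volume) + is.null(phi_b) != 1L)
    stop("give exactly one of `volume` or `phi_b`", call. = FALSE)
  if (!is.null(volume)) stopifnot(volume > 0) else stopifnot(phi_b > 0)
  structure(list(volume = volume, phi_b = phi_b, present = TRUE),
            class = "bubble_spec")
}

bubble_volume <- function(bubble, pad) {
  if (!is.null(bubble$volume)) bubble$volume
  else 4 / 3 * pi * (pad$pad_diameter / 2 / bubble$phi_b)^3
}

round_half_up <- function(x) floor(x + 0.5)

#' Net pad force for the uniform contact modes
#'
#' In air, and underwater without a trapped bubble, all `N` fluid bridges are
#' identical and non-interacting, so the net force is `F_net(d) = N f(d)`.
#' The single-bridge force uses `(gamma_fa, theta_fa)` in air and
#' `(gamma_fw, theta_fw)` underwater, with `theta_fw` derived by
#' [underwater_contact_angle()].
#'
#' @param pad A [pad_geometry()].
#' @param substrate A [substrate_wetting()] (carries the fluid tensions).
#' @param mode `"air"` or `"underwater_no_bubble"`.
#' @param gaps Gap grid (µm); default [default_gap_grid()].
#' @param n_segments Profile resolution per bridge solve.
#' @return A `pad_force_result`: data frame with per-gap `F_net`, single
#'   bridge forces, hair partition and bubble term (zero here), plus
#'   adhesion attributes.
#' @export
net_force_uniform <- function(pad, substrate,
                              mode = c("air", "underwater_no_bubble"),
                              gaps = default_gap_grid(pad),
                              n_segments = 200L) {
  mode <- match.arg(mode)
  stopifnot(inherits(pad, "pad_geometry"), inherits(substrate, "substrate_wetting"))
  tns <- substrate$tensions
  if (mode == "air") {
    theta <- substrate$theta_fa; gamma <- tns$gamma_fa
  } else {
    theta <- substrate$theta_fw; gamma <- tns$gamma_fw
  }
  sp <- bridge_spec(pad$hair_diameter / 2, volume = pad$fluid_volume,
                    contact_angle = theta, tension = gamma,
                    label = if (mode == "air") "fluid-in-air" else "fluid-in-water")
  fc <- force_curve(sp, gaps, n_segments = n_segments)
  N <- pad$n_hairs
  in_air <- mode == "air"
  df <- data.frame(
    gap = fc$gap,
    F_net = N * fc$force,
    N_in = if (in_air) N else 0L, N_out = if (in_air) 0L else N,
    f_air = if (in_air) fc$force else 0,
    f_water = if (in_air) 0 else fc$force,
    f_bubble = 0,
    bubble_ruptured = TRUE,
    ruptured = fc$ruptured)
  pad_result(df, mode, substrate, pad, rupture_gap = attr(fc, "rupture_gap"))
}

#' Solve the trapped bubble as a pinned gas bridge
#'
#' The bubble is a bridge of volume `V_b` pinned at the pad rim
#' (`pin_radius = D_p/2`), with tension `gamma_wa`, spanning the distance
#' `d + L` from pad plane to substrate. Its contact angle with the substrate,
#' measured through the gas phase, is `180 - theta_wa`. A bubble that cannot
#' span `d + L` is reported as ruptured with zero force and zero bottom
#' contact.
#'
#' @param pad A [pad_geometry()].
#' @param bubble A [bubble_spec()].
#' @param theta_wa Water contact angle in air on the substrate (deg).
#' @param gamma_wa Water-air surface tension (mN/m).
#' @param gap Hair-tip gap `d` (µm); the bubble spans `d + hair_length`.
#' @param n_segments Profile resolution.
#' @param init Optional reduced-unit warm start.
#' @return A `bridge_state` for the bubble, or a ruptured stub with
#'   `force = 0`, `bottom_radius = 0` and `ruptured = TRUE`.
#' @export
bubble_bridge <- function(pad, bubble, theta_wa, gamma_wa, gap,
                          n_segments = 200L, init = NULL) {
  stopifnot(inherits(pad, "pad_geometry"), inherits(bubble, "bubble_spec"))
  sp <- bridge_spec(pad$pad_diameter / 2, volume = bubble_volume(bubble, pad),
                    contact_angle = 180 - theta_wa, tension = gamma_wa,
                    label = "air-in-water")
  span <- gap + pad$hair_length
  st <- tryCatch(solve_bridge(sp, span, n_segments = n_segments, init = init),
                 capibridge_ruptured = function(e) NULL)
  if (is.null(st)) {
    st <- structure(list(gap = span, force = 0, force_laplace = 0,
                         force_tension = 0, bottom_radius = 0,
                         bottom_area = 0, laplace_pressure = NA_real_,
                         ruptured = TRUE, spec = sp),
                    class = "bridge_state")
  } else st$ruptured <- FALSE
  st
}

#' Partition hairs into inside/outside the bubble
#'
#' Assuming a uniform areal hair density on the pad, the fraction of hairs
#' whose tips sit inside the bubble equals the area fraction of the pad
#' covered by the bubble's substrate contact:
#' `N_in = round(N min(1, (R_bottom / (D_p/2))^2))` (ties rounded up).
#'
#' @param pad A [pad_geometry()].
#' @param bubble_state The bubble's `bridge_state` at the evaluation gap.
#' @return Integer vector `c(N_in, N_out)`.
#' @export
partition_hairs <- function(pad, bubble_state) {
  frac <- min(1, (bubble_state$bottom_radius / (pad$pad_diameter / 2))^2)
  n_in <- as.integer(round_half_up(pad$n_hairs * frac))
  c(N_in = n_in, N_out = pad$n_hairs - n_in)
}

#' Net pad force with a trapped bubble
#'
#' In the Cassie state the net force is
#' `F_net(d) = N_in f_air(d) + N_out f_water(d) + f_bubble(d + L)`:
#' hairs inside the bubble form fluid bridges in air, hairs outside form
#' bridges in water, and the bubble meniscus adds its own capillary force.
#' The partition `N_in/N_out` is re-evaluated at every gap from the bubble's
#' substrate contact radius.
#'
#' @inheritParams net_force_uniform
#' @param bubble A [bubble_spec()].
#' @return A `pad_force_result` with the full per-gap component bookkeeping.
#' @export
net_force_bubble <- function(pad, bubble, substrate,
                             gaps = default_gap_grid(pad),
                             n_segments = 200L) {
  stopifnot(inherits(bubble, "bubble_spec"))
  tns <- substrate$tensions
  sp_air <- bridge_spec(pad$hair_diameter / 2, volume = pad$fluid_volume,
                        contact_angle = substrate$theta_fa,
                        tension = tns$gamma_fa, label = "fluid-in-air")
  sp_wat <- bridge_spec(pad$hair_diameter / 2, volume = pad$fluid_volume,
                        contact_angle = substrate$theta_fw,
                        tension = tns$gamma_fw, label = "fluid-in-water")
  fc_air <- force_curve(sp_air, gaps, n_segments = n_segments)
  fc_wat <- force_curve(sp_wat, gaps, n_segments = n_segments)
  m <- length(gaps)
  f_bub <- numeric(m); n_in <- integer(m); bub_rupt <- logical(m)
  init <- NULL
  for (i in seq_len(m)) {
    st <- bubble_bridge(pad, bubble, substrate$theta_wa, tns$gamma_wa,
                        gaps[i], n_segments = n_segments, init = init)
    f_bub[i] <- st$force
    bub_rupt[i] <- isTRUE(st$ruptured)
    if (!bub_rupt[i]) init <- c(st$reduced$p, st$reduced$rb, st$reduced$S)
    n_in[i] <- partition_hairs(pad, st)[["N_in"]]
  }
  df <- data.frame(
    gap = gaps,
    F_net = n_in * fc_air$force + (pad$n_hairs - n_in) * fc_wat$force + f_bub,
    N_in = n_in, N_out = pad$n_hairs - n_in,
    f_air = fc_air$force, f_water = fc_wat$force, f_bubble = f_bub,
    bubble_ruptured = bub_rupt,
    ruptured = fc_air$ruptured | fc_wat$ruptured)
  pad_result(df, "underwater_bubble", substrate, pad,
             rupture_gap = min(attr(fc_air, "rupture_gap"),
                               attr(fc_wat, "rupture_gap")))
}

#' Net pad force for any contact mode
#'
#' Dispatches to [net_force_uniform()] or [net_force_bubble()].
#'
#' @inheritParams net_force_uniform
#' @param mode One of `"air"`, `"underwater_no_bubble"`,
#'   `"underwater_bubble"`.
#' @param bubble A [bubble_spec()]; required for `"underwater_bubble"`.
#' @export
pad_force <- function(pad, substrate,
                      mode = c("air", "underwater_no_bubble",
                               "underwater_bubble"),
                      gaps = default_gap_grid(pad), bubble = NULL,
                      n_segments = 200L) {
  mode <- match.arg(mode)
  if (mode == "underwater_bubble") {
    if (is.null(bubble))
      stop("underwater_bubble mode requires a bubble_spec", call. = FALSE)
    net_force_bubble(pad, bubble, substrate, gaps, n_segments)
  } else {
    net_force_uniform(pad, substrate, mode, gaps, n_segments)
  }
}

#' Default gap grid for a pad force curve
#'
#' 200 points from `0.05 D_h` to `2.5 s_f` (past the rupture distance of the
#' fluid bridges at the default size parameter; gaps beyond rupture carry
#' zero force and a flag).
#'
#' @param pad A [pad_geometry()].
#' @param n Number of grid points.
#' @export
default_gap_grid <- function(pad, n = 200L) {
  s_f <- equivalent_radius(pad$fluid_volume)
  seq(0.05 * pad$hair_diameter, 2.5 * s_f, length.out = n)
}

pad_result <- function(df, mode, substrate, pad, rupture_gap) {
  adh <- curve_minimum(df$gap[!df$ruptured], df$F_net[!df$ruptured])
  structure(df, class = c("pad_force_result", "data.frame"),
            mode = mode, substrate = substrate$name, pad = pad,
            adhesion_force = adh$force, adhesion_gap = adh$gap,
            rupture_gap = rupture_gap)
}

#' Adhesion force of a pad force result
#'
#' The adhesion of a contact mode is the minimum of `F_net` over the gap
#' grid, refined by a parabola through the bracketing points (negative =
#' attraction).
#'
#' @param result A `pad_force_result` (or `force_curve`).
#' @return List with `force` (µN) and `gap` (µm).
#' @export
pad_adhesion <- function(result) {
  list(force = attr(result, "adhesion_force"),
       gap = attr(result, "adhesion_gap"))
}

#' @export
print.pad_force_result <- function(x, ...) {
  cat(sprintf(
    "<pad_force_result> mode %s on %s: adhesion %.4g uN at gap %.4g um (%d gaps)\n",
    attr(x, "mode"), attr(x, "substrate"), attr(x, "adhesion_force"),
    attr(x, "adhesion_gap"), nrow(x)))
  invisible(x)
}
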