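#' Define a pinned capillary bridge
#'
#' A bridge of fixed volume pinned to a circular rim of radius `pin_radius`,
#' meeting a flat substrate at `contact_angle` (measured through the bridge
#' phase), with interfacial tension `tension` against its surroundings.
#' Gravity is neglected: at the micrometre scale of adhesive hairs the Bond
#' number is below 1e-6, so the equilibrium shape is a constant-mean-curvature
#' surface.
#'
#' The volume can be given directly (`volume`, in µm³ = fl) or through the
#' dimensionless size parameter `phi = pin_radius / s`, where
#' `s = (3 volume / 4 pi)^(1/3)` is the radius of the sphere of equal volume.
#' Larger `phi` means less liquid relative to the rim it is pinned to.
#'
#' @param pin_radius Rim radius (µm), e.g. half the hair tip diameter.
#' @param volume Bridge volume (µm³ = fl). Give either `volume` or `phi`.
#' @param phi Size parameter `pin_radius / s` (dimensionless).
#' @param contact_angle Contact angle with the substrate, through the bridge
#'   phase (degrees, strictly between 0 and 180).
#' @param tension Interfacial tension of the bridge surface (mN/m).
#' @param label Free-text label, e.g. `"oil-in-air"` or `"air-in-water"`.
#' @return An object of class `bridge_spec`.
#' @examples
#' bridge_spec(pin_radius = 1, phi = 2, contact_angle = 60, tension = 27.5)
#' @export
bridge_spec <- function(pin_radius, volume = NULL, phi = NULL,
                        contact_angle, tension, label = "") {
  stopifnot(is.numeric(pin_radius), length(pin_radius) == 1L, pin_radius > 0,
            is.numeric(contact_angle), length(contact_angle) == 1L,
            is.numeric(tension), length(tension) == 1L, tension > 0)
  if (contact_angle <= 0 || contact_angle >= 180)
    stop("invalid-spec: contact_angle must lie strictly between 0 and 180 deg",
         call. = FALSE)
  if (is.null(volume) + is.null(phi) != 1L)
    stop("give exactly one of `volume` or `phi`", call. = FALSE)
  if (is.null(volume)) {
    stopifnot(phi > 0)
    volume <- 4 / 3 * pi * (pin_radius / phi)^3
  }
  stopifnot(volume > 0)
  structure(
    list(pin_radius = pin_radius, volume = volume,
         contact_angle = contact_angle, tension = tension,
         label = as.character(label)),
    class = "bridge_spec")
}

#' Equivalent-sphere radius of a bridge volume
#'
#' @param volume Volume (µm³).
#' @return Radius `s` (µm) with `volume = 4/3 pi s^3`.
#' @export
equivalent_radius <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

#' Size parameter of a bridge spec
#'
#' @param spec A [bridge_spec()].
#' @return `phi = pin_radius / s` (dimensionless).
#' @export
size_parameter <- function(spec) spec$pin_radius / equivalent_radius(spec$volume)

#' @export
print.bridge_spec <- function(x, ...) {
  cat(sprintf(
    "<bridge_spec%s> pin radius %.4g um, volume %.4g fl (phi = %.4g), theta %.4g deg, gamma %.4g mN/m\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    x$pin_radius, x$volume, size_parameter(x), x$contact_angle, x$tension))
  invisible(x)
}

#' @export
print.bridge_state <- function(x, ...) {
  cat(sprintf(
    "<bridge_state> gap %.4g um: f = %.4g uN (Laplace %.4g, tension %.4g), dP = %.4g kPa, R_bottom = %.4g um\n",
    x$gap, x$force, x$force_laplace, x$force_tension,
    x$laplace_pressure, x$bottom_radius))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
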