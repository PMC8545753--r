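#' Interfacial tensions of an adhesive fluid / water / air system
#'
#' @param gamma_fa Fluid-air surface tension (mN/m).
#' @param gamma_wa Water-air surface tension (mN/m).
#' @param gamma_fw Fluid-water interfacial tension (mN/m).
#' @return An object of class `fluid_tensions`.
#' @examples
#' fluid_tensions(27.5, 72.8, 53.5)  # n-hexadecane-like tarsal fluid
#' @export
fluid_tensions <- function(gamma_fa, gamma_wa, gamma_fw) {
  stopifnot(gamma_fa > 0, gamma_wa > 0, gamma_fw > 0)
  structure(list(gamma_fa = gamma_fa, gamma_wa = gamma_wa,
                 gamma_fw = gamma_fw), class = "fluid_tensions")
}

#' Underwater contact angle of an oily fluid on a substrate
#'
#' Combining the Young-Dupre balances of the fluid-air, water-air and
#' fluid-water contact lines on the same solid eliminates the solid surface
#' energies and gives the contact angle of the fluid on the substrate when
#' both are submerged in water:
#' \deqn{\cos\theta_{fw} = \frac{\gamma_{fa}\cos\theta_{fa} -
#'       \gamma_{wa}\cos\theta_{wa}}{\gamma_{fw}}}
#' Receding angles are the intended inputs for adhesion (pull-off) modelling.
#'
#' @param tensions A [fluid_tensions()].
#' @param theta_fa Fluid contact angle in air (deg, in `[0, 180]`).
#' @param theta_wa Water contact angle in air (deg, in `[0, 180]`).
#' @return The underwater fluid contact angle `theta_fw` (deg).
#' @examples
#' underwater_contact_angle(fluid_tensions(27.5, 72.8, 53.5), 56, 93)
#' @export
underwater_contact_angle <- function(tensions, theta_fa, theta_wa) {
  stopifnot(inherits(tensions, "fluid_tensions"),
            theta_fa >= 0, theta_fa <= 180, theta_wa >= 0, theta_wa <= 180)
  num <- tensions$gamma_fa * cos(deg2rad(theta_fa)) -
    tensions$gamma_wa * cos(deg2rad(theta_wa))
  x <- num / tensions$gamma_fw
  if (x > 1)
    stop(sprintf(
      "complete wetting underwater: gamma_fa cos(theta_fa) - gamma_wa cos(theta_wa) = %.4g exceeds +gamma_fw = %.4g",
      num, tensions$gamma_fw), call. = FALSE)
  if (x < -1)
    stop(sprintf(
      "complete dewetting underwater: gamma_fa cos(theta_fa) - gamma_wa cos(theta_wa) = %.4g is below -gamma_fw = %.4g",
      num, -tensions$gamma_fw), call. = FALSE)
  rad2deg(acos(x))
}

#' Wetting description of one substrate
#'
#' Bundles the in-air contact angles of the adhesive fluid and of water on a
#' named substrate, and derives the underwater fluid angle via
#' [underwater_contact_angle()].
#'
#' @param name Substrate name (e.g. `"glass"`, `"PFOTS"`).
#' @param theta_fa Fluid contact angle in air (deg).
#' @param theta_wa Water contact angle in air (deg).
#' @param tensions A [fluid_tensions()] used to derive `theta_fw`.
#' @return An object of class `substrate_wetting` with fields `name`,
#'   `theta_fa`, `theta_wa`, `theta_fw` and the tensions.
#' @export
substrate_wetting <- function(name, theta_fa, theta_wa, tensions) {
  structure(list(
    name = name, theta_fa = theta_fa, theta_wa = theta_wa,
    theta_fw = underwater_contact_angle(tensions, theta_fa, theta_wa),
    tensions = tensions), class = "substrate_wetting")
}

#' @export
print.substrate_wetting <- function(x, ...) {
  cat(sprintf(
    "<substrate_wetting> %s: theta_fa = %.4g deg, theta_wa = %.4g deg, theta_fw = %.4g deg\n",
    x$name, x$theta_fa, x$theta_wa, x$theta_fw))
  invisible(x)
}
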