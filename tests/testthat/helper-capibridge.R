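# Shared fixtures: small reduced-unit bridges and quick grids.

unit_spec <- function(theta, phi = 2, tension = 1)
  bridge_spec(1, phi = phi, contact_angle = theta, tension = tension)

quick_gaps <- function(n = 80, to = 1.25) seq(0.1, to, length.out = n)

# catenoid through (r = 1, z = gap) with waist on the substrate (theta = 90):
# r(z) = c cosh(z / c); returns c and the enclosed volume (closed form)
catenoid_data <- function(gap) {
  c0 <- stats::uniroot(function(c) c * cosh(gap / c) - 1,
                       c(0.2, 0.999), tol = 1e-14)$root
  vol <- pi * c0^2 * (gap / 2 + c0 * sinh(2 * gap / c0) / 4)
  list(c = c0, volume = vol)
}

# small pad for fast pad-level tests (same physics, fewer hairs)
tiny_pad <- function(n_hairs = 10)
  pad_geometry(pad_diameter = 200, hair_diameter = 2, hair_length = 50,
               n_hairs = n_hairs, phi_f = 2)
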