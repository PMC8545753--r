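test_that("bridge_spec round-trips volume and size parameter", {
  sp <- bridge_spec(2, phi = 1.5, contact_angle = 70, tension = 27.5)
  expect_equal(size_parameter(sp), 1.5, tolerance = 1e-12)
  sp2 <- bridge_spec(2, volume = sp$volume, contact_angle = 70, tension = 27.5)
  expect_equal(size_parameter(sp2), 1.5, tolerance = 1e-12)
  expect_error(bridge_spec(1, phi = 2, contact_angle = 0, tension = 1),
               "invalid-spec")
  expect_error(bridge_spec(1, phi = 2, contact_angle = 185, tension = 1),
               "invalid-spec")
})

test_that("zero-pressure bridge matches the catenoid through the same boundary data", {
  gap <- 0.4
  cat0 <- catenoid_data(gap)
  sp <- bridge_spec(1, volume = cat0$volume, contact_angle = 90, tension = 1)
  st <- solve_bridge(sp, gap)
  # |dP| * s / gamma below 1e-4 qualifies as the zero-pressure limit
  s_f <- equivalent_radius(sp$volume)
  expect_lt(abs(st$laplace_pressure) * s_f, 1e-4)
  r_cat <- cat0$c * cosh(st$profile$z_um / cat0$c)
  expect_lt(max(abs(st$profile$r_um - r_cat) / r_cat), 1e-3)
})

test_that("solved states conserve volume and satisfy the boundary conditions", {
  for (theta in c(30, 75, 120)) {
    for (gap in c(0.15, 0.3, 0.45)) {
      st <- solve_bridge(unit_spec(theta), gap)
      red <- st$reduced
      sh <- capibridge:::yl_shoot_cpp(red$p, red$rb, red$S,
                                      theta * pi / 180, red$n)
      expect_lt(abs(sh$V - red$vol) / red$vol, 1e-6)
      expect_lt(abs(sh$r - 1), 1e-6)
      expect_lt(abs(sh$z - red$gap) / red$gap, 1e-6)
      # profile starts on the substrate and ends at the pin radius
      expect_equal(st$profile$z_um[1], 0)
      expect_equal(tail(st$profile$r_um, 1), 1, tolerance = 1e-6)
    }
  }
})

test_that("shooting and energy-minimization backends agree away from reentrant shapes", {
  sp <- unit_spec(60)
  s1 <- solve_bridge(sp, 0.5)
  s2 <- solve_bridge_energy(sp, 0.5, n_segments = 200)
  expect_lt(abs(s1$force - s2$force) / abs(s1$force), 0.01)
  expect_lt(abs(s1$laplace_pressure - s2$laplace_pressure) /
              abs(s1$laplace_pressure), 0.02)
  expect_lt(abs(s1$bottom_radius - s2$bottom_radius), 0.01)
})

test_that("force equals -dE/dd at fixed volume", {
  for (theta in c(45, 90, 135)) {
    sp <- unit_spec(theta)
    st <- solve_bridge(sp, 0.3)
    d <- 1e-3
    ep <- solve_bridge(sp, 0.3 + d)$energy
    em <- solve_bridge(sp, 0.3 - d)$energy
    f_energy <- -(ep - em) / (2 * d) * 1e-3   # fJ/um = nN -> uN
    expect_lt(abs(st$force - f_energy) / abs(st$force), 0.01)
  }
})

test_that("force is exactly linear in the length scale", {
  sp1 <- unit_spec(70)
  f1 <- solve_bridge(sp1, 0.3)$force
  for (lam in c(0.1, 3, 50)) {
    spl <- bridge_spec(lam, volume = sp1$volume * lam^3, contact_angle = 70,
                       tension = 1)
    fl <- solve_bridge(spl, 0.3 * lam)$force
    expect_lt(abs(fl / (lam * f1) - 1), 1e-3)
  }
})

test_that("pure-tension force at theta = 90 with zero Laplace pressure", {
  gap <- 0.4
  cat0 <- catenoid_data(gap)
  sp <- bridge_spec(1, volume = cat0$volume, contact_angle = 90, tension = 1)
  st <- solve_bridge(sp, gap)
  fc <- bridge_force(st)
  # R_bottom = c (the waist), gamma = 1 mN/m: f = -2 pi c * 1e-3 uN
  expect_equal(fc$total, -2 * pi * cat0$c * 1e-3, tolerance = 1e-3)
  expect_lt(abs(fc$laplace / fc$total), 1e-3)
})

test_that("force curves are repulsive at contact, attractive at intermediate gap, zero after rupture", {
  fc <- force_curve(unit_spec(30), quick_gaps(), n_segments = 100)
  expect_gt(fc$force[1], 0)
  expect_lt(min(fc$force), 0)
  expect_true(any(fc$ruptured))
  expect_true(all(fc$force[fc$ruptured] == 0))
  rg <- attr(fc, "rupture_gap")
  expect_true(all(fc$gap[!fc$ruptured] <= rg + 1e-9))
  # forces decay toward zero approaching rupture
  last <- max(which(!fc$ruptured))
  expect_lt(abs(fc$force[last]), abs(attr(fc, "adhesion_force")) / 2)
})

test_that("adhesion force converges under gap-grid refinement", {
  sp <- unit_spec(56)
  a1 <- attr(force_curve(sp, quick_gaps(150), n_segments = 100),
             "adhesion_force")
  a2 <- attr(force_curve(sp, quick_gaps(300), n_segments = 100),
             "adhesion_force")
  expect_lt(abs(a1 - a2) / abs(a2), 0.005)
})

test_that("adhesion_from_curve recovers a parabola vertex and handles flat curves", {
  x <- seq(0.1, 1, length.out = 25)
  y <- 3 * (x - 0.4371)^2 - 2.5
  got <- capibridge:::curve_minimum(x, y)
  expect_equal(got$gap, 0.4371, tolerance = 1e-6)
  expect_equal(got$force, -2.5, tolerance = 1e-6)
  flat <- data.frame(gap = x, force = rep(0, 25))
  expect_equal(adhesion_from_curve(flat)$force, 0)
  expect_equal(adhesion_from_curve(flat)$gap, x[1])
})

test_that("gaps beyond rupture raise a classed rupture condition", {
  expect_error(solve_bridge(unit_spec(60), 5),
               class = "capibridge_ruptured")
  # grid entirely beyond rupture: zero forces, rupture_gap below the grid
  fc <- force_curve(unit_spec(60), seq(2, 3, length.out = 5))
  expect_true(all(fc$force == 0))
  expect_true(all(fc$ruptured))
})

test_that("reentrant equilibria are flagged as overhanging", {
  st <- solve_bridge(unit_spec(30), 0.25)
  expect_true(st$overhang)
  st2 <- solve_bridge(unit_spec(90), 0.3)
  expect_false(st2$overhang)
})
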