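test_that("contact-angle sweep normalization is scale free and tabulates components", {
  sw <- sweep_contact_angle(theta_grid = c(30, 90, 150), n_gaps = 60,
                            n_segments = 100)
  expect_equal(nrow(sw), 3)
  # total = Laplace + tension components at the adhesion gap
  expect_equal(sw$F_norm, sw$F_norm_laplace + sw$F_norm_tension,
               tolerance = 0.02)
  expect_true(all(diff(abs(sw$F_norm)) < 0))   # decreasing with theta here
  expect_equal(max(sw$pct_of_max), 100)
})

test_that("a hair diameter giving a single hair reproduces the single-bridge result", {
  cfg <- beetle_config()
  # area_total = pi (Dh/2)^2 with one hair
  Dh <- 4
  sw <- sweep_hair_diameter(cfg, Dh_grid = Dh, area_total = pi * (Dh / 2)^2,
                            modes = "air", n_gaps = 60, n_segments = 100)
  expect_true(all(sw$n_hairs == 1))
  sub <- cfg$substrates$glass
  sp <- bridge_spec(Dh / 2, phi = 2, contact_angle = sub$theta_fa,
                    tension = cfg$tensions$gamma_fa)
  pad1 <- pad_geometry(cfg$pad$pad_diameter, Dh, cfg$pad$hair_length, 1,
                       phi_f = 2)
  fc <- force_curve(sp, default_gap_grid(pad1, n = 60), n_segments = 100)
  expect_equal(sw$adhesion_uN[sw$substrate == "glass"],
               adhesion_from_curve(fc)$force, tolerance = 1e-8)
})

test_that("contact splitting scales adhesion like 1/Dh at fixed total area", {
  cfg <- beetle_config()
  sw <- sweep_hair_diameter(cfg, Dh_grid = c(1, 2, 4),
                            modes = "underwater_no_bubble",
                            n_gaps = 100, n_segments = 100)
  for (s in unique(sw$substrate)) {
    d <- sw[sw$substrate == s, ]
    expect_true(all(diff(abs(d$adhesion_uN)) < 0))  # stronger for finer hairs
    slope <- coef(lm(log(abs(adhesion_uN)) ~ log(Dh_um), data = d))[2]
    expect_lt(abs(slope + 1), 0.1)
  }
})

test_that("studies are deterministic and embed their provenance", {
  cfg <- beetle_config()
  a <- sweep_contact_angle(theta_grid = c(60, 120), n_gaps = 40,
                           n_segments = 100)
  b <- sweep_contact_angle(theta_grid = c(60, 120), n_gaps = 40,
                           n_segments = 100)
  expect_identical(a, b)
  sw <- sensitivity(cfg, "gamma_fw", relative_perturbations = 0,
                    n_gaps = 40, n_segments = 100)
  prov <- attr(sw, "provenance")
  expect_true(all(c("gamma_fw_mN_m", "n_hairs") %in% prov$parameter))
  path <- tempfile(fileext = ".csv")
  write_study(sw, path)
  head <- readLines(path, n = 1)
  expect_match(head, "^# gamma_fa_mN_m = 27.5")
})

test_that("zero perturbation reproduces the baseline ratio exactly", {
  cfg <- beetle_config()
  sw <- sensitivity(cfg, "gamma_fw", relative_perturbations = c(-0.1, 0, 0.1),
                    n_gaps = 60, n_segments = 100)
  base <- sw[sw$delta == 0 & sw$substrate == "PFOTS", ]
  sub <- cfg$substrates$PFOTS
  wet <- pad_adhesion(net_force_uniform(
    cfg$pad, sub, "underwater_no_bubble",
    gaps = default_gap_grid(cfg$pad, n = 60), n_segments = 100))$force
  dry <- pad_adhesion(net_force_uniform(
    cfg$pad, sub, "air",
    gaps = default_gap_grid(cfg$pad, n = 60), n_segments = 100))$force
  expect_equal(base$ratio, abs(wet / dry), tolerance = 1e-12)
  # the fluid-water tension moves the ratio monotonically
  r <- sw$ratio[sw$substrate == "PFOTS"][order(sw$delta[sw$substrate == "PFOTS"])]
  expect_true(all(diff(r) > 0) || all(diff(r) < 0))
})

test_that("pad and hair geometry do not affect the no-bubble wet/dry ratio", {
  cfg <- beetle_config()
  sw <- sensitivity(cfg, "pad_diameter", relative_perturbations = c(0, 0.2),
                    n_gaps = 60, n_segments = 100)
  for (s in unique(sw$substrate)) {
    r <- sw$ratio[sw$substrate == s]
    expect_lt(abs(r[2] / r[1] - 1), 1e-3)
  }
})

test_that("whole-animal prediction flips the air/water ordering between glass and PTFE", {
  gk <- gecko_config()
  pred <- predict_whole_animal(gk, n_gaps = 80, n_segments = 100)
  get <- function(s, c) pred$whole_animal_N[pred$substrate == s &
                                            pred$condition == c]
  expect_gt(abs(get("PTFE", "wet")), abs(get("PTFE", "dry")))
  expect_gt(abs(get("glass", "dry")), abs(get("glass", "wet")))
})
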