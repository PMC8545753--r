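#' Beetle model configuration (ladybird hairy pad)
#'
#' The default parameter set for the ladybird-beetle hairy pad: an
#' n-hexadecane-like tarsal fluid (`gamma_fa` 27.5, `gamma_wa` 72.8,
#' `gamma_fw` 53.5 mN/m), receding contact angles on untreated glass
#' (hydrophilic; fluid 6 deg, water 20 deg) and fluorinated PFOTS glass
#' (hydrophobic; fluid 56 deg, water 93 deg), and a pad of 2000 hairs of tip
#' diameter 2 µm (total hair contact area 6283 µm²), length 50 µm, on a
#' 200 µm pad, each tip carrying a fluid bridge at size parameter
#' `phi_f = 2`. The trapped bubble has size parameter `phi_b = 1.5`
#' (equivalent-sphere radius two-thirds of the pad radius).
#'
#' @return List with elements `tensions` ([fluid_tensions()]), `substrates`
#'   (named list of [substrate_wetting()]), `pad` ([pad_geometry()]) and
#'   `bubble` ([bubble_spec()]).
#' @examples
#' cfg <- beetle_config()
#' cfg$substrates$PFOTS$theta_fw   # underwater fluid angle on PFOTS
#' @export
beetle_config <- function() {
  tns <- fluid_tensions(gamma_fa = 27.5, gamma_wa = 72.8, gamma_fw = 53.5)
  list(
    tensions = tns,
    substrates = list(
      glass = substrate_wetting("glass", theta_fa = 6, theta_wa = 20, tns),
      PFOTS = substrate_wetting("PFOTS", theta_fa = 56, theta_wa = 93, tns)),
    pad = pad_geometry(pad_diameter = 200, hair_diameter = 2,
                       hair_length = 50, n_hairs = 2000, phi_f = 2),
    bubble = bubble_spec(phi_b = 1.5))
}

#' Gecko model configuration (phospholipid-mediated toe adhesion)
#'
#' Parameter set for the whole-animal gecko prediction: setal tip diameter
#' 400 nm, toe pad diameter 4 mm with 10% hair coverage, phospholipid fluid
#' volume 4.19e-3 fl per hair (`phi_f = 2`), phospholipid tensions 30 mN/m
#' in air and 42 mN/m against water, and contact angles of the phospholipid
#' (6, 10, 20, 80 deg) and of water (50, 85, 94, 97 deg) on glass, PMMA,
#' OTS-SAM and PTFE. Twenty toes (5 per leg, 4 legs) make up the animal.
#'
#' @return List with `tensions`, `substrates`, `toe` ([pad_geometry()] of one
#'   toe), `n_toes` and `coverage`.
#' @export
gecko_config <- function() {
  tns <- fluid_tensions(gamma_fa = 30, gamma_wa = 72.8, gamma_fw = 42)
  ang <- list(glass = c(6, 50), PMMA = c(10, 85),
              `OTS-SAM` = c(20, 94), PTFE = c(80, 97))
  subs <- lapply(names(ang), function(nm)
    substrate_wetting(nm, theta_fa = ang[[nm]][1], theta_wa = ang[[nm]][2], tns))
  names(subs) <- names(ang)
  toe_d <- 4000; hair_d <- 0.4; coverage <- 0.1
  n_toe <- round_half_up(coverage * pi * (toe_d / 2)^2 / (pi * (hair_d / 2)^2))
  list(tensions = tns, substrates = subs,
       toe = pad_geometry(pad_diameter = toe_d, hair_diameter = hair_d,
                          hair_length = 50, n_hairs = n_toe,
                          fluid_volume = 4.19e-3),
       n_toes = 20L, coverage = coverage)
}

#' Read a model configuration from a YAML file
#'
#' The file mirrors the structure of [beetle_config()]: a `fluids` section
#' with the three tensions, a `substrates` section with per-substrate in-air
#' contact angles, a `pad` section and an optional `bubble` section. See
#' `system.file("extdata", "beetle.yaml", package = "capibridge")` for a
#' complete example. Derived underwater angles are computed on load and
#' echoed by [config_table()].
#'
#' @param path Path to a YAML config file.
#' @return A config list as from [beetle_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fl <- raw$fluids
  tns <- fluid_tensions(fl$gamma_fa, fl$gamma_wa, fl$gamma_fw)
  subs <- lapply(names(raw$substrates), function(nm) {
    s <- raw$substrates[[nm]]
    substrate_wetting(nm, s$theta_fa, s$theta_wa, tns)
  })
  names(subs) <- names(raw$substrates)
  p <- raw$pad
  pad <- pad_geometry(p$pad_diameter, p$hair_diameter, p$hair_length,
                      p$n_hairs,
                      fluid_volume = p$fluid_volume, phi_f = p$phi_f)
  bub <- if (!is.null(raw$bubble))
    bubble_spec(volume = raw$bubble$volume, phi_b = raw$bubble$phi_b)
  list(tensions = tns, substrates = subs, pad = pad, bubble = bub)
}

#' Resolved parameter table of a configuration
#'
#' Flattens a config into a two-column data frame (parameter, value) used as
#' the provenance header of study outputs, so every number entering a sweep
#' is auditable.
#'
#' @param cfg A config list ([beetle_config()], [read_config()], ...).
#' @return Data frame with columns `parameter` and `value`.
#' @export
config_table <- function(cfg) {
  rows <- list(
    c("gamma_fa_mN_m", cfg$tensions$gamma_fa),
    c("gamma_wa_mN_m", cfg$tensions$gamma_wa),
    c("gamma_fw_mN_m", cfg$tensions$gamma_fw))
  for (s in cfg$substrates)
    rows <- c(rows, list(
      c(paste0("theta_fa_", s$name, "_deg"), s$theta_fa),
      c(paste0("theta_wa_", s$name, "_deg"), s$theta_wa),
      c(paste0("theta_fw_", s$name, "_deg"), round(s$theta_fw, 2))))
  pad <- cfg$pad %||% cfg$toe
  if (!is.null(pad))
    rows <- c(rows, list(
      c("pad_diameter_um", pad$pad_diameter),
      c("hair_diameter_um", pad$hair_diameter),
      c("hair_length_um", pad$hair_length),
      c("n_hairs", pad$n_hairs),
      c("fluid_volume_fl", signif(pad$fluid_volume, 6))))
  if (!is.null(cfg$bubble)) {
    vb <- if (!is.null(cfg$pad)) bubble_volume(cfg$bubble, cfg$pad)
          else cfg$bubble$volume
    rows <- c(rows, list(c("bubble_volume_fl", signif(vb, 6))))
  }
  data.frame(parameter = vapply(rows, `[`, "", 1),
             value = vapply(rows, `[`, "", 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
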