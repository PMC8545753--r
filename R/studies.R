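#' Contact-angle sweep of the single-bridge adhesion
#'
#' Solves force-distance curves of one pinned bridge at fixed size parameter
#' `phi_f` for a grid of substrate contact angles, and tabulates the
#' normalized adhesion `F_min / (gamma s_f)` together with its
#' Laplace-pressure and surface-tension components (evaluated by re-solving
#' the bridge at the refined adhesion gap). Capillarity without gravity is
#' scale free, so the normalized result is independent of the tension and
#' pin radius used.
#'
#' @param phi_f Fluid size parameter (default 2).
#' @param theta_grid Contact angles (deg); the default covers the sweep from
#'   near-complete wetting (6 deg) to near-complete dewetting (150 deg).
#' @param n_gaps Gap-grid resolution per curve.
#' @param n_segments Profile resolution per solve.
#' @return A `sweep_result` data frame: `theta_deg`, `F_norm`,
#'   `F_norm_laplace`, `F_norm_tension`, `gap_norm` (adhesion gap over
#'   `s_f`), `pct_of_max`.
#' @examples
#' \donttest{sweep_contact_angle(theta_grid = c(30, 90, 150), n_gaps = 60)}
#' @export
sweep_contact_angle <- function(phi_f = 2,
                                theta_grid = c(6, 30, 56, 70, 90, 100,
                                               120, 138, 150),
                                n_gaps = 200L, n_segments = 200L) {
  stopifnot(phi_f > 0)
  s_f <- 1 / phi_f           # pin radius 1, tension 1: results are reduced
  res <- lapply(theta_grid, function(th) {
    sp <- bridge_spec(1, phi = phi_f, contact_angle = th, tension = 1)
    fc <- force_curve(sp, seq(0.05 * 2, 2.5 * s_f, length.out = n_gaps) / 1,
                      n_segments = n_segments)
    adh <- adhesion_from_curve(fc)
    st <- solve_bridge(sp, adh$gap, n_segments = n_segments)
    # forces are in uN for gamma = 1 mN/m, R = 1 um; 1e3/(gamma s_f) makes
    # them dimensionless
    k <- 1e3 / s_f
    data.frame(theta_deg = th, F_norm = adh$force * k,
               F_norm_laplace = st$force_laplace * k,
               F_norm_tension = st$force_tension * k,
               gap_norm = adh$gap / s_f)
  })
  out <- do.call(rbind, res)
  out$pct_of_max <- 100 * abs(out$F_norm) / max(abs(out$F_norm))
  sweep_result(out, swept = "theta_deg",
               provenance = data.frame(parameter = "phi_f", value = phi_f))
}

#' Force curves of all contact modes on all substrates
#'
#' Computes the pad-level force-distance curve for the three contact modes
#' (in air, underwater without bubble, underwater with the trapped bubble)
#' on every substrate in the configuration, plus the isolated bubble
#' contribution, and the per-(mode, substrate) adhesion forces.
#'
#' @param cfg A config list ([beetle_config()] or [read_config()]).
#' @param gaps Gap grid (µm); defaults to [default_gap_grid()] of the pad.
#' @param n_segments Profile resolution.
#' @return List with `curves` (named `substrate.mode` list of
#'   `pad_force_result`) and `adhesion` (data frame `substrate`, `mode`,
#'   `adhesion_uN`, `gap_um`, `f_bubble_at_adhesion_uN`).
#' @export
substrate_comparison <- function(cfg, gaps = default_gap_grid(cfg$pad),
                                 n_segments = 200L) {
  modes <- c("air", "underwater_no_bubble", "underwater_bubble")
  curves <- list()
  rows <- list()
  for (sub in cfg$substrates) {
    for (mode in modes) {
      r <- pad_force(cfg$pad, sub, mode, gaps = gaps, bubble = cfg$bubble,
                     n_segments = n_segments)
      curves[[paste(sub$name, mode, sep = ".")]] <- r
      adh <- pad_adhesion(r)
      ig <- which.min(abs(r$gap - adh$gap))
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = sub$name, mode = mode, adhesion_uN = adh$force,
        gap_um = adh$gap, f_bubble_at_adhesion_uN = r$f_bubble[ig])
    }
  }
  adhesion <- do.call(rbind, rows)
  attr(adhesion, "provenance") <- config_table(cfg)
  list(curves = curves, adhesion = adhesion)
}

#' Bubble-volume sweep of underwater pad adhesion
#'
#' Varies the trapped-bubble volume at otherwise fixed parameters and
#' records, per substrate, the adhesion force of the underwater-with-bubble
#' mode, the fraction of hairs contacting inside the bubble at the adhesion
#' gap, and whether all hairs are entrapped. The default grid is
#' logarithmic in volume and spans the crossover where `N_in` first drops
#' below `N`.
#'
#' @param cfg A config list.
#' @param Vb_grid Bubble volumes (µm³). Default: 16 log-spaced values with
#'   reduced volume `V_b / (D_p/2)^3` between 0.25 and 4.
#' @param gaps Gap grid (µm).
#' @param n_segments Profile resolution.
#' @return A `sweep_result` with one row per (substrate, volume).
#' @export
sweep_bubble_volume <- function(cfg, Vb_grid = NULL,
                                gaps = default_gap_grid(cfg$pad),
                                n_segments = 200L) {
  Rp <- cfg$pad$pad_diameter / 2
  if (is.null(Vb_grid))
    Vb_grid <- exp(seq(log(0.25), log(4), length.out = 16L)) * Rp^3
  rows <- list()
  for (sub in cfg$substrates) {
    for (vb in Vb_grid) {
      r <- net_force_bubble(cfg$pad, bubble_spec(volume = vb), sub,
                            gaps = gaps, n_segments = n_segments)
      adh <- pad_adhesion(r)
      ig <- which.min(abs(r$gap - adh$gap))
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = sub$name, Vb_fl = vb,
        phi_b = Rp / equivalent_radius(vb),
        adhesion_uN = adh$force, N_in_frac = r$N_in[ig] / cfg$pad$n_hairs,
        f_bubble_uN = r$f_bubble[ig],
        all_entrapped = r$N_in[ig] == cfg$pad$n_hairs)
    }
  }
  sweep_result(do.call(rbind, rows), swept = "Vb_fl",
               provenance = config_table(cfg))
}

#' Contact-splitting sweep: hair diameter at fixed total contact area
#'
#' Varies the hair tip diameter `D_h` while keeping the total hair contact
#' area fixed at `area_total` (default 6283 µm²), so the number of hairs
#' scales as `N = round(area_total / (pi (D_h/2)^2))`. The fluid volume per
#' hair rescales with the hair (`phi_f` fixed), so the single-bridge force
#' is self-similar (`f` proportional to `D_h`) and the net adhesion grows as
#' contact is split into more, finer hairs.
#'
#' @param cfg A config list.
#' @param Dh_grid Hair tip diameters (µm).
#' @param area_total Fixed total hair contact area (µm²).
#' @param modes Contact modes to evaluate.
#' @param n_gaps Gap-grid resolution.
#' @param n_segments Profile resolution.
#' @return A `sweep_result` with one row per (substrate, mode, diameter).
#' @export
sweep_hair_diameter <- function(cfg, Dh_grid = c(0.5, 1, 2, 4, 8),
                                area_total = 6283,
                                modes = c("air", "underwater_no_bubble",
                                          "underwater_bubble"),
                                n_gaps = 200L, n_segments = 200L) {
  phi_f <- size_parameter(bridge_spec(
    cfg$pad$hair_diameter / 2, volume = cfg$pad$fluid_volume,
    contact_angle = 90, tension = 1))
  rows <- list()
  for (Dh in Dh_grid) {
    N <- max(1L, as.integer(round_half_up(area_total / (pi * (Dh / 2)^2))))
    pad <- pad_geometry(cfg$pad$pad_diameter, Dh, cfg$pad$hair_length, N,
                        phi_f = phi_f)
    gaps <- default_gap_grid(pad, n = n_gaps)
    for (sub in cfg$substrates) {
      for (mode in modes) {
        r <- pad_force(pad, sub, mode, gaps = gaps, bubble = cfg$bubble,
                       n_segments = n_segments)
        rows[[length(rows) + 1L]] <- data.frame(
          substrate = sub$name, mode = mode, Dh_um = Dh, n_hairs = N,
          adhesion_uN = pad_adhesion(r)$force)
      }
    }
  }
  sweep_result(do.call(rbind, rows), swept = "Dh_um",
               provenance = config_table(cfg))
}

#' Whole-animal adhesion prediction
#'
#' Predicts per-toe and whole-animal adhesion on each substrate of a gecko
#' configuration, in the dry mode (hairs in air) and the wet mode (submerged,
#' no bubble: phospholipid bridges in water at the derived underwater
#' contact angle).
#'
#' @param cfg A gecko-style config ([gecko_config()]).
#' @param n_gaps Gap-grid resolution.
#' @param n_segments Profile resolution.
#' @return A `sweep_result`: `substrate`, `condition` (dry/wet),
#'   `theta_deg` (the acting contact angle), `per_toe_uN`, `whole_animal_N`.
#' @export
predict_whole_animal <- function(cfg, n_gaps = 200L, n_segments = 200L) {
  gaps <- default_gap_grid(cfg$toe, n = n_gaps)
  rows <- list()
  for (sub in cfg$substrates) {
    for (cond in c("dry", "wet")) {
      mode <- if (cond == "dry") "air" else "underwater_no_bubble"
      r <- net_force_uniform(cfg$toe, sub, mode, gaps = gaps,
                             n_segments = n_segments)
      f <- pad_adhesion(r)$force
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = sub$name, condition = cond,
        theta_deg = if (cond == "dry") sub$theta_fa else sub$theta_fw,
        per_toe_uN = f,
        whole_animal_N = f * cfg$n_toes * 1e-6)
    }
  }
  sweep_result(do.call(rbind, rows), swept = "substrate",
               provenance = config_table(cfg))
}

#' Sensitivity of the underwater/air adhesion ratio to one parameter
#'
#' Recomputes the ratio `|adhesion underwater| / |adhesion in air|` per
#' substrate while scaling one model parameter by `1 + delta` for each
#' relative perturbation `delta`, and reports the elasticity
#' `d log(ratio) / d log(parameter)` (least-squares slope over the perturbed
#' points).
#'
#' @param cfg A config list.
#' @param parameter One of `"gamma_fa"`, `"gamma_wa"`, `"gamma_fw"`,
#'   `"pad_diameter"`, `"hair_diameter"`, `"hair_length"`, `"fluid_volume"`,
#'   `"bubble_volume"`.
#' @param relative_perturbations Relative changes applied to the parameter.
#' @param mode Underwater mode used in the numerator.
#' @param n_gaps Gap-grid resolution.
#' @param n_segments Profile resolution.
#' @return A `sweep_result` with per-(substrate, perturbation) ratios and an
#'   `elasticity` attribute (named per substrate).
#' @export
sensitivity <- function(cfg, parameter,
                        relative_perturbations = c(-0.1, 0, 0.1),
                        mode = c("underwater_no_bubble", "underwater_bubble"),
                        n_gaps = 200L, n_segments = 200L) {
  mode <- match.arg(mode)
  par_ok <- c("gamma_fa", "gamma_wa", "gamma_fw", "pad_diameter",
              "hair_diameter", "hair_length", "fluid_volume",
              "bubble_volume")
  if (!parameter %in% par_ok)
    stop("unknown parameter: ", parameter, call. = FALSE)
  rows <- list()
  for (delta in relative_perturbations) {
    c2 <- perturb_config(cfg, parameter, delta)
    for (sub in c2$substrates) {
      wet <- pad_force(c2$pad, sub, mode, bubble = c2$bubble,
                       gaps = default_gap_grid(c2$pad, n = n_gaps),
                       n_segments = n_segments)
      dry <- pad_force(c2$pad, sub, "air",
                       gaps = default_gap_grid(c2$pad, n = n_gaps),
                       n_segments = n_segments)
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = sub$name, parameter = parameter, delta = delta,
        wet_uN = pad_adhesion(wet)$force, dry_uN = pad_adhesion(dry)$force,
        ratio = abs(pad_adhesion(wet)$force / pad_adhesion(dry)$force))
    }
  }
  out <- do.call(rbind, rows)
  el <- vapply(unique(out$substrate), function(s) {
    d <- out[out$substrate == s, ]
    if (length(unique(d$delta)) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(log(ratio) ~ log1p(delta), data = d))[2])
  }, numeric(1))
  res <- sweep_result(out, swept = "delta", provenance = config_table(cfg))
  attr(res, "elasticity") <- el
  res
}

perturb_config <- function(cfg, parameter, delta) {
  s <- 1 + delta
  tns <- cfg$tensions
  pad <- cfg$pad
  bub <- cfg$bubble
  if (parameter %in% c("gamma_fa", "gamma_wa", "gamma_fw")) {
    tns[[parameter]] <- tns[[parameter]] * s
    tns <- fluid_tensions(tns$gamma_fa, tns$gamma_wa, tns$gamma_fw)
  } else if (parameter == "bubble_volume") {
    bub <- bubble_spec(volume = bubble_volume(bub, pad) * s)
  } else {
    val <- pad[[parameter]] * s
    args <- list(pad_diameter = pad$pad_diameter,
                 hair_diameter = pad$hair_diameter,
                 hair_length = pad$hair_length, n_hairs = pad$n_hairs,
                 fluid_volume = pad$fluid_volume)
    args[[parameter]] <- val
    pad <- do.call(pad_geometry, args)
  }
  subs <- lapply(cfg$substrates, function(x)
    substrate_wetting(x$name, x$theta_fa, x$theta_wa, tns))
  names(subs) <- names(cfg$substrates)
  list(tensions = tns, substrates = subs, pad = pad, bubble = bub)
}

sweep_result <- function(df, swept, provenance) {
  structure(df, class = c("sweep_result", "data.frame"),
            swept = swept, provenance = provenance)
}

#' Write a study table with its provenance header
#'
#' Writes a sweep/adhesion table as delimited text, preceded by `#`-prefixed
#' lines holding the fully resolved parameter set that produced it.
#'
#' @param x A `sweep_result` (or any data frame with a `provenance`
#'   attribute).
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_study <- function(x, path, sep = ",") {
  prov <- attr(x, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov))
    writeLines(sprintf("# %s = %s", prov$parameter, prov$value), con)
  utils::write.table(as.data.frame(x), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
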