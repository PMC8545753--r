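#' Protocol stages of an adhesion test recording
#'
#' The motion protocol of one approach-retract adhesion test, in order:
#' approach, lateral pull, second approach (compression), pause, retract.
#' @export
trace_stages <- function() c("approach", "lateral", "approach2", "pause", "retract")

#' Construct a force trace
#'
#' A force-versus-time recording with a per-sample motion-stage label from
#' the instrument's motion log. Negative force = attraction.
#'
#' @param time Sample times (s), strictly increasing.
#' @param force Forces (µN), finite.
#' @param stage Per-sample labels from [trace_stages()], appearing in
#'   protocol order.
#' @param metadata Optional list (speeds, step sizes, ground truth, ...).
#' @return An object of class `force_trace` (a data frame).
#' @export
force_trace <- function(time, force, stage, metadata = list()) {
  stopifnot(length(time) == length(force), length(time) == length(stage))
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (!all(is.finite(force)))
    stop("force must be finite", call. = FALSE)
  stage <- as.character(stage)
  if (!all(stage %in% trace_stages()))
    stop("unknown stage label(s): ",
         paste(setdiff(unique(stage), trace_stages()), collapse = ", "),
         call. = FALSE)
  seen <- rle(stage)$values
  if (any(duplicated(seen)) ||
      !identical(seen, trace_stages()[trace_stages() %in% seen]))
    stop("stages must appear contiguously in protocol order", call. = FALSE)
  structure(data.frame(time = time, force = force, stage = stage),
            class = c("force_trace", "data.frame"), metadata = metadata)
}

#' Read / write force traces as delimited text
#'
#' Files have the header `time_s,force_uN,stage`.
#'
#' @param path File path.
#' @rdname trace_io
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  force_trace(d$time_s, d$force_uN, d$stage)
}

#' @param trace A `force_trace`.
#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time, force_uN = trace$force,
               stage = trace$stage),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Block-average a trace to a fixed number of points per stage
#'
#' Each stage is averaged to `points_per_stage` points (both time and force
#' are block means), preserving stage boundaries. A stage with fewer samples
#' than requested keeps its native sampling, with a warning.
#'
#' @param raw A `force_trace`.
#' @param points_per_stage Target points per motion stage (default 512).
#' @return A resampled `force_trace`.
#' @export
resample_per_step <- function(raw, points_per_stage = 512L) {
  stopifnot(inherits(raw, "force_trace"))
  pieces <- lapply(unique(raw$stage), function(sg) {
    d <- raw[raw$stage == sg, ]
    m <- nrow(d)
    if (m < points_per_stage) {
      warning(sprintf("stage '%s' has %d < %d samples; keeping native sampling",
                      sg, m, points_per_stage), call. = FALSE)
      return(d)
    }
    idx <- floor(seq(0, m, length.out = points_per_stage + 1L))
    grp <- factor(findInterval(seq_len(m) - 1L, idx[-length(idx)]),
                  levels = seq_len(points_per_stage))
    data.frame(time = as.numeric(tapply(d$time, grp, mean)),
               force = as.numeric(tapply(d$force, grp, mean)),
               stage = sg)
  })
  out <- do.call(rbind, pieces)
  force_trace(out$time, out$force, out$stage,
              metadata = c(attr(raw, "metadata"),
                           list(points_per_stage = points_per_stage)))
}

#' Subtract a no-contact background recording by matching times
#'
#' Underwater recordings carry a contact-free background (meniscus surface
#' tension and buoyancy acting on the submerged leg) that follows the same
#' motion protocol. It is removed by evaluating the background force at the
#' trace's timestamps (linear interpolation by default; nearest-sample
#' matching for step-like backgrounds) and subtracting.
#'
#' @param trace A `force_trace` with substrate contact.
#' @param background A contact-free `force_trace` of the same protocol.
#' @param match `"interpolate"` (default) or `"nearest"`.
#' @return The corrected `force_trace`; metadata records the background
#'   magnitude (max |background|).
#' @export
background_subtract <- function(trace, background,
                                match = c("interpolate", "nearest")) {
  stopifnot(inherits(trace, "force_trace"), inherits(background, "force_trace"))
  match <- match.arg(match)
  if (!identical(rle(trace$stage)$values, rle(background$stage)$values))
    stop("protocol mismatch: stage sequences differ", call. = FALSE)
  if (min(background$time) > max(trace$time) ||
      max(background$time) < min(trace$time))
    stop("time ranges of trace and background are disjoint", call. = FALSE)
  bg <- if (match == "interpolate") {
    stats::approx(background$time, background$force, xout = trace$time,
                  rule = 2)$y
  } else {
    background$force[vapply(trace$time, function(t)
      which.min(abs(background$time - t)), integer(1))]
  }
  force_trace(trace$time, trace$force - bg, trace$stage,
              metadata = c(attr(trace, "metadata"),
                           list(background_magnitude = max(abs(bg)))))
}

#' Pull-off force of a trace
#'
#' The pull-off force is the minimum (most negative) force during the
#' retraction stage. A retraction that never goes negative is reported as
#' zero pull-off with a `no_adhesion` flag (the bad-contact case).
#'
#' @param trace A `force_trace` containing a retract stage.
#' @return List with `force` (µN, `<= 0`), `magnitude` (`|force|`), `time`
#'   (of the minimum) and `no_adhesion` flag.
#' @export
pulloff_force <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  d <- trace[trace$stage == "retract", ]
  if (nrow(d) == 0L)
    stop("trace has no retract stage", call. = FALSE)
  i <- which.min(d$force)
  if (d$force[i] >= 0)
    return(list(force = 0, magnitude = 0, time = d$time[i],
                no_adhesion = TRUE))
  list(force = d$force[i], magnitude = -d$force[i], time = d$time[i],
       no_adhesion = FALSE)
}

#' Mean pull-off over replicate measurements
#'
#' Replicate pull-offs on fresh substrate spots are averaged (one value per
#' pad) to avoid pseudo-replication in downstream comparisons.
#'
#' @param pulloffs Numeric vector of pull-off forces (µN).
#' @return List with `mean` (µN) and `n`.
#' @export
replicate_mean <- function(pulloffs) {
  stopifnot(is.numeric(pulloffs), length(pulloffs) >= 1L)
  list(mean = mean(pulloffs), n = length(pulloffs))
}

#' Generate a synthetic adhesion-test recording
#'
#' Emulates one five-stage approach-retract recording: stage motions at
#' 62.5 µm/s, a smooth additive background (the meniscus drag on a
#' submerged leg), Gaussian sensor noise, and an adhesion dip of the
#' requested depth during retraction. Returns both the contact trace and the
#' matching contact-free background recording; the injected ground truth is
#' embedded in the metadata.
#'
#' @param pulloff Injected pull-off force (µN, negative = attraction).
#' @param background_amplitude Scale of the smooth background (µN).
#' @param noise_sd Gaussian noise standard deviation (µN).
#' @param seed Integer seed; the pair is deterministic given the seed.
#' @param sample_rate Samples per second.
#' @param stage_lengths Named travel (µm) or duration-equivalent per stage.
#' @param speed Stage speed (µm/s).
#' @return List with `trace` and `background`, both `force_trace` objects.
#' @examples
#' tb <- synth_trace(pulloff = -850, seed = 1)
#' pulloff_force(background_subtract(tb$trace, tb$background))$force
#' @export
synth_trace <- function(pulloff = -850, background_amplitude = 50,
                        noise_sd = 5, seed = 1L, sample_rate = 984,
                        stage_lengths = c(approach = 100, lateral = 100,
                                          approach2 = 10, pause = 62.5,
                                          retract = 120),
                        speed = 62.5) {
  stopifnot(pulloff <= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stages <- trace_stages()
  durations <- stage_lengths[stages] / speed
  n_per <- pmax(8L, as.integer(round(durations * sample_rate)))
  n <- sum(n_per)
  time <- seq_len(n) / sample_rate
  stage <- rep(stages, n_per)
  # contact signal: gentle compression during approaches, adhesion dip on
  # retract placed early in the stage (detachment), zero after rupture
  sig <- numeric(n)
  i_a2 <- which(stage == "approach2"); i_p <- which(stage == "pause")
  sig[i_a2] <- seq(0, 40, length.out = length(i_a2))
  sig[i_p] <- 40 * exp(-seq(0, 3, length.out = length(i_p)))  # relaxation
  i_r <- which(stage == "retract")
  tr <- seq(0, 1, length.out = length(i_r))
  dip_center <- 0.25; dip_width <- 0.06
  sig[i_r] <- 40 * exp(-tr / 0.02) +
    pulloff * exp(-((tr - dip_center) / dip_width)^2)
  # smooth background: slow meniscus drift over the whole protocol
  bgf <- background_amplitude *
    (0.6 * sin(2 * pi * time / max(time)) + 0.4 * time / max(time))
  trace <- force_trace(
    time, sig + bgf + stats::rnorm(n, 0, noise_sd), stage,
    metadata = list(true_pulloff = pulloff, noise_sd = noise_sd,
                    background_amplitude = background_amplitude,
                    speed_um_s = speed, seed = seed))
  background <- force_trace(
    time, bgf + stats::rnorm(n, 0, noise_sd), stage,
    metadata = list(background_amplitude = background_amplitude, seed = seed))
  list(trace = trace, background = background)
}
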