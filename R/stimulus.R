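#' Passive visual stimulation protocol
#'
#' The passive protocol presents 3 s grating trials: 1 s uniform gray, 1 s
#' stationary sinusoidal grating, 1 s of the same grating drifting orthogonal
#' to its orientation. Eight orientations (45 degree steps) are crossed with
#' three spatial period / drift velocity pairs chosen so every pairing drifts
#' at the same temporal frequency (about 7 cycles/s). Grating trials are
#' interleaved with 3 s full-screen blink trials (1 s black - 1 s white - 1 s
#' black, i.e. 0.5 Hz).
#'
#' @name stimulus_protocol
NULL

# rank-matched period (mm/cycle) / velocity (mm/s) pairs: constant cycles/s
.pvis_periods <- c(170, 85, 42.5)
.pvis_velocities <- c(1200, 600, 300)
.pvis_orientations <- seq(0, 315, by = 45)

#' Build a pseudorandom passive visual stimulus sequence
#'
#' Generates \code{24 * reps} grating trials (8 orientations x 3 rank-matched
#' period/velocity pairs, each condition repeated exactly \code{reps} times)
#' plus \code{reps} blink trials, in pseudorandom order with one blink trial
#' placed uniformly within each block of 24 gratings. Each trial lasts 3 s;
#' grating trials carry uniform/stationary/moving epoch boundaries at 0, 1 and
#' 2 s relative to onset, blink trials black/white/black boundaries at the
#' same times.
#'
#' @param reps_per_condition repetitions of each of the 24 grating conditions
#'   (and number of blink trials). The default 100 yields 2,500 trials.
#' @param seed integer seed for the pseudorandom ordering.
#' @param epoch_s duration of each within-trial epoch in seconds.
#' @return A data frame of class \code{"pvis_sequence"}: one row per trial with
#'   columns \code{trial}, \code{kind} ("grating"/"blink"),
#'   \code{orientation_deg}, \code{period_mm}, \code{velocity_mm_s},
#'   \code{onset_s}, and epoch boundary columns \code{t_uniform}, \code{t_still},
#'   \code{t_moving} (epoch start times, seconds from session start).
#' @export
build_pvis_sequence <- function(reps_per_condition = 100, seed = 1L,
                                epoch_s = 1) {
  stopifnot(reps_per_condition >= 1, epoch_s > 0)
  reps <- as.integer(reps_per_condition)
  conds <- expand.grid(orientation_deg = .pvis_orientations,
                       pair = seq_along(.pvis_periods))
  grating <- conds[rep(seq_len(nrow(conds)), each = reps), ]
  n_grating <- nrow(grating)                     # 24 * reps

  set.seed(as.integer(seed))
  ord <- sample.int(n_grating)
  grating <- grating[ord, ]
  # one blink per disjoint block of 25 slots (24 gratings + 1 blink)
  blink_at <- (seq_len(reps) - 1L) * 25L + sample.int(25L, reps, replace = TRUE)
  is_blink <- logical(n_grating + reps)
  is_blink[blink_at] <- TRUE
  kind <- ifelse(is_blink, "blink", "grating")
  n_tot <- n_grating + reps

  orientation <- rep(NA_real_, n_tot)
  period <- rep(NA_real_, n_tot)
  velocity <- rep(NA_real_, n_tot)
  orientation[!is_blink] <- grating$orientation_deg
  period[!is_blink] <- .pvis_periods[grating$pair]
  velocity[!is_blink] <- .pvis_velocities[grating$pair]

  trial_s <- 3 * epoch_s
  onset <- (seq_len(n_tot) - 1) * trial_s
  out <- data.frame(
    trial = seq_len(n_tot),
    kind = kind,
    orientation_deg = orientation,
    period_mm = period,
    velocity_mm_s = velocity,
    onset_s = onset,
    t_uniform = onset,
    t_still = onset + epoch_s,
    t_moving = onset + 2 * epoch_s,
    stringsAsFactors = FALSE
  )
  attr(out, "epoch_s") <- epoch_s
  attr(out, "reps") <- reps
  class(out) <- c("pvis_sequence", "data.frame")
  out
}

#' @export
print.pvis_sequence <- function(x, ...) {
  cat(sprintf("Passive visual stimulus sequence: %d trials (%d grating, %d blink), epoch %g s\n",
              nrow(x), sum(x$kind == "grating"), sum(x$kind == "blink"),
              attr(x, "epoch_s")))
  invisible(x)
}

#' Temporal frequency of a drifting grating
#'
#' @param velocity_mm_s drift velocity in mm/s.
#' @param spatial_period_mm spatial period in mm/cycle; must be positive.
#' @return temporal frequency in cycles/s.
#' @export
grating_temporal_frequency <- function(velocity_mm_s, spatial_period_mm) {
  if (any(spatial_period_mm <= 0)) stop("spatial period must be positive")
  velocity_mm_s / spatial_period_mm
}

#' Apparent temporal frequency of maze stripes during running
#'
#' With \code{n_cycles} grating cycles projected along a track of
#' \code{track_length_cm}, an animal running at \code{run_speed_cm_s}
#' experiences visual motion at \code{run_speed / (track_length / n_cycles)}
#' cycles/s.
#'
#' @param run_speed_cm_s running speed, cm/s (nonnegative).
#' @param track_length_cm track length, cm (positive).
#' @param n_cycles number of grating cycles along the track (positive).
#' @return apparent temporal frequency in cycles/s.
#' @export
apparent_temporal_frequency <- function(run_speed_cm_s, track_length_cm,
                                        n_cycles) {
  if (any(track_length_cm <= 0) || any(n_cycles <= 0))
    stop("track length and cycle count must be positive")
  if (any(run_speed_cm_s < 0)) stop("run speed must be nonnegative")
  run_speed_cm_s / (track_length_cm / n_cycles)
}

#' Stripe phase at a track position
#'
#' Maps a linearized position (percent of track) to the phase of the
#' sinusoidally modulated luminance grating at that location.
#'
#' @param position_pct position along the track in percent, in [0, 100].
#' @param n_cycles grating cycles along the full track.
#' @return phase in degrees, in [0, 360).
#' @export
maze_stripe_phase <- function(position_pct, n_cycles = 16) {
  if (any(position_pct < 0 | position_pct > 100))
    stop("position must be within [0, 100] percent")
  (position_pct / 100 * n_cycles * 360) %% 360
}
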