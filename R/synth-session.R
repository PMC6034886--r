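#' Synthetic linear-maze and passive-stimulation sessions
#'
#' The maze generator emulates a rat shuttling on a linear track whose
#' projected visual environment is randomly swapped between a uniform gray
#' image and a stationary grating after every traversal. Trajectories are
#' constant-speed end-to-end runs separated by Gaussian-jittered reward-zone
#' dwells; each unit fires as an inhomogeneous Poisson process built from an
#' optional Gaussian place field and a multiplicative condition factor that
#' realizes a requested visual modulation index exactly in expectation.
#'
#' @name synthetic_sessions
NULL

#' Linear-maze session configuration
#'
#' @param track_length_cm track length (cm).
#' @param n_trials number of end-to-end traversals.
#' @param run_speed_cm_s running speed during traversals (cm/s).
#' @param reward_zone_cm depth of the reward zone at each track end (cm).
#' @param frame_rate position sampling rate (frames/s).
#' @param lfp_rate LFP sampling rate (samples/s).
#' @param dwell_mean_s mean reward-zone dwell between runs (s).
#' @param dwell_sd_s SD of the dwell time (s).
#' @param n_cycles grating cycles projected along the full track.
#' @param seed integer seed.
#' @return list of class \code{"session_config"}.
#' @export
session_config <- function(track_length_cm = 230, n_trials = 40,
                           run_speed_cm_s = 85, reward_zone_cm = 10,
                           frame_rate = 30, lfp_rate = 1250,
                           dwell_mean_s = 25, dwell_sd_s = 5,
                           n_cycles = 16, seed = 1L) {
  stopifnot(track_length_cm > 0, frame_rate > 0, n_trials >= 2,
            reward_zone_cm < track_length_cm / 2, run_speed_cm_s > 0)
  structure(list(track_length_cm = track_length_cm, n_trials = n_trials,
                 run_speed_cm_s = run_speed_cm_s,
                 reward_zone_cm = reward_zone_cm, frame_rate = frame_rate,
                 lfp_rate = lfp_rate, dwell_mean_s = dwell_mean_s,
                 dwell_sd_s = dwell_sd_s, n_cycles = n_cycles,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Specification of one simulated maze unit
#'
#' @param base_rate_hz spatially uniform baseline rate (spikes/s).
#' @param field_center_pct place-field center (percent of track), or NA for a
#'   spatially uniform unit.
#' @param field_width_pct place-field Gaussian SD (percent of track).
#' @param field_peak_hz added rate at the field center (spikes/s).
#' @param visual_mi ground-truth visual modulation index
#'   (striped vs uniform whole-trial rates), in (-1, 1).
#' @param speed_gain optional linear rate gain with running speed
#'   (spikes/s per cm/s); 0 for speed-independent firing.
#' @param stripe_mod depth of sinusoidal rate modulation by the stripe phase
#'   during striped trials, in [0, 1); the circular MI of the resulting phase
#'   tuning equals this depth exactly in expectation.
#' @param stripe_phase_deg preferred stripe phase (degrees).
#' @return list of class \code{"maze_unit_spec"}.
#' @export
maze_unit_spec <- function(base_rate_hz = 1, field_center_pct = NA,
                           field_width_pct = 8, field_peak_hz = 0,
                           visual_mi = 0, speed_gain = 0,
                           stripe_mod = 0, stripe_phase_deg = 0) {
  if (abs(visual_mi) >= 1) stop("visual MI must lie within (-1, 1)")
  stopifnot(base_rate_hz >= 0, field_peak_hz >= 0,
            stripe_mod >= 0, stripe_mod < 1)
  structure(list(base_rate_hz = base_rate_hz,
                 field_center_pct = field_center_pct,
                 field_width_pct = field_width_pct,
                 field_peak_hz = field_peak_hz, visual_mi = visual_mi,
                 speed_gain = speed_gain, stripe_mod = stripe_mod,
                 stripe_phase_deg = stripe_phase_deg),
            class = "maze_unit_spec")
}

#' Generate a linear-maze session with ground truth
#'
#' @param config a \code{\link{session_config}}.
#' @param units list of \code{\link{maze_unit_spec}}.
#' @return list of class \code{"maze_session"}: \code{positions} (data frame
#'   \code{t}, \code{x_cm}, \code{y_cm} at the frame rate), \code{trials}
#'   (data frame \code{start}, \code{end}, \code{direction},
#'   \code{condition}), \code{spikes} (list of spike-time vectors),
#'   \code{duration_s}, \code{config}, and \code{ground_truth} (per-unit spec
#'   recap).
#' @export
gen_maze_session <- function(config = session_config(), units = list()) {
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$track_length_cm
  dt <- 1 / cfg$frame_rate
  run_dur <- L / cfg$run_speed_cm_s

  conditions <- sample(c("uniform", "striped"), cfg$n_trials, replace = TRUE)
  t_now <- 0
  pos <- numeric(0); tim <- numeric(0)
  trials <- data.frame(start = numeric(cfg$n_trials),
                       end = numeric(cfg$n_trials),
                       direction = character(cfg$n_trials),
                       condition = conditions, stringsAsFactors = FALSE)
  # condition of the projected scene as a step function of time: the scene is
  # swapped when the animal completes a run, so trial i's condition holds from
  # the end of run i-1 through the end of run i
  scene_change_t <- numeric(cfg$n_trials)
  at_end <- 0      # current track end (0 or L)
  for (i in seq_len(cfg$n_trials)) {
    dwell <- max(2, stats::rnorm(1, cfg$dwell_mean_s, cfg$dwell_sd_s))
    td <- seq(0, dwell, by = dt)
    pos <- c(pos, rep(at_end, length(td)))
    tim <- c(tim, t_now + td)
    t_now <- t_now + dwell
    scene_change_t[i] <- if (i == 1) 0 else trials$end[i - 1]
    tr <- seq(0, run_dur, by = dt)
    xr <- if (at_end == 0) tr * cfg$run_speed_cm_s else L - tr * cfg$run_speed_cm_s
    pos <- c(pos, xr)
    tim <- c(tim, t_now + tr)
    trials$start[i] <- t_now
    trials$end[i] <- t_now + run_dur
    trials$direction[i] <- if (at_end == 0) "forward" else "backward"
    t_now <- t_now + run_dur + dt
    at_end <- L - at_end
  }
  duration <- t_now + 2
  positions <- data.frame(t = tim, x_cm = pos,
                          y_cm = stats::rnorm(length(pos), 0, 0.5))

  cond_at <- function(t) {      # scene condition as a function of time
    idx <- findInterval(t, scene_change_t)
    idx[idx < 1] <- 1
    conditions[pmin(idx, cfg$n_trials)]
  }
  pos_at <- function(t) stats::approx(tim, pos, xout = t, rule = 2)$y
  speed_at <- function(t) {
    v <- c(0, abs(diff(pos)) / dt)
    stats::approx(tim, v, xout = t, rule = 2)$y
  }

  spikes <- vector("list", length(units))
  for (u in seq_along(units)) {
    s <- units[[u]]
    g <- (1 + s$visual_mi) / (1 - s$visual_mi)  # striped/uniform rate ratio
    rate_fun <- function(t) {
      p <- pos_at(t) / L * 100
      r <- s$base_rate_hz
      if (!is.na(s$field_center_pct))
        r <- r + s$field_peak_hz *
          exp(-(p - s$field_center_pct)^2 / (2 * s$field_width_pct^2))
      if (s$speed_gain != 0) r <- r + s$speed_gain * speed_at(t)
      striped <- cond_at(t) == "striped"
      if (s$stripe_mod > 0) {
        ph <- maze_stripe_phase(pmin(pmax(p, 0), 100), cfg$n_cycles) * pi / 180
        r <- r * ifelse(striped,
                        1 + s$stripe_mod * cos(ph - s$stripe_phase_deg * pi / 180),
                        1)
      }
      r * ifelse(striped, g, 1)
    }
    rmax <- (s$base_rate_hz + s$field_peak_hz +
             abs(s$speed_gain) * cfg$run_speed_cm_s) *
      max(g, 1) * (1 + s$stripe_mod) + 1e-9
    n <- stats::rpois(1, rmax * duration)
    cand <- sort(stats::runif(n, 0, duration))
    keep <- stats::runif(n) < rate_fun(cand) / rmax
    spikes[[u]] <- cand[keep]
  }

  structure(list(positions = positions, trials = trials, spikes = spikes,
                 duration_s = duration, config = cfg,
                 ground_truth = units),
            class = "maze_session")
}

#' @export
print.maze_session <- function(x, ...) {
  cat(sprintf("Linear-maze session: %d trials (%d striped), %d units, %.0f s\n",
              nrow(x$trials), sum(x$trials$condition == "striped"),
              length(x$spikes), x$duration_s))
  invisible(x)
}

#' Specification of one simulated passive-stimulation unit
#'
#' Rate multipliers are applied per within-trial epoch; a multiplier below 1
#' models inhibition, above 1 excitation. Scalars are recycled over the 24
#' grating conditions.
#'
#' @param base_rate_hz rate during the uniform-gray epoch (spikes/s).
#' @param mult_still multiplier(s) for the stationary-grating epoch
#'   (length 1 or 24).
#' @param mult_moving multiplier(s) for the moving-grating epoch.
#' @param mult_white multiplier for the white period of blink trials.
#' @return list of class \code{"pvis_unit_spec"}.
#' @export
pvis_unit_spec <- function(base_rate_hz = 5, mult_still = 1, mult_moving = 1,
                           mult_white = 1) {
  if (any(c(mult_still, mult_moving, mult_white) < 0))
    stop("rate multipliers must be nonnegative")
  structure(list(base_rate_hz = base_rate_hz,
                 mult_still = rep_len(mult_still, 24),
                 mult_moving = rep_len(mult_moving, 24),
                 mult_white = mult_white),
            class = "pvis_unit_spec")
}

#' Generate spike trains aligned to a passive stimulus sequence
#'
#' Spikes are drawn from piecewise-constant rates per epoch. Ground truth
#' stores the per-condition modulation indices implied by the multipliers,
#' \code{(m - 1) / (m + 1)}.
#'
#' @param sequence a \code{\link{build_pvis_sequence}} result.
#' @param units list of \code{\link{pvis_unit_spec}}.
#' @param seed integer seed.
#' @return list of class \code{"pvis_session"} with \code{sequence},
#'   \code{spikes} (list of spike-time vectors) and \code{ground_truth}
#'   (per unit: \code{mi_still}, \code{mi_moving}, length-24 vectors).
#' @export
gen_pvis_session <- function(sequence, units, seed = 1L) {
  set.seed(as.integer(seed))
  epoch <- attr(sequence, "epoch_s")
  cond_id <- pvis_condition_id(sequence)
  spikes <- vector("list", length(units))
  gt <- vector("list", length(units))
  for (u in seq_along(units)) {
    s <- units[[u]]
    out <- numeric(0)
    for (i in seq_len(nrow(sequence))) {
      if (sequence$kind[i] == "grating") {
        k <- cond_id[i]
        mults <- c(1, s$mult_still[k], s$mult_moving[k])
      } else {
        mults <- c(1, s$mult_white, 1)   # black - white - black
      }
      for (e in 1:3) {
        r <- s$base_rate_hz * mults[e]
        n <- stats::rpois(1, r * epoch)
        if (n > 0)
          out <- c(out, sequence$onset_s[i] + (e - 1) * epoch +
                     sort(stats::runif(n, 0, epoch)))
      }
    }
    spikes[[u]] <- out
    gt[[u]] <- list(mi_still = (s$mult_still - 1) / (s$mult_still + 1),
                    mi_moving = (s$mult_moving - 1) / (s$mult_moving + 1))
  }
  structure(list(sequence = sequence, spikes = spikes, ground_truth = gt),
            class = "pvis_session")
}

#' Integer condition id (1..24) of each grating trial
#'
#' Conditions enumerate orientation (8) crossed with the rank-matched
#' period/velocity pair (3). Blink trials get NA.
#'
#' @param sequence a stimulus sequence data frame.
#' @return integer vector along trials.
#' @export
pvis_condition_id <- function(sequence) {
  pair <- match(sequence$period_mm, .pvis_periods)
  ori <- match(sequence$orientation_deg, .pvis_orientations)
  ifelse(sequence$kind == "grating", (pair - 1L) * 8L + ori, NA_integer_)
}
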