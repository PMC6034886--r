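#' Active visual (linear maze) analysis
#'
#' Trajectory linearization, automated trial extraction, occupancy-normalized
#' spatial rate maps, responsivity and modulation indices for the
#' uniform-vs-striped maze conditions, a label-shuffle test of spatially
#' resolved modulation with family-wise calibrated boundaries, velocity-MI
#' coupling, stripe-phase tuning, and reward-zone / running-speed controls.
#'
#' @name maze_spatial
NULL

#' Linearize 2-D tracker positions onto the maze axis
#'
#' Positions are orthogonally projected onto the track axis, smoothed with a
#' 10-frame-wide Gaussian kernel and rounded to 1% precision.
#'
#' @param xy two-column matrix/data frame of positions (cm).
#' @param axis_from,axis_to endpoints of the track axis (cm); default derives
#'   the axis from the extreme x positions.
#' @param kernel_frames total width of the Gaussian smoothing kernel (frames);
#'   the kernel SD is \code{kernel_frames / 4} and support is clipped at
#'   \code{kernel_frames / 2} frames each side.
#' @param round_pct precision of the returned percentages.
#' @return numeric vector of positions in percent of track, in [0, 100].
#' @export
linearize_positions <- function(xy, axis_from = NULL, axis_to = NULL,
                                kernel_frames = 10, round_pct = 1) {
  xy <- as.matrix(xy)
  if (is.null(axis_from) || is.null(axis_to)) {
    i0 <- which.min(xy[, 1]); i1 <- which.max(xy[, 1])
    axis_from <- xy[i0, ]; axis_to <- xy[i1, ]
  }
  v <- as.numeric(axis_to) - as.numeric(axis_from)
  len2 <- sum(v^2)
  if (len2 == 0) stop("degenerate track axis")
  centered <- sweep(xy, 2, as.numeric(axis_from))
  proj <- as.numeric(centered %*% v) / len2          # fraction along axis
  pct <- pmin(pmax(proj, 0), 1) * 100
  sdk <- kernel_frames / 4
  r <- ceiling(kernel_frames / 2)
  k <- stats::dnorm(-r:r, sd = sdk)
  k <- k / sum(k)
  n <- length(pct)
  padded <- c(rep(pct[1], r), pct, rep(pct[n], r))
  sm <- as.numeric(stats::filter(padded, k, sides = 2))[(r + 1):(r + n)]
  round(sm / round_pct) * round_pct
}

#' Running speed from linearized positions
#'
#' Central differences of position (converted to cm) at the frame rate.
#'
#' @param pos_pct linearized positions (percent of track).
#' @param frame_rate frames/s.
#' @param track_length_cm track length (cm).
#' @return speed in cm/s, same length as \code{pos_pct}.
#' @export
running_speed <- function(pos_pct, frame_rate = 30, track_length_cm = 230) {
  x <- pos_pct / 100 * track_length_cm
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2 * frame_rate
  v[1] <- (x[2] - x[1]) * frame_rate
  v[n] <- (x[n] - x[n - 1]) * frame_rate
  abs(v)
}

#' Extract successful running trials
#'
#' Detects 50% crossings of the linearized position, tracks each crossing
#' backward and forward in time until the speed drops below the threshold,
#' and keeps runs whose start and stop positions both lie outside the central
#' 10%-90% span (runs that stall mid-track are discarded).
#'
#' @param pos_pct linearized positions (percent).
#' @param t frame times (s).
#' @param frame_rate frames/s.
#' @param track_length_cm track length (cm).
#' @param speed_thresh_cm_s stop-speed threshold (cm/s).
#' @return data frame with \code{start}, \code{end} (s), \code{direction}
#'   ("forward"/"backward"), \code{start_pct}, \code{end_pct}.
#' @export
extract_trials <- function(pos_pct, t, frame_rate = 30,
                           track_length_cm = 230, speed_thresh_cm_s = 5) {
  v <- running_speed(pos_pct, frame_rate, track_length_cm)
  d <- pos_pct - 50
  crossings <- which(d[-1] * d[-length(d)] < 0 | d[-length(d)] == 0)
  n <- length(pos_pct)
  seen <- integer(0)
  out <- list()
  for (ci in crossings) {
    i0 <- ci
    while (i0 > 1 && v[i0 - 1] >= speed_thresh_cm_s) i0 <- i0 - 1
    i1 <- ci + 1
    while (i1 < n && v[i1 + 1] >= speed_thresh_cm_s) i1 <- i1 + 1
    key <- i0
    if (key %in% seen) next
    seen <- c(seen, key)
    p0 <- pos_pct[i0]; p1 <- pos_pct[i1]
    if (p0 > 10 && p0 < 90) next          # stalled start inside the track
    if (p1 > 10 && p1 < 90) next
    if (sign(p1 - p0) == 0) next
    out[[length(out) + 1]] <- data.frame(
      start = t[i0], end = t[i1],
      direction = if (p1 > p0) "forward" else "backward",
      start_pct = p0, end_pct = p1, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      direction = character(0), start_pct = numeric(0),
                      end_pct = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Occupancy-normalized spatial rate map
#'
#' Bins positions inside the analysis span over the selected trials into
#' equal-width half-open bins, accumulates occupancy time and spike counts,
#' and divides. Bins never visited get NA rates and are flagged.
#'
#' @param spikes spike times (s).
#' @param pos_pct linearized positions (percent).
#' @param t frame times (s).
#' @param trials data frame with \code{start}/\code{end} columns; only spikes
#'   and samples inside these windows are used.
#' @param n_bins number of spatial bins.
#' @param span analysis span in percent of track.
#' @return list of class \code{"rate_map"}: \code{bin_edges_pct},
#'   \code{occupancy_s}, \code{count}, \code{rate_hz} (NA where unvisited),
#'   \code{n_spikes}.
#' @export
occupancy_rate_map <- function(spikes, pos_pct, t, trials, n_bins = 20,
                               span = c(10, 90)) {
  stopifnot(nrow(trials) >= 1)
  dt <- stats::median(diff(t))
  edges <- seq(span[1], span[2], length.out = n_bins + 1)
  in_trial <- function(x) {
    idx <- rep(FALSE, length(x))
    for (i in seq_len(nrow(trials)))
      idx <- idx | (x >= trials$start[i] & x <= trials$end[i])
    idx
  }
  keep <- in_trial(t) & pos_pct >= span[1] & pos_pct <= span[2]
  bin_of <- function(p) pmin(n_bins, findInterval(p, edges,
                                                  rightmost.closed = TRUE))
  occ <- tabulate(bin_of(pos_pct[keep]), nbins = n_bins) * dt
  sp_pos <- stats::approx(t, pos_pct, xout = spikes, rule = 2)$y
  skeep <- in_trial(spikes) & sp_pos >= span[1] & sp_pos <= span[2]
  cnt <- tabulate(bin_of(sp_pos[skeep]), nbins = n_bins)
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  structure(list(bin_edges_pct = edges, occupancy_s = occ, count = cnt,
                 rate_hz = rate, n_spikes = sum(skeep)),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("Rate map: %d bins, %d spikes, peak %.2f Hz\n",
              length(x$count), x$n_spikes, max(x$rate_hz, na.rm = TRUE)))
  invisible(x)
}

#' Active visual responsivity and modulation index
#'
#' Paired t test of the bin-wise occupancy-compensated rates between the
#' uniform and striped rate maps; the modulation index compares the
#' whole-trial mean rates, \code{(FR_striped - FR_uniform) /
#' (FR_striped + FR_uniform)}.
#'
#' @param map_uniform,map_striped \code{\link{occupancy_rate_map}} results on
#'   identical bins.
#' @param min_bins minimum jointly valid bin pairs.
#' @return list with \code{p}, \code{mi}, \code{n_bins}.
#' @export
avis_responsivity <- function(map_uniform, map_striped, min_bins = 5) {
  stopifnot(length(map_uniform$rate_hz) == length(map_striped$rate_hz))
  ok <- !is.na(map_uniform$rate_hz) & !is.na(map_striped$rate_hz)
  if (sum(ok) < min_bins)
    return(list(p = NA_real_, mi = NA_real_, n_bins = sum(ok)))
  a <- map_striped$rate_hz[ok]; b <- map_uniform$rate_hz[ok]
  p <- if (stats::sd(a - b) == 0) 1 else
    stats::t.test(a, b, paired = TRUE)$p.value
  fr_s <- sum(map_striped$count) / sum(map_striped$occupancy_s)
  fr_u <- sum(map_uniform$count) / sum(map_uniform$occupancy_s)
  list(p = p, mi = modulation_index(fr_s, fr_u), n_bins = sum(ok))
}

# per-trial occupancy-normalized rate matrix (trials x bins)
.trial_rate_matrix <- function(spikes, pos_pct, t, trials, n_bins = 20,
                               span = c(10, 90)) {
  M <- matrix(NA_real_, nrow(trials), n_bins)
  for (i in seq_len(nrow(trials))) {
    m <- occupancy_rate_map(spikes, pos_pct, t, trials[i, , drop = FALSE],
                            n_bins = n_bins, span = span)
    M[i, ] <- ifelse(m$occupancy_s > 0, m$count / m$occupancy_s, NA_real_)
  }
  M
}

# moving average with shrinking window at the edges, as a bins x bins matrix
.ma_matrix <- function(n_bins, width = 5) {
  k <- (width - 1) %/% 2
  S <- matrix(0, n_bins, n_bins)
  for (i in seq_len(n_bins)) {
    j <- max(1, i - k):min(n_bins, i + k)
    S[j, i] <- 1 / length(j)
  }
  S
}

#' Label-shuffle test of spatially resolved visual modulation
#'
#' The smoothed bin-wise difference of the striped and uniform firing
#' patterns is compared against a surrogate ensemble built by shuffling the
#' uniform/striped trial labels. Local two-sided confidence boundaries are
#' placed at the 2.5% tails of the surrogate values per spatial bin; a global
#' boundary is then calibrated by tightening the local tail fraction until
#' only 5% of the surrogates exceed the boundary at one or more bins, which
#' controls the family-wise error across bins.
#'
#' @param spikes spike times (s).
#' @param pos_pct linearized positions (percent).
#' @param t frame times (s).
#' @param trials data frame with \code{start}, \code{end}, \code{condition}
#'   ("uniform"/"striped").
#' @param n_shuffles surrogate count.
#' @param n_bins spatial bins.
#' @param span analysis span (percent).
#' @param smooth_bins moving-average width applied identically to the real
#'   and every surrogate difference curve.
#' @param local_tail one-sided local tail fraction.
#' @param global_fwer target family-wise breaking fraction.
#' @param min_trials minimum trials per condition.
#' @param seed integer seed for the shuffles.
#' @return list of class \code{"shuffle_result"}: \code{real} (smoothed
#'   difference curve), \code{surrogates} (n_shuffles x bins, smoothed),
#'   \code{local_lo}/\code{local_hi}, \code{global_lo}/\code{global_hi},
#'   \code{significant} (logical per bin), \code{break_fraction} (achieved
#'   surrogate breaking fraction), \code{local_exceedance} (mean one-sided
#'   per-bin exceedance of the local boundaries), \code{global_scale} (the
#'   calibrated widening factor applied to the local boundaries).
#' @export
shuffle_significance <- function(spikes, pos_pct, t, trials,
                                 n_shuffles = 1000, n_bins = 20,
                                 span = c(10, 90), smooth_bins = 5,
                                 local_tail = 0.025, global_fwer = 0.05,
                                 min_trials = 10, seed = 1L) {
  n_u <- sum(trials$condition == "uniform")
  n_s <- sum(trials$condition == "striped")
  if (n_u < min_trials || n_s < min_trials)
    stop("need at least ", min_trials, " trials per condition")
  M <- .trial_rate_matrix(spikes, pos_pct, t, trials, n_bins, span)
  M[is.na(M)] <- 0   # unvisited bins in single trials contribute zero rate
  shuffle_curves(M, trials$condition, n_shuffles = n_shuffles,
                 smooth_bins = smooth_bins, local_tail = local_tail,
                 global_fwer = global_fwer, seed = seed)
}

#' Shuffle calibration on a precomputed trial-by-bin rate matrix
#'
#' Workhorse behind \code{\link{shuffle_significance}}; exposed so calibration
#' studies can run on many simulated sessions without re-binning.
#'
#' @param M trials x bins rate matrix.
#' @param condition character vector of trial labels
#'   ("uniform"/"striped").
#' @inheritParams shuffle_significance
#' @return see \code{\link{shuffle_significance}}.
#' @export
shuffle_curves <- function(M, condition, n_shuffles = 1000, smooth_bins = 5,
                           local_tail = 0.025, global_fwer = 0.05,
                           seed = 1L) {
  set.seed(as.integer(seed))
  n_trials <- nrow(M); n_bins <- ncol(M)
  is_s <- condition == "striped"
  n_s <- sum(is_s); n_u <- n_trials - n_s
  S <- .ma_matrix(n_bins, smooth_bins)
  w_real <- ifelse(is_s, 1 / n_s, -1 / n_u)
  real <- as.numeric(w_real %*% M %*% S)
  # surrogate differences: permuted label weights, identical smoothing
  W <- vapply(seq_len(n_shuffles), function(i) sample(w_real),
              numeric(n_trials))
  D <- t(W) %*% M %*% S                      # n_shuffles x n_bins, smoothed

  sorted <- apply(D, 2, sort)                # ascending per bin
  k_local <- max(1L, round(local_tail * n_shuffles))
  local_b <- list(lo = (sorted[k_local, ] + sorted[k_local + 1, ]) / 2,
                  hi = (sorted[n_shuffles - k_local + 1, ] +
                          sorted[n_shuffles - k_local, ]) / 2)
  local_exc <- mean(c(colMeans(sweep(D, 2, local_b$hi, ">")),
                      colMeans(sweep(D, 2, local_b$lo, "<"))))
  # global calibration: widen the local boundaries continuously outward from
  # the per-bin surrogate median until the family-wise breaking fraction of
  # the surrogate ensemble itself reaches the target; the continuous scale
  # lets surrogates drop out one at a time, so the target is met exactly up
  # to the 1/n_shuffles granularity
  med <- apply(D, 2, stats::median)
  bounds_at <- function(cc) {
    list(lo = med + cc * (local_b$lo - med),
         hi = med + cc * (local_b$hi - med))
  }
  break_frac_at <- function(b) {
    mean(rowSums(sweep(D, 2, b$hi, ">") | sweep(D, 2, b$lo, "<")) > 0)
  }
  c_lo <- 1; c_hi <- 1
  while (break_frac_at(bounds_at(c_hi)) > global_fwer && c_hi < 1024)
    c_hi <- c_hi * 2
  if (c_hi > 1) {
    for (i in 1:50) {      # smallest scale with admissible breaking fraction
      c_mid <- (c_lo + c_hi) / 2
      if (break_frac_at(bounds_at(c_mid)) > global_fwer) c_lo <- c_mid
      else c_hi <- c_mid
    }
  }
  global_b <- bounds_at(c_hi)
  break_frac <- break_frac_at(global_b)
  structure(list(real = real, surrogates = D,
                 local_lo = local_b$lo, local_hi = local_b$hi,
                 global_lo = global_b$lo, global_hi = global_b$hi,
                 significant = real > global_b$hi | real < global_b$lo,
                 break_fraction = break_frac,
                 local_exceedance = local_exc,
                 global_scale = c_hi, n_shuffles = n_shuffles),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf("Label-shuffle test: %d surrogates; %d/%d bins significant; surrogate break fraction %.1f%% (global tail %.3g)\n",
              x$n_shuffles, sum(x$significant), length(x$significant),
              100 * x$break_fraction, x$global_scale))
  invisible(x)
}

#' Velocity dependence of the visual modulation index
#'
#' Instantaneous speeds are averaged within 10-cm spatial bins; each
#' simultaneously recorded responsive unit contributes a bin-wise MI from its
#' condition rate maps, the median across units is taken per bin, non-finite
#' MIs are dropped, and the cleaned median MIs are correlated with the
#' corresponding bin speeds. Sessions with fewer than \code{min_units} units
#' are excluded.
#'
#' @param spikes_list list of spike-time vectors (responsive units only).
#' @param pos_pct linearized positions (percent).
#' @param t frame times (s).
#' @param trials trials data frame with \code{condition}.
#' @param track_length_cm track length (cm).
#' @param frame_rate frames/s.
#' @param bin_cm spatial bin width (cm).
#' @param span analysis span (percent).
#' @param min_units minimum number of responsive units.
#' @return list with \code{speed_cm_s}, \code{median_mi} (per bin),
#'   \code{rho}, \code{p}.
#' @export
velocity_mi_profile <- function(spikes_list, pos_pct, t, trials,
                                track_length_cm = 230, frame_rate = 30,
                                bin_cm = 10, span = c(10, 90),
                                min_units = 3) {
  if (length(spikes_list) < min_units)
    stop("session excluded: fewer than ", min_units, " responsive units")
  n_bins <- max(2, round((span[2] - span[1]) / 100 * track_length_cm / bin_cm))
  tr_u <- trials[trials$condition == "uniform", ]
  tr_s <- trials[trials$condition == "striped", ]
  mi_mat <- vapply(spikes_list, function(sp) {
    mu <- occupancy_rate_map(sp, pos_pct, t, tr_u, n_bins = n_bins, span = span)
    ms <- occupancy_rate_map(sp, pos_pct, t, tr_s, n_bins = n_bins, span = span)
    modulation_index(ms$rate_hz, mu$rate_hz)
  }, numeric(n_bins))
  med_mi <- apply(mi_mat, 1, function(r) stats::median(r[is.finite(r)]))
  v <- running_speed(pos_pct, frame_rate, track_length_cm)
  edges <- seq(span[1], span[2], length.out = n_bins + 1)
  in_tr <- rep(FALSE, length(t))
  for (i in seq_len(nrow(trials)))
    in_tr <- in_tr | (t >= trials$start[i] & t <= trials$end[i])
  keep <- in_tr & pos_pct >= span[1] & pos_pct <= span[2]
  b <- pmin(n_bins, findInterval(pos_pct[keep], edges, rightmost.closed = TRUE))
  speed <- vapply(seq_len(n_bins), function(i) mean(v[keep][b == i]),
                  numeric(1))
  ok <- is.finite(med_mi) & is.finite(speed)
  ct <- stats::cor.test(speed[ok], med_mi[ok])
  list(speed_cm_s = speed, median_mi = med_mi,
       rho = unname(ct$estimate), p = ct$p.value)
}

#' Stripe-phase tuning of a unit
#'
#' Positions are mapped to the phase of the projected luminance grating,
#' activity is averaged across all cycles and trials into an
#' occupancy-normalized circular histogram, uniformity is tested with the
#' Rayleigh test, and the circular modulation index compares the rate at the
#' peak phase with the rate 180 degrees opposite.
#'
#' @param spikes spike times (s).
#' @param pos_pct linearized positions (percent).
#' @param t frame times (s).
#' @param trials trials to analyze (e.g. the striped trials).
#' @param n_cycles grating cycles entering the circular average.
#' @param n_phase_bins phase bins.
#' @param span analysis span (percent).
#' @param min_spikes minimum in-analysis spikes.
#' @return list of class \code{"stripe_phase_tuning"}: \code{phase_deg},
#'   \code{rate_hz}, \code{rayleigh_p}, \code{mi}, \code{peak_phase_deg},
#'   \code{n_spikes}.
#' @export
stripe_phase_tuning <- function(spikes, pos_pct, t, trials, n_cycles = 14,
                                n_phase_bins = 20, span = c(10, 90),
                                min_spikes = 50) {
  dt <- stats::median(diff(t))
  in_win <- function(x) {
    idx <- rep(FALSE, length(x))
    for (i in seq_len(nrow(trials)))
      idx <- idx | (x >= trials$start[i] & x <= trials$end[i])
    idx
  }
  keep <- in_win(t) & pos_pct >= span[1] & pos_pct <= span[2]
  sp_pos <- stats::approx(t, pos_pct, xout = spikes, rule = 2)$y
  skeep <- in_win(spikes) & sp_pos >= span[1] & sp_pos <= span[2]
  if (sum(skeep) < min_spikes)
    return(structure(list(mi = NA_real_, rayleigh_p = NA_real_,
                          n_spikes = sum(skeep)),
                     class = "stripe_phase_tuning"))
  ph_occ <- maze_stripe_phase(pos_pct[keep], n_cycles)
  ph_spk <- maze_stripe_phase(sp_pos[skeep], n_cycles)
  bw <- 360 / n_phase_bins
  bin <- function(p) pmin(n_phase_bins, floor(p / bw) + 1L)
  occ <- tabulate(bin(ph_occ), nbins = n_phase_bins) * dt
  cnt <- tabulate(bin(ph_spk), nbins = n_phase_bins)
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  peak <- which.max(rate)
  opp <- (peak - 1 + n_phase_bins %/% 2) %% n_phase_bins + 1
  structure(list(phase_deg = (seq_len(n_phase_bins) - 0.5) * bw,
                 rate_hz = rate,
                 rayleigh_p = rayleigh_test(ph_spk * pi / 180)$p,
                 mi = modulation_index(rate[peak], rate[opp]),
                 peak_phase_deg = (peak - 0.5) * bw,
                 n_spikes = sum(skeep)),
            class = "stripe_phase_tuning")
}

#' Reward-zone dwell times and condition comparison of dwell firing
#'
#' A dwell is the inter-trial period spent within the reward zones (the outer
#' \code{zone_cm} of the track at each end); its condition is that of the
#' scene projected during the dwell, i.e. of the upcoming trial. Per unit,
#' dwell firing rates are compared between conditions with a two-sample test.
#'
#' @param spikes_list list of spike-time vectors.
#' @param pos_pct linearized positions (percent).
#' @param t frame times (s).
#' @param trials trials data frame with \code{condition}.
#' @param track_length_cm track length (cm).
#' @param zone_cm reward-zone depth at each end (cm).
#' @param test "wilcoxon" or "t".
#' @return list with \code{dwells} (data frame: \code{trial},
#'   \code{condition}, \code{dwell_s}) and \code{units} (data frame:
#'   \code{unit}, \code{fr_uniform}, \code{fr_striped}, \code{p}).
#' @export
reward_zone_stats <- function(spikes_list, pos_pct, t, trials,
                              track_length_cm = 230, zone_cm = 10,
                              test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  zone_pct <- zone_cm / track_length_cm * 100
  in_zone <- pos_pct <= zone_pct | pos_pct >= 100 - zone_pct
  dt <- stats::median(diff(t))
  n_tr <- nrow(trials)
  win_start <- c(min(t), trials$end[-n_tr])
  win_end <- trials$start
  dwell_s <- numeric(n_tr)
  fr <- matrix(0, length(spikes_list), n_tr)
  for (i in seq_len(n_tr)) {
    sel <- t >= win_start[i] & t <= win_end[i] & in_zone
    dwell_s[i] <- sum(sel) * dt
    if (dwell_s[i] > 0) {
      tz <- t[sel]
      for (u in seq_along(spikes_list)) {
        sp <- spikes_list[[u]]
        sp <- sp[sp >= win_start[i] & sp <= win_end[i]]
        if (length(sp)) {
          zp <- stats::approx(t, as.numeric(in_zone), xout = sp, rule = 2,
                              method = "constant")$y
          fr[u, i] <- sum(zp > 0.5) / dwell_s[i]
        }
      }
    }
  }
  if (all(dwell_s == 0)) stop("no reward-zone occupancy")
  is_s <- trials$condition == "striped"
  units <- do.call(rbind, lapply(seq_along(spikes_list), function(u) {
    a <- fr[u, is_s & dwell_s > 0]; b <- fr[u, !is_s & dwell_s > 0]
    p <- if (length(a) < 2 || length(b) < 2 ||
             (stats::sd(c(a, b)) == 0)) NA_real_
    else if (test == "t") stats::t.test(a, b)$p.value
    else stats::wilcox.test(a, b, exact = FALSE)$p.value
    data.frame(unit = u, fr_uniform = mean(b), fr_striped = mean(a), p = p)
  }))
  list(dwells = data.frame(trial = seq_len(n_tr),
                           condition = trials$condition, dwell_s = dwell_s),
       units = units)
}

#' Speed modulation of firing rate
#'
#' Firing rate and mean running speed are computed in fixed time bins and
#' linearly correlated (Pearson).
#'
#' @param spikes spike times (s).
#' @param pos_pct linearized positions (percent).
#' @param t frame times (s).
#' @param frame_rate frames/s.
#' @param track_length_cm track length (cm).
#' @param bin_s time-bin width (s).
#' @return list with \code{rho}, \code{p}, \code{n_bins}.
#' @export
speed_modulation <- function(spikes, pos_pct, t, frame_rate = 30,
                             track_length_cm = 230, bin_s = 1) {
  v <- running_speed(pos_pct, frame_rate, track_length_cm)
  edges <- seq(min(t), max(t), by = bin_s)
  if (length(edges) < 4) stop("session too short for speed binning")
  bins_t <- pmin(length(edges) - 1, findInterval(t, edges))
  speed <- vapply(seq_len(length(edges) - 1),
                  function(i) mean(v[bins_t == i]), numeric(1))
  cnt <- tabulate(pmin(length(edges) - 1,
                       findInterval(spikes[spikes >= min(t) &
                                             spikes <= max(t)], edges)),
                  nbins = length(edges) - 1)
  rate <- cnt / bin_s
  if (stats::sd(speed, na.rm = TRUE) == 0) stop("constant speed")
  ok <- is.finite(speed)
  ct <- stats::cor.test(speed[ok], rate[ok])
  list(rho = unname(ct$estimate), p = ct$p.value, n_bins = sum(ok))
}
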