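#' Passive visual response analysis
#'
#' Epoch firing rates, modulation indices, peristimulus time histograms,
#' per-condition responsivity tests and luminance (blink) responses for units
#' recorded under the passive grating protocol.
#'
#' @name visual_response
NULL

#' Modulation index of two rates
#'
#' \code{(a - b) / (a + b)}, bounded in [-1, 1]; undefined (NA) when both
#' rates are zero.
#'
#' @param a,b nonnegative rates (vectorized).
#' @return modulation index (NA where a + b == 0).
#' @export
modulation_index <- function(a, b) {
  if (any(a < 0 | b < 0, na.rm = TRUE)) stop("rates must be nonnegative")
  ifelse(a + b == 0, NA_real_, (a - b) / (a + b))
}

#' Peristimulus time histogram
#'
#' Counts spikes in half-open bins relative to each trial onset and normalizes
#' to spikes/s per trial.
#'
#' @param spikes spike times (s).
#' @param onsets trial onset times (s).
#' @param bin_ms bin width (ms).
#' @param window_s two-element window relative to onset (s).
#' @return list of class \code{"psth"}: \code{t_ms} (bin left edges, ms),
#'   \code{rate_hz}, \code{count}, \code{n_trials}.
#' @export
compute_psth <- function(spikes, onsets, bin_ms = 20, window_s = c(0, 3)) {
  stopifnot(length(onsets) >= 1, bin_ms > 0, window_s[2] > window_s[1])
  edges <- seq(window_s[1], window_s[2], by = bin_ms / 1000)
  counts <- numeric(length(edges) - 1)
  for (on in onsets) {
    rel <- spikes - on
    rel <- rel[rel >= window_s[1] & rel < edges[length(edges)]]
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges),
                                  nbins = length(counts))
  }
  structure(list(t_ms = edges[-length(edges)] * 1000,
                 rate_hz = counts / length(onsets) / (bin_ms / 1000),
                 count = counts, n_trials = length(onsets)),
            class = "psth")
}

#' Per-trial epoch firing rates of grating trials
#'
#' @param spikes spike times (s).
#' @param sequence a \code{\link{build_pvis_sequence}} result.
#' @return data frame, one row per grating trial: \code{trial},
#'   \code{condition} (1..24), \code{fr_uniform}, \code{fr_still},
#'   \code{fr_moving} (spikes/s).
#' @export
epoch_rates <- function(spikes, sequence) {
  epoch <- attr(sequence, "epoch_s")
  g <- sequence[sequence$kind == "grating", ]
  cond <- pvis_condition_id(sequence)[sequence$kind == "grating"]
  count_in <- function(a, b) {
    vapply(seq_along(a), function(i)
      sum(spikes >= a[i] & spikes < b[i]), numeric(1))
  }
  data.frame(
    trial = g$trial,
    condition = cond,
    fr_uniform = count_in(g$t_uniform, g$t_still) / epoch,
    fr_still = count_in(g$t_still, g$t_moving) / epoch,
    fr_moving = count_in(g$t_moving, g$t_moving + epoch) / epoch)
}

#' Passive visual responsivity
#'
#' Per condition, trial-wise rates during the stationary and the moving epoch
#' are each compared with the uniform-gray epoch by a paired test; a unit is
#' responsive when at least \code{min_significant} conditions are significant
#' in either comparison.
#'
#' @param rates output of \code{\link{epoch_rates}}.
#' @param alpha per-test significance level.
#' @param min_trials minimum trials per condition; conditions with fewer are
#'   skipped and flagged.
#' @param min_significant number of significant conditions required.
#' @param test "t" (paired t test) or "wilcoxon" (signed rank).
#' @return list of class \code{"pvis_responsivity"}: \code{per_condition}
#'   (data frame with \code{condition}, \code{p_still}, \code{p_moving},
#'   \code{mi_still}, \code{mi_moving}, \code{n_trials}, \code{skipped}),
#'   \code{n_significant}, \code{responsive}.
#' @export
pvis_responsivity <- function(rates, alpha = 0.05, min_trials = 10,
                              min_significant = 2, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  conds <- sort(unique(rates$condition))
  paired_p <- function(a, b) {
    if (stats::sd(a - b) == 0) return(1)
    if (test == "t") stats::t.test(a, b, paired = TRUE)$p.value
    else stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }
  rows <- lapply(conds, function(k) {
    r <- rates[rates$condition == k, ]
    if (nrow(r) < min_trials)
      return(data.frame(condition = k, p_still = NA, p_moving = NA,
                        mi_still = NA, mi_moving = NA, n_trials = nrow(r),
                        skipped = TRUE))
    data.frame(condition = k,
               p_still = paired_p(r$fr_still, r$fr_uniform),
               p_moving = paired_p(r$fr_moving, r$fr_uniform),
               mi_still = modulation_index(mean(r$fr_still), mean(r$fr_uniform)),
               mi_moving = modulation_index(mean(r$fr_moving), mean(r$fr_uniform)),
               n_trials = nrow(r), skipped = FALSE)
  })
  per <- do.call(rbind, rows)
  nsig <- sum(pmin(per$p_still, per$p_moving) < alpha, na.rm = TRUE)
  structure(list(per_condition = per, n_significant = nsig,
                 responsive = nsig >= min_significant, alpha = alpha),
            class = "pvis_responsivity")
}

#' @export
print.pvis_responsivity <- function(x, ...) {
  cat(sprintf("Passive visual responsivity: %d/%d conditions significant at alpha = %g -> %s\n",
              x$n_significant, nrow(x$per_condition), x$alpha,
              if (x$responsive) "responsive" else "not responsive"))
  invisible(x)
}

#' Mean response vector of a unit
#'
#' Component-wise mean of the per-condition stationary and moving modulation
#' indices over conditions where they are defined.
#'
#' @param mi_still,mi_moving per-condition modulation indices.
#' @return list with \code{x} (mean stationary MI) and \code{y} (mean moving
#'   MI); both NA when no condition is defined.
#' @export
response_vector <- function(mi_still, mi_moving) {
  if (all(is.na(mi_still)) && all(is.na(mi_moving)))
    return(list(x = NA_real_, y = NA_real_))
  list(x = mean(mi_still, na.rm = TRUE), y = mean(mi_moving, na.rm = TRUE))
}

#' Luminance response from blink trials
#'
#' Trial-by-trial paired comparison of the firing rate in the white period of
#' the full-screen blink trials against the surrounding black periods.
#'
#' @param spikes spike times (s).
#' @param sequence stimulus sequence; only blink trials are used.
#' @param alpha significance level.
#' @param min_trials minimum number of blink trials.
#' @return list with \code{direction} ("excited", "inhibited" or "none"),
#'   \code{p}, \code{fr_white}, \code{fr_black}, \code{n_trials}.
#' @export
luminance_response <- function(spikes, sequence, alpha = 0.05,
                               min_trials = 10) {
  epoch <- attr(sequence, "epoch_s")
  b <- sequence[sequence$kind == "blink", ]
  if (nrow(b) < min_trials) {
    warning("too few blink trials; luminance response undefined")
    return(list(direction = "none", p = NA_real_, fr_white = NA_real_,
                fr_black = NA_real_, n_trials = nrow(b)))
  }
  nsp <- function(a, d) vapply(a, function(on)
    sum(spikes >= on & spikes < on + d), numeric(1))
  white <- nsp(b$t_still, epoch) / epoch
  black <- (nsp(b$t_uniform, epoch) + nsp(b$t_moving, epoch)) / (2 * epoch)
  p <- if (stats::sd(white - black) == 0) 1 else
    stats::t.test(white, black, paired = TRUE)$p.value
  dir <- if (p >= alpha) "none" else
    if (mean(white - black) > 0) "excited" else "inhibited"
  list(direction = dir, p = p, fr_white = mean(white),
       fr_black = mean(black), n_trials = nrow(b))
}
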