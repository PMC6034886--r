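#' Synthetic spike trains and waveforms for the three striatal classes
#'
#' Archetypes describe the target statistics of a generated unit: mean firing
#' rate, proportion of interspike intervals exceeding 2 s (ISI2s), post-spike
#' suppression, and waveform shape (width and trough-to-peak time). Trains are
#' drawn from a renewal process whose ISIs are a suppression floor plus either
#' a truncated-exponential short interval or, with probability
#' \code{isi2s_fraction}, an explicit >2 s interval, so every target feature
#' is realized exactly in expectation.
#'
#' @name synthetic_units
NULL

#' A unit archetype
#'
#' @param label one of \code{"PFN"}, \code{"FFN"}, \code{"TFN"}.
#' @param target_rate_hz mean firing rate, spikes/s (> 0).
#' @param isi2s_fraction proportion of ISIs exceeding 2 s, in [0, 1].
#' @param suppression_ms post-spike suppression window, ms (>= 0).
#' @param waveform_width_ms spike full width at half trough amplitude, ms.
#' @param trough_to_peak_ms trough-to-peak time, ms.
#' @return list of class \code{"unit_archetype"}.
#' @export
unit_archetype <- function(label = c("PFN", "FFN", "TFN"),
                           target_rate_hz = NULL, isi2s_fraction = NULL,
                           suppression_ms = NULL, waveform_width_ms = NULL,
                           trough_to_peak_ms = NULL) {
  label <- match.arg(label)
  # class-typical defaults: MSN-like phasic, PV-like fast, ChAT-like tonic
  def <- switch(label,
    PFN = list(rate = 1.2, isi2s = 0.10, supp = 20, width = 0.45, t2p = 0.65),
    FFN = list(rate = 15,  isi2s = 0,    supp = 4,  width = 0.20, t2p = 0.25),
    TFN = list(rate = 3,   isi2s = 0,    supp = 200, width = 0.60, t2p = 0.90))
  a <- list(label = label,
            target_rate_hz = target_rate_hz %||% def$rate,
            isi2s_fraction = isi2s_fraction %||% def$isi2s,
            suppression_ms = suppression_ms %||% def$supp,
            waveform_width_ms = waveform_width_ms %||% def$width,
            trough_to_peak_ms = trough_to_peak_ms %||% def$t2p)
  stopifnot(a$target_rate_hz > 0,
            a$isi2s_fraction >= 0, a$isi2s_fraction <= 1,
            a$suppression_ms >= 0)
  class(a) <- "unit_archetype"
  a
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# mean of Exp(rate) truncated to [0, upper]
.trunc_exp_mean <- function(rate, upper) {
  p <- 1 - exp(-rate * upper)
  1 / rate - upper * exp(-rate * upper) / p
}

.rtrunc_exp <- function(n, rate, upper) {
  u <- stats::runif(n, 0, 1 - exp(-rate * upper))
  -log(1 - u) / rate
}

#' Generate a spike train realizing a unit archetype
#'
#' @param archetype a \code{\link{unit_archetype}}.
#' @param duration_s recording duration in seconds (> 0).
#' @param seed integer seed.
#' @return list of class \code{"spike_train"}: \code{spikes} (sorted times, s),
#'   \code{waveform} (mean waveform over [-1, +1] ms), \code{sample_rate_hz},
#'   \code{duration_s}, \code{archetype}.
#' @export
gen_unit <- function(archetype, duration_s, seed = 1L) {
  if (duration_s <= 0) stop("duration must be positive")
  set.seed(as.integer(seed))
  a <- archetype
  supp <- a$suppression_ms / 1000
  q <- a$isi2s_fraction
  target_mean_isi <- 1 / a$target_rate_hz
  # ISI = supp + mix( truncated Exp (<= 2 - supp), q : 2 - supp + Exp(1) )
  long_excess_mean <- 1           # mean length beyond 2 s of a long ISI
  upper <- 2 - supp
  if (upper <= 0) stop("suppression window must be below 2 s")
  short_mean_target <- (target_mean_isi - supp -
                        q * (upper + long_excess_mean)) / (1 - q)
  if (short_mean_target <= 0)
    stop("archetype infeasible: rate too high for the requested ISI2s/suppression")
  f <- function(rate) .trunc_exp_mean(rate, upper) - short_mean_target
  rate_short <- stats::uniroot(f, c(1e-6, 1e5))$root
  draw_isi <- function(n) {
    is_long <- stats::runif(n) < q
    supp + ifelse(is_long,
                  upper + stats::rexp(n, 1 / long_excess_mean),
                  .rtrunc_exp(n, rate_short, upper))
  }
  isi <- draw_isi(ceiling(duration_s * a$target_rate_hz * 1.5) + 50)
  while (sum(isi) < duration_s) isi <- c(isi, draw_isi(100))
  spikes <- cumsum(isi)
  spikes <- spikes[spikes <= duration_s]
  wf <- synth_waveform(a$waveform_width_ms, a$trough_to_peak_ms)
  structure(list(spikes = spikes, waveform = wf$v,
                 sample_rate_hz = wf$sample_rate_hz,
                 duration_s = duration_s, archetype = a),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %g s (%.2f Hz)%s\n",
              length(x$spikes), x$duration_s,
              length(x$spikes) / x$duration_s,
              if (!is.null(x$archetype)) paste0(", archetype ",
                                                x$archetype$label) else ""))
  invisible(x)
}

#' Synthesize a mean spike waveform
#'
#' Negative Gaussian trough at 0 ms (FWHM = \code{width_ms}) plus a smaller
#' positive after-peak at \code{t2p_ms}, sampled over [-1, +1] ms.
#'
#' @param width_ms full width at half trough amplitude, ms.
#' @param t2p_ms trough-to-peak time, ms.
#' @param sample_rate_hz waveform sample rate.
#' @param peak_frac after-peak amplitude as a fraction of trough amplitude.
#' @return list with \code{v} (voltages), \code{t_ms}, \code{sample_rate_hz}.
#' @export
synth_waveform <- function(width_ms, t2p_ms, sample_rate_hz = 32000,
                           peak_frac = 0.35) {
  t <- seq(-1, 1, by = 1000 / sample_rate_hz)
  sd_tr <- width_ms / (2 * sqrt(2 * log(2)))
  sd_pk <- max(t2p_ms / 4, 0.8 * sd_tr)
  v <- -exp(-t^2 / (2 * sd_tr^2)) +
    peak_frac * exp(-(t - t2p_ms)^2 / (2 * sd_pk^2))
  list(v = v, t_ms = t, sample_rate_hz = sample_rate_hz)
}
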