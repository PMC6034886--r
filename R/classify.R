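#' Striatal unit classification
#'
#' Striatal single units are sorted into three putative classes from five
#' features: spike width (full width at half trough amplitude),
#' trough-to-peak time, mean firing rate, the proportion of interspike
#' intervals exceeding 2 s (ISI2s), and the post-spike suppression time (PSST,
#' the lag at which the smoothed autocorrelogram recovers to the mean rate).
#' Units with more than 2% ISI2s are phasically firing neurons (PFN, putative
#' medium spiny neurons); narrow-spiked, fast-firing, short-PSST units are
#' fast-firing neurons (FFN, putative parvalbumin interneurons); low-rate,
#' long-PSST units are tonically firing neurons (TFN, putative cholinergic
#' interneurons). Everything else is left unclassified.
#'
#' @name unit_classification
NULL

#' Default classification thresholds
#'
#' Only the 2% ISI2s cut is a published convention; the width, rate and PSST
#' cuts are the package's defaults for the qualitative "narrow/high/low"
#' rules and can be overridden.
#'
#' @param isi2s_cut proportion of >2 s ISIs above which a unit is a PFN.
#' @param narrow_width_ms spike width below which a spike counts as narrow.
#' @param high_rate_hz firing rate above which a unit counts as fast-firing.
#' @param psst_cut_ms post-spike suppression time separating low from high.
#' @return a named list of thresholds.
#' @export
class_thresholds <- function(isi2s_cut = 0.02, narrow_width_ms = 0.35,
                             high_rate_hz = 5, psst_cut_ms = 100) {
  stopifnot(isi2s_cut > 0, narrow_width_ms > 0, high_rate_hz > 0,
            psst_cut_ms > 0)
  list(isi2s_cut = isi2s_cut, narrow_width_ms = narrow_width_ms,
       high_rate_hz = high_rate_hz, psst_cut_ms = psst_cut_ms)
}

#' Waveform features: spike width and trough-to-peak time
#'
#' The mean waveform (sampled over [-1, +1] ms around threshold crossing) is
#' linearly detrended first. Width is the full width of the trough at half its
#' (detrended) amplitude, with linear interpolation between samples;
#' trough-to-peak is the time from the global minimum to the subsequent
#' maximum.
#'
#' @param waveform numeric vector of voltages.
#' @param sample_rate_hz sampling rate of the waveform.
#' @return list with \code{spike_width_ms}, \code{trough_to_peak_ms}, and
#'   \code{ok} (FALSE when the waveform has no interior trough and features
#'   are undefined).
#' @export
extract_waveform_features <- function(waveform, sample_rate_hz = 32000) {
  n <- length(waveform)
  stopifnot(n >= 5, sample_rate_hz > 0)
  t_ms <- (seq_len(n) - 1) / sample_rate_hz * 1000
  w <- stats::residuals(stats::lm(waveform ~ t_ms))
  # amplitude is measured against the baseline at the waveform edges
  n_edge <- max(2L, round(0.1 * n))
  w <- w - mean(w[c(seq_len(n_edge), (n - n_edge + 1):n)])
  i_min <- which.min(w)
  if (i_min == 1L || i_min == n || w[i_min] >= 0)
    return(list(spike_width_ms = NA_real_, trough_to_peak_ms = NA_real_,
                ok = FALSE))
  half <- w[i_min] / 2
  # walk outwards from the trough to the half-amplitude crossings
  il <- i_min
  while (il > 1L && w[il] < half) il <- il - 1L
  ir <- i_min
  while (ir < n && w[ir] < half) ir <- ir + 1L
  interp_t <- function(i0, i1) {       # crossing between samples i0 < i1
    if (w[i1] == w[i0]) return(t_ms[i0])
    t_ms[i0] + (half - w[i0]) / (w[i1] - w[i0]) * (t_ms[i1] - t_ms[i0])
  }
  tl <- if (w[il] >= half) interp_t(il, il + 1L) else t_ms[il]
  tr <- if (w[ir] >= half) interp_t(ir - 1L, ir) else t_ms[ir]
  after <- w[i_min:n]
  i_peak <- i_min - 1L + which.max(after)
  list(spike_width_ms = tr - tl,
       trough_to_peak_ms = t_ms[i_peak] - t_ms[i_min],
       ok = TRUE)
}

#' Spike-train autocorrelogram
#'
#' Counts of spike pairs per positive lag bin, normalized to a rate
#' (coincidences per reference spike per second).
#'
#' @param spikes sorted spike times, seconds.
#' @param bin_ms bin width in ms.
#' @param max_lag_ms largest lag in ms.
#' @return list with \code{lag_ms} (bin centers) and \code{rate_hz}.
#' @export
spike_autocorrelogram <- function(spikes, bin_ms = 10, max_lag_ms = 1000) {
  stopifnot(length(spikes) >= 2, bin_ms > 0, max_lag_ms > bin_ms)
  max_lag <- max_lag_ms / 1000
  edges <- seq(0, max_lag, by = bin_ms / 1000)
  counts <- numeric(length(edges) - 1)
  n <- length(spikes)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && spikes[j] - spikes[i] < max_lag) j <- j + 1L
    if (j > i + 1L) {
      d <- spikes[(i + 1L):(j - 1L)] - spikes[i]
      idx <- pmin(length(counts), floor(d / (bin_ms / 1000)) + 1L)
      tab <- tabulate(idx, nbins = length(counts))
      counts <- counts + tab
    }
  }
  rate <- counts / n / (bin_ms / 1000)
  list(lag_ms = (edges[-1] + edges[-length(edges)]) / 2 * 1000, rate_hz = rate)
}

#' Train features: firing rate, ISI2s, and post-spike suppression time
#'
#' PSST is measured as the first lag at which the autocorrelogram (10 ms bins,
#' 50 ms boxcar smoothing) reaches the train's mean rate.
#'
#' @param spikes sorted spike times, seconds.
#' @param duration_s recording duration, seconds.
#' @param acg_bin_ms autocorrelogram bin width (ms).
#' @param acg_smooth_bins boxcar width in bins for ACG smoothing.
#' @param acg_max_lag_ms largest ACG lag considered (ms).
#' @return list with \code{firing_rate_hz}, \code{isi2s}, \code{psst_ms}, and
#'   \code{ok} (FALSE when fewer than 2 spikes).
#' @export
extract_train_features <- function(spikes, duration_s, acg_bin_ms = 10,
                                   acg_smooth_bins = 5,
                                   acg_max_lag_ms = 1000) {
  stopifnot(duration_s > 0)
  if (length(spikes) < 2)
    return(list(firing_rate_hz = NA_real_, isi2s = NA_real_,
                psst_ms = NA_real_, ok = FALSE))
  isi <- diff(spikes)
  fr <- length(spikes) / duration_s
  acg <- spike_autocorrelogram(spikes, bin_ms = acg_bin_ms,
                               max_lag_ms = acg_max_lag_ms)
  k <- rep(1 / acg_smooth_bins, acg_smooth_bins)
  sm <- stats::filter(acg$rate_hz, k, sides = 2)
  sm[is.na(sm)] <- acg$rate_hz[is.na(sm)]
  hit <- which(sm >= fr)
  psst <- if (length(hit)) acg$lag_ms[hit[1]] - acg_bin_ms / 2 else acg_max_lag_ms
  list(firing_rate_hz = fr, isi2s = mean(isi > 2), psst_ms = psst, ok = TRUE)
}

#' Classify a unit from its features
#'
#' Rule order: ISI2s above the cut gives PFN; otherwise narrow + fast + short
#' PSST gives FFN; otherwise slow + long PSST gives TFN; otherwise
#' unclassified. Units with undefined features are always unclassified.
#'
#' @param features list with \code{spike_width_ms}, \code{trough_to_peak_ms},
#'   \code{firing_rate_hz}, \code{isi2s}, \code{psst_ms} (as returned by the
#'   extractors, possibly concatenated).
#' @param thresholds output of \code{\link{class_thresholds}}.
#' @return one of \code{"PFN"}, \code{"FFN"}, \code{"TFN"},
#'   \code{"unclassified"}.
#' @export
classify_unit <- function(features, thresholds = class_thresholds()) {
  need <- c("spike_width_ms", "firing_rate_hz", "isi2s", "psst_ms")
  v <- unlist(features[need])
  if (any(is.na(v))) return("unclassified")
  th <- thresholds
  if (features$isi2s > th$isi2s_cut) return("PFN")
  if (features$spike_width_ms < th$narrow_width_ms &&
      features$firing_rate_hz > th$high_rate_hz &&
      features$psst_ms < th$psst_cut_ms) return("FFN")
  if (features$firing_rate_hz <= th$high_rate_hz &&
      features$psst_ms >= th$psst_cut_ms) return("TFN")
  "unclassified"
}

#' Extract all five features and classify a generated or recorded unit
#'
#' Convenience wrapper combining \code{\link{extract_waveform_features}},
#' \code{\link{extract_train_features}} and \code{\link{classify_unit}}.
#'
#' @param spikes sorted spike times (s).
#' @param waveform mean waveform voltages.
#' @param duration_s recording duration (s).
#' @param sample_rate_hz waveform sample rate.
#' @param thresholds classification thresholds.
#' @return list of the five features plus \code{label}.
#' @export
classify_spike_train <- function(spikes, waveform, duration_s,
                                 sample_rate_hz = 32000,
                                 thresholds = class_thresholds()) {
  wf <- extract_waveform_features(waveform, sample_rate_hz)
  tf <- extract_train_features(spikes, duration_s)
  feats <- c(wf[c("spike_width_ms", "trough_to_peak_ms")],
             tf[c("firing_rate_hz", "isi2s", "psst_ms")])
  feats$label <- if (!wf$ok || !tf$ok) "unclassified" else
    classify_unit(feats, thresholds)
  feats
}
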