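#' LFP oscillation analysis
#'
#' Band-limited filtering, spike-LFP phase coupling, whitened spectra,
#' pairwise Granger causality, and a lag-by-frequency cross-correlation map
#' with zero-lag suppression that exposes lagged, intermittent band-limited
#' synchrony hidden from ordinary coherence estimates.
#'
#' @name lfp_oscillations
NULL

#' The five analysis frequency bands
#'
#' @return data frame with columns \code{name}, \code{low_hz}, \code{high_hz}.
#' @export
lfp_bands <- function() {
  data.frame(name = c("delta", "theta", "beta", "low_gamma", "mid_gamma"),
             low_hz = c(1, 4, 12, 30, 45),
             high_hz = c(4, 12, 30, 45, 80),
             stringsAsFactors = FALSE)
}

.band_edges <- function(band) {
  b <- lfp_bands()
  i <- match(band, b$name)
  if (is.na(i)) stop("unknown band name: ", band)
  c(b$low_hz[i], b$high_hz[i])
}

#' Zero-phase Butterworth band-pass filter
#'
#' Eighth-order (8-pole) Butterworth band-pass applied with zero phase lag.
#' \code{method = "filtfilt"} runs \code{signal::butter} forward-backward;
#' \code{method = "fft"} (the default) applies the identical squared
#' magnitude response in the frequency domain, which is the exact
#' steady-state equivalent of forward-backward filtering and remains
#' numerically stable for narrow or very low passbands, where the recursive
#' filter diverges (e.g. the delta band at 1,250 samples/s).
#'
#' @param x numeric signal.
#' @param band band name (see \code{\link{lfp_bands}}), or NULL when
#'   \code{low_hz}/\code{high_hz} are given.
#' @param fs sample rate (Hz).
#' @param low_hz,high_hz custom band edges (Hz).
#' @param order filter order per pass direction (4 gives an 8-pole band-pass).
#' @param method "filtfilt" or "fft".
#' @return filtered signal, same length as \code{x}.
#' @export
bandpass <- function(x, band = NULL, fs = 1250, low_hz = NULL, high_hz = NULL,
                     order = 4, method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  if (!is.null(band)) {
    e <- .band_edges(band)
    low_hz <- e[1]; high_hz <- e[2]
  }
  stopifnot(low_hz > 0, high_hz > low_hz)
  if (high_hz >= fs / 2) stop("band edge at or above Nyquist frequency")
  if (method == "filtfilt") {
    bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  } else {
    n <- length(x)
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
    f <- abs(f)
    w0sq <- low_hz * high_hz
    bw <- high_hz - low_hz
    u <- ifelse(f == 0, Inf, (f^2 - w0sq) / (f * bw))
    hsq <- 1 / (1 + u^(2 * order))   # |H|^2 of the 2*order-pole band-pass
    Re(stats::fft(stats::fft(x) * hsq, inverse = TRUE)) / n
  }
}

#' Analytic signal via the Hilbert transform
#'
#' @param x numeric signal.
#' @return complex analytic signal, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited component
#'
#' @param x raw signal.
#' @param band band name.
#' @param fs sample rate.
#' @param method filtering method passed to \code{\link{bandpass}}.
#' @return phase in radians, (-pi, pi].
#' @export
instantaneous_phase <- function(x, band, fs = 1250, method = "fft") {
  Arg(analytic_signal(bandpass(x, band = band, fs = fs, method = method)))
}

#' Rayleigh test of circular uniformity
#'
#' @param phases_rad phases in radians.
#' @return list with \code{n}, \code{rbar}, \code{z} and \code{p}
#'   (Wilkie approximation).
#' @export
rayleigh_test <- function(phases_rad) {
  n <- length(phases_rad)
  stopifnot(n >= 2)
  rbar <- Mod(mean(exp(1i * phases_rad)))
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(n = n, rbar = rbar, z = z, p = max(min(p, 1), 0))
}

#' Spike-LFP phase coupling
#'
#' Spike phases are read from the analytic signal of the band-filtered LFP,
#' binned at 18 degrees, smoothed with a 5-bin circular moving average; the
#' peak and trough of the smoothed distribution give the preferred and
#' unpreferred phases, and the modulation index is
#' (FR_max - FR_min) / (FR_max + FR_min) of the smoothed occurrence
#' frequencies.
#'
#' @param spikes spike times (s).
#' @param lfp LFP trace.
#' @param band band name.
#' @param fs LFP sample rate.
#' @param min_spikes minimum spike count for a defined result.
#' @param bin_deg histogram bin width (degrees).
#' @param smooth_bins circular moving-average width in bins.
#' @return list of class \code{"phase_coupling"}: \code{phase_deg} (bin
#'   centers), \code{count}, \code{smoothed}, \code{preferred_deg},
#'   \code{unpreferred_deg}, \code{mi}, \code{rayleigh_p}, \code{n}.
#' @export
spike_phase_coupling <- function(spikes, lfp, band, fs = 1250,
                                 min_spikes = 50, bin_deg = 18,
                                 smooth_bins = 5) {
  idx <- round(spikes * fs) + 1
  idx <- idx[idx >= 1 & idx <= length(lfp)]
  if (length(idx) < min_spikes)
    return(structure(list(mi = NA_real_, rayleigh_p = NA_real_,
                          n = length(idx)), class = "phase_coupling"))
  ph <- instantaneous_phase(lfp, band, fs)[idx]
  deg <- (ph * 180 / pi) %% 360
  nb <- round(360 / bin_deg)
  bin <- pmin(nb, floor(deg / bin_deg) + 1L)
  count <- tabulate(bin, nbins = nb)
  sm <- circular_moving_average(count, smooth_bins)
  centers <- (seq_len(nb) - 0.5) * bin_deg
  ray <- rayleigh_test(ph)
  structure(list(phase_deg = centers, count = count, smoothed = sm,
                 preferred_deg = centers[which.max(sm)],
                 unpreferred_deg = centers[which.min(sm)],
                 mi = (max(sm) - min(sm)) / (max(sm) + min(sm)),
                 rayleigh_p = ray$p, n = length(idx)),
            class = "phase_coupling")
}

#' Circular moving average
#'
#' @param x numeric vector treated as circular.
#' @param width odd window width.
#' @return smoothed vector, same length.
#' @export
circular_moving_average <- function(x, width = 5) {
  stopifnot(width %% 2 == 1, width <= length(x))
  n <- length(x)
  k <- (width - 1) / 2
  xx <- c(x[(n - k + 1):n], x, x[1:k])
  as.numeric(stats::filter(xx, rep(1 / width, width), sides = 2))[(k + 1):(k + n)]
}

#' Median reference across simultaneously recorded LFP channels
#'
#' @param lfp_matrix samples x channels matrix.
#' @return per-sample median trace.
#' @export
lfp_median_reference <- function(lfp_matrix) {
  apply(as.matrix(lfp_matrix), 1, stats::median)
}

#' Whitened power spectrum
#'
#' Tapered, smoothed periodogram whitened by multiplying power with frequency
#' and expressed in decibels.
#'
#' @param x signal.
#' @param fs sample rate (Hz).
#' @param spans smoothing spans passed to \code{stats::spec.pgram}.
#' @param taper split-cosine taper proportion.
#' @return data frame with \code{freq_hz} and \code{db}.
#' @export
whitened_spectrum <- function(x, fs = 1250, spans = c(7, 7), taper = 0.1) {
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = spans,
                          taper = taper, detrend = TRUE, plot = FALSE)
  data.frame(freq_hz = sp$freq, db = 10 * log10(sp$spec * sp$freq))
}

#' Pairwise Granger causality over a range of lag orders
#'
#' For each candidate lag order (2-40 ms expressed in samples), fits the
#' restricted (own past only) and full (own plus other signal's past)
#' autoregressions by least squares and reports the F statistic of the
#' restriction together with its critical value. The lag with the highest F
#' is the displayed lag.
#'
#' @param x,y equal-length signals; causality is assessed x to y and y to x.
#' @param fs sample rate (Hz).
#' @param lag_range_ms candidate lag range in ms.
#' @param alpha significance level for the critical values.
#' @return list of class \code{"granger_result"} with elements
#'   \code{x_to_y} and \code{y_to_x}, each a list holding the per-order table
#'   (\code{order}, \code{lag_ms}, \code{F}, \code{crit}), \code{best_lag_ms},
#'   \code{best_F}, \code{best_crit}.
#' @export
granger_pair <- function(x, y, fs, lag_range_ms = c(2, 40), alpha = 0.05) {
  stopifnot(length(x) == length(y))
  p_lo <- max(1L, ceiling(lag_range_ms[1] / 1000 * fs))
  p_hi <- floor(lag_range_ms[2] / 1000 * fs)
  if (p_hi < p_lo) stop("lag range contains no whole sample lag")
  one_dir <- function(from, to) {
    tab <- lapply(p_lo:p_hi, function(p) {
      n <- length(to)
      Yl <- stats::embed(to, p + 1)      # col 1: y_t, cols 2..p+1: lags
      Xl <- stats::embed(from, p + 1)[, -1, drop = FALSE]
      yv <- Yl[, 1]
      Zr <- cbind(1, Yl[, -1, drop = FALSE])
      Zf <- cbind(Zr, Xl)
      rss <- function(Z) {
        fit <- stats::lm.fit(Z, yv)
        sum(fit$residuals^2)
      }
      rss_r <- rss(Zr); rss_f <- rss(Zf)
      df2 <- length(yv) - ncol(Zf)
      if (df2 < 1 || rss_f <= 0) return(NULL)
      Fv <- ((rss_r - rss_f) / p) / (rss_f / df2)
      data.frame(order = p, lag_ms = p / fs * 1000, F = Fv,
                 crit = stats::qf(1 - alpha, p, df2))
    })
    tab <- do.call(rbind, tab)
    i <- which.max(tab$F)
    list(table = tab, best_lag_ms = tab$lag_ms[i], best_F = tab$F[i],
         best_crit = tab$crit[i])
  }
  structure(list(x_to_y = one_dir(x, y), y_to_x = one_dir(y, x),
                 alpha = alpha),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("Granger causality: x->y F = %.2f (crit %.2f) at %.1f ms; y->x F = %.2f (crit %.2f) at %.1f ms\n",
              x$x_to_y$best_F, x$x_to_y$best_crit, x$x_to_y$best_lag_ms,
              x$y_to_x$best_F, x$y_to_x$best_crit, x$y_to_x$best_lag_ms))
  invisible(x)
}

.resample_linear <- function(x, fs_from, fs_to) {
  n <- length(x)
  t_new <- seq(0, (n - 1) / fs_from, by = 1 / fs_to)
  stats::approx(seq(0, (n - 1) / fs_from, by = 1 / fs_from), x,
                xout = t_new)$y
}

#' Lag-by-frequency cross-correlation map with zero-lag suppression
#'
#' Both signals are iteratively band-pass filtered at 1 Hz steps (2 Hz wide
#' zero-phase 8-pole Butterworth passbands, applied in the frequency domain),
#' cross-correlated over +/-100 ms lags in 2 ms steps, and each
#' cross-correlogram is converted to a magnitude by the absolute value of its
#' analytic signal along the lag axis. The analytic correlogram is computed
#' exactly as half the cross-correlation of the two filtered channels'
#' analytic signals, which avoids the wraparound leakage a Hilbert transform
#' of the short correlogram itself would introduce. Correlograms are
#' normalized per band by the filtered signals' standard deviations, so the
#' magnitude is a correlation coefficient. The additive distortion of
#' synchronous
#' (zero-lag-symmetric) components is removed by subtracting the minimum of
#' each symmetric lag pair from both members, which cancels any lag-symmetric
#' component exactly and zeroes lag 0.
#'
#' @param x,y equal-length signals.
#' @param fs sample rate (Hz). When \code{fs * lag_step_ms / 1000} is not an
#'   integer the signals are linearly resampled to 500 Hz.
#' @param freqs_hz integer center frequencies of the iterative filters.
#' @param max_lag_ms half-width of the lag window (ms).
#' @param lag_step_ms lag step (ms).
#' @param bw_hz passband width of each iterative filter (Hz); edge bands are
#'   clipped at 0.5 Hz.
#' @return list of class \code{"xcorr_map"}: \code{freq_hz}, \code{lag_ms},
#'   \code{raw} and \code{suppressed} (frequency x lag magnitude matrices),
#'   \code{correlogram} (the signed normalized correlograms), \code{fs}.
#' @export
tf_lagged_xcorr <- function(x, y, fs, freqs_hz = 1:100, max_lag_ms = 100,
                            lag_step_ms = 2, bw_hz = 2) {
  stopifnot(length(x) == length(y))
  step_samp <- fs * lag_step_ms / 1000
  if (abs(step_samp - round(step_samp)) > 1e-9) {
    x <- .resample_linear(x, fs, 500)
    y <- .resample_linear(y, fs, 500)
    fs <- 500
    step_samp <- fs * lag_step_ms / 1000
  }
  step_samp <- as.integer(round(step_samp))
  max_lag_samp <- as.integer(round(fs * max_lag_ms / 1000))
  n <- length(x)
  if (n <= 4 * max_lag_samp) stop("signals shorter than the lag window")
  if (max(freqs_hz) + bw_hz / 2 >= fs / 2)
    stop("highest filter band reaches the Nyquist frequency")
  x <- x - mean(x); y <- y - mean(y)
  sd_x <- stats::sd(x); sd_y <- stats::sd(y)
  fx <- stats::fft(x); fy <- stats::fft(y)
  f_axis <- abs(c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n)
  lags <- seq(-max_lag_samp, max_lag_samp, by = step_samp)
  lag_ms <- lags / fs * 1000
  # the Hilbert envelope along the lag axis is obtained exactly, without
  # short-sequence transform artifacts, from the identity
  #   analytic(xcorr(x, y)) = xcorr(analytic(x), analytic(y)) / 2
  # which holds for any pair of real signals
  half <- c(1, rep(2, ceiling(n / 2) - 1), rep(1, 1 - n %% 2),
            rep(0, floor(n / 2) - (1 - n %% 2)))
  raw <- matrix(0, nrow = length(freqs_hz), ncol = length(lags))
  signed <- matrix(0, nrow = length(freqs_hz), ncol = length(lags))
  for (k in seq_along(freqs_hz)) {
    f0 <- freqs_hz[k]
    lo <- max(f0 - bw_hz / 2, 0.5)
    hi <- f0 + bw_hz / 2
    w0sq <- lo * hi; bw <- hi - lo
    u <- ifelse(f_axis == 0, Inf, (f_axis^2 - w0sq) / (f_axis * bw))
    hsq <- 1 / (1 + u^8)
    fxb <- fx * hsq; fyb <- fy * hsq
    xf <- Re(stats::fft(fxb, inverse = TRUE)) / n
    yf <- Re(stats::fft(fyb, inverse = TRUE)) / n
    denom <- stats::sd(xf) * stats::sd(yf) * n
    # a band carrying no appreciable signal has an undefined correlation
    # coefficient; report it as zero rather than dividing by ~0
    if (denom < (1e-7 * sd_x) * (1e-7 * sd_y) * n) next
    zx <- stats::fft(fxb * half, inverse = TRUE) / n
    zy <- stats::fft(fyb * half, inverse = TRUE) / n
    # circular complex cross-correlation from the cross-spectrum, then
    # subtract the wrapped end products so the result equals plain linear
    # lag sums
    rc <- stats::fft(Conj(fxb * half) * (fyb * half), inverse = TRUE) / n
    cc <- vapply(lags, function(tau) {
      if (tau >= 0) {
        v <- rc[tau + 1]
        if (tau > 0) v <- v - sum(Conj(zx[(n - tau + 1):n]) * zy[seq_len(tau)])
      } else {
        v <- rc[n + tau + 1] - sum(Conj(zx[seq_len(-tau)]) * zy[(n + tau + 1):n])
      }
      v / 2 / denom
    }, complex(1))
    raw[k, ] <- Mod(cc)
    signed[k, ] <- Re(cc)
  }
  supp <- raw - pmin(raw, raw[, rev(seq_len(ncol(raw))), drop = FALSE])
  structure(list(freq_hz = freqs_hz, lag_ms = lag_ms, raw = raw,
                 suppressed = supp, correlogram = signed, fs = fs),
            class = "xcorr_map")
}

#' @export
print.xcorr_map <- function(x, ...) {
  i <- which(x$suppressed == max(x$suppressed), arr.ind = TRUE)[1, ]
  cat(sprintf("Lag x frequency cross-correlation map: %d freqs x %d lags; suppressed max %.3g at %g Hz, %+g ms\n",
              length(x$freq_hz), length(x$lag_ms), max(x$suppressed),
              x$freq_hz[i[1]], x$lag_ms[i[2]]))
  invisible(x)
}

#' Maximal suppressed coherence in a frequency/lag window
#'
#' @param map an \code{\link{tf_lagged_xcorr}} result.
#' @param freq_range_hz two-element frequency window (Hz).
#' @param lag_range_ms two-element lag window (ms).
#' @return the maximum suppressed magnitude inside the window.
#' @export
extract_coherence_index <- function(map, freq_range_hz, lag_range_ms) {
  fi <- which(map$freq_hz >= freq_range_hz[1] & map$freq_hz <= freq_range_hz[2])
  li <- which(map$lag_ms >= lag_range_ms[1] & map$lag_ms <= lag_range_ms[2])
  if (!length(fi) || !length(li)) stop("empty frequency/lag window")
  max(map$suppressed[fi, li, drop = FALSE])
}

#' Count connected suprathreshold domains of a suppressed map
#'
#' Thresholds the suppressed magnitude matrix at \code{mean + z_thresh * SD}
#' and counts 8-connected components.
#'
#' @param map an \code{\link{tf_lagged_xcorr}} result (or a bare matrix).
#' @param z_thresh threshold in SD units above the map mean.
#' @param min_size smallest component size (cells) counted as a domain. The
#'   iterative filters smear any genuine band-limited lagged interaction over
#'   several frequency rows and lag bins, so single-cell specks of
#'   near-threshold noise are not meaningful domains.
#' @return list with \code{n_domains}, \code{labels} (labeled matrix) and
#'   \code{threshold}.
#' @export
count_xcorr_domains <- function(map, z_thresh = 3, min_size = 10) {
  m <- if (inherits(map, "xcorr_map")) map$suppressed else map
  thr <- mean(m) + z_thresh * stats::sd(m)
  lab <- label_components(m > thr)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  lab2 <- array(match(lab, keep, nomatch = 0L), dim = dim(lab))
  list(n_domains = length(keep), labels = lab2, threshold = thr)
}

#' Label 8-connected components of a logical matrix
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1L) %% nr + 1L
      cc <- (i - 1L) %/% nr + 1L
      rr <- r + offs$dr; ccn <- cc + offs$dc
      ok <- rr >= 1 & rr <= nr & ccn >= 1 & ccn <= nc
      nb <- (ccn[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}
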