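#' Synthetic LFP traces with controllable spike phase locking
#'
#' An LFP trace is built as a sum of band-limited oscillations plus 1/f
#' background noise. Units can be phase-locked to a band component by
#' von-Mises-weighted thinning of their spikes: a spike at band phase theta is
#' kept with probability exp(kappa * (cos(theta - theta0) - 1)), which leaves
#' the surviving spikes with a von Mises phase distribution of concentration
#' kappa. The requested locking strength is the target phase modulation index
#' of the downstream 18-degree, 5-bin-smoothed phase histogram; the
#' strength-to-kappa mapping is computed once by deterministic numerical
#' integration of the von Mises density through that exact pipeline.
#'
#' @name synthetic_lfp
NULL

# phase MI of a von Mises density after 18-degree binning and 5-bin circular
# moving-average smoothing (deterministic)
.vm_phase_mi <- function(kappa, bin_deg = 18, smooth_bins = 5) {
  nb <- round(360 / bin_deg)
  edges <- seq(0, 2 * pi, length.out = nb + 1)
  dens <- function(th) exp(kappa * cos(th)) / (2 * pi * besselI(kappa, 0))
  p <- vapply(seq_len(nb), function(b)
    stats::integrate(dens, edges[b], edges[b + 1])$value, numeric(1))
  sm <- circular_moving_average(p, smooth_bins)
  (max(sm) - min(sm)) / (max(sm) + min(sm))
}

#' Von Mises concentration realizing a target phase modulation index
#'
#' @param target_mi desired phase MI in [0, 1).
#' @return concentration parameter kappa.
#' @export
phase_locking_kappa <- function(target_mi) {
  stopifnot(target_mi >= 0, target_mi < 1)
  if (target_mi == 0) return(0)
  stats::uniroot(function(k) .vm_phase_mi(k) - target_mi,
                 c(1e-4, 50), tol = 1e-6)$root
}

#' Generate an LFP trace, optionally phase-locking spike trains to it
#'
#' @param duration_s trace duration (s).
#' @param fs sample rate (samples/s).
#' @param band_components list of components, each
#'   \code{list(band = name, amplitude = a, freq_hz = f)}; \code{freq_hz}
#'   defaults to the band's geometric center frequency.
#' @param locked_units list of \code{list(spikes = times, band = name,
#'   preferred_phase_deg = p, strength = s)}; \code{strength} in [0, 1) is the
#'   target phase MI.
#' @param noise_amp amplitude scale of the 1/f background noise (0 disables).
#' @param seed integer seed.
#' @return list of class \code{"lfp_record"}: \code{signal}, \code{fs},
#'   \code{duration_s}, \code{components} (with realized phases),
#'   \code{locked_spikes} (list of thinned spike-time vectors).
#' @export
gen_lfp <- function(duration_s, fs = 1250, band_components = list(),
                    locked_units = list(), noise_amp = 0.2, seed = 1L) {
  stopifnot(duration_s > 0)
  set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  comps <- list()
  for (c in band_components) {
    e <- .band_edges(c$band)   # validates the name
    f0 <- c$freq_hz %||% sqrt(e[1] * e[2])
    if (f0 < e[1] || f0 > e[2]) stop("component frequency outside its band")
    ph0 <- stats::runif(1, 0, 2 * pi)
    sig <- sig + c$amplitude * cos(2 * pi * f0 * t + ph0)
    comps[[length(comps) + 1]] <- list(band = c$band, freq_hz = f0,
                                       amplitude = c$amplitude, phase0 = ph0)
  }
  if (noise_amp > 0) sig <- sig + noise_amp * .one_over_f_noise(n, fs)

  locked <- vector("list", length(locked_units))
  for (u in seq_along(locked_units)) {
    lu <- locked_units[[u]]
    stopifnot(lu$strength >= 0, lu$strength < 1)
    comp <- Filter(function(cc) cc$band == lu$band, comps)
    if (!length(comp)) stop("no band component to lock to: ", lu$band)
    comp <- comp[[1]]
    if (lu$strength == 0) { locked[[u]] <- lu$spikes; next }
    kappa <- phase_locking_kappa(lu$strength)
    th <- (2 * pi * comp$freq_hz * lu$spikes + comp$phase0) %% (2 * pi)
    th0 <- lu$preferred_phase_deg * pi / 180
    keep <- stats::runif(length(th)) < exp(kappa * (cos(th - th0) - 1))
    locked[[u]] <- lu$spikes[keep]
  }
  structure(list(signal = sig, fs = fs, duration_s = duration_s,
                 components = comps, locked_spikes = locked),
            class = "lfp_record")
}

# 1/f amplitude-shaped Gaussian noise via FFT
.one_over_f_noise <- function(n, fs) {
  white <- stats::rnorm(n)
  W <- stats::fft(white)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  shape <- ifelse(f == 0, 0, 1 / sqrt(abs(f)))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' @export
print.lfp_record <- function(x, ...) {
  cat(sprintf("LFP record: %g s at %g Hz, %d band component(s), %d locked unit(s)\n",
              x$duration_s, x$fs, length(x$components),
              length(x$locked_spikes)))
  invisible(x)
}

#' Artificial two-channel demonstration pair for the suppressed lag map
#'
#' Builds the demonstration construction for the zero-lag-suppressed
#' lag-by-frequency cross-correlation: a continuous narrowband theta
#' oscillation present on both channels with a phase-equivalent time delay,
#' two discrete gamma-burst trains
#' (low- and mid-gamma) copied onto the second channel at distinct time
#' delays, and a coincident square wave on both channels mimicking a shared
#' recording artifact (a 50 Hz mains-like square by default). The suppressed
#' map should show one domain per delayed component and no trace of the
#' zero-lag artifact.
#'
#' The artifact frequency should be kept spectrally separated from the
#' delayed components: because the correlogram magnitude is a nonlinear
#' function of the band signal, a synchronous tone sharing a band with leaked
#' delayed content leaves an interference residue after suppression that can
#' rival the genuine domains.
#'
#' @param duration_s duration (s).
#' @param fs sample rate (Hz).
#' @param theta_freq_hz theta frequency.
#' @param theta_phase_shift_deg phase delay of channel 2's theta.
#' @param gamma1 \code{c(freq_hz, delay_ms)} of the low-gamma bursts.
#' @param gamma2 \code{c(freq_hz, delay_ms)} of the mid-gamma bursts.
#' @param artifact_amp amplitude of the coincident square wave (0 disables).
#' @param artifact_freq_hz square-wave frequency.
#' @param burst_len_s duration of each gamma burst.
#' @param n_bursts bursts per gamma train.
#' @param noise_sd white-noise SD added independently per channel.
#' @param max_lag_ms analysis lag window half-width; delays beyond it are
#'   rejected.
#' @param seed integer seed.
#' @return list of class \code{"lfp_pair"}: \code{x}, \code{y}, \code{fs},
#'   and \code{truth} (expected lag of each delayed component, ms).
#' @export
gen_lfp_pair_s8 <- function(duration_s = 1200, fs = 500, theta_freq_hz = 5,
                            theta_phase_shift_deg = 45,
                            gamma1 = c(40, 30), gamma2 = c(70, 50),
                            artifact_amp = 0.3, artifact_freq_hz = 50,
                            burst_len_s = 0.5, n_bursts = 480,
                            noise_sd = 0.2, max_lag_ms = 100, seed = 1L) {
  delays <- c(gamma1[2], gamma2[2])
  if (any(delays <= 0 | delays > 100)) stop("delays must lie within (0, 100] ms")
  if (any(delays > max_lag_ms))
    stop("delay exceeds the analysis lag window")
  set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  # theta as amplitude-fluctuating narrowband noise: a constant-amplitude
  # tone has a flat correlogram envelope that the zero-lag suppression
  # cancels, so the envelope fluctuations must be delayed along with the
  # carrier for the theta domain to survive
  theta_lag_s <- theta_phase_shift_deg / 360 / theta_freq_hz
  theta_lag_samp <- round(theta_lag_s * fs)
  w <- stats::fft(stats::rnorm(n))
  f_ax <- abs(c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n)
  band <- f_ax >= theta_freq_hz - 2 & f_ax <= theta_freq_hz + 2
  theta1 <- Re(stats::fft(w * band, inverse = TRUE)) / n
  theta1 <- theta1 / stats::sd(theta1)
  theta2 <- c(numeric(theta_lag_samp), theta1[seq_len(n - theta_lag_samp)])

  burst_train <- function(freq, n_bursts) {
    x <- numeric(n)
    len <- round(burst_len_s * fs)
    starts <- sort(sample.int(n - len - round(0.2 * fs), n_bursts))
    env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / len))   # Hann envelope
    for (s0 in starts) {
      idx <- s0:(s0 + len - 1)
      x[idx] <- x[idx] + env * cos(2 * pi * freq * t[idx])
    }
    x
  }
  delay_sig <- function(x, delay_ms) {
    d <- round(delay_ms / 1000 * fs)
    c(numeric(d), x[seq_len(n - d)])
  }
  g1 <- burst_train(gamma1[1], n_bursts)
  g2 <- burst_train(gamma2[1], n_bursts)
  # half-period bookkeeping in integer arithmetic: sign(sin(...)) or
  # floating-point floor() would turn the samples landing on the zero
  # crossings into pseudo-random +/-1 flips through rounding error,
  # injecting broadband common noise
  half_idx <- ((seq_len(n) - 1) * 2 * artifact_freq_hz) %/% fs
  square <- artifact_amp * (1 - 2 * (half_idx %% 2))

  ch1 <- theta1 + g1 + g2 + square + stats::rnorm(n, 0, noise_sd)
  ch2 <- theta2 + delay_sig(g1, gamma1[2]) + delay_sig(g2, gamma2[2]) +
    square + stats::rnorm(n, 0, noise_sd)

  theta_lag_ms <- theta_lag_samp / fs * 1000
  structure(list(x = ch1, y = ch2, fs = fs,
                 truth = list(theta_lag_ms = theta_lag_ms,
                              gamma1_lag_ms = gamma1[2],
                              gamma2_lag_ms = gamma2[2],
                              gamma1_freq_hz = gamma1[1],
                              gamma2_freq_hz = gamma2[1])),
            class = "lfp_pair")
}
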