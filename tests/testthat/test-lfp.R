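test_that("band table matches the published partition", {
  b <- lfp_bands()
  expect_equal(b$name, c("delta", "theta", "beta", "low_gamma", "mid_gamma"))
  expect_equal(b$low_hz, c(1, 4, 12, 30, 45))
  expect_equal(b$high_hz, c(4, 12, 30, 45, 80))
})

test_that("bandpass keeps in-band tones and rejects out-of-band tones", {
  fs <- 1250
  t <- seq(0, 8, by = 1 / fs)
  x <- sin(2 * pi * 8 * t) + sin(2 * pi * 60 * t)
  y <- bandpass(x, "theta", fs)
  mid <- seq(fs, length(t) - fs)         # ignore edges
  ref <- sin(2 * pi * 8 * t)
  expect_lt(max(abs(y[mid] - ref[mid])), 0.05)
  # the two methods agree where the recursive filter is stable
  y2 <- bandpass(x, "theta", fs, method = "filtfilt")
  expect_gt(cor(y[mid], y2[mid]), 0.999)
  # the frequency-domain method stays finite even for the delta band
  expect_true(all(is.finite(bandpass(x, "delta", fs))))
  expect_error(bandpass(x, fs = 100, low_hz = 10, high_hz = 60), "Nyquist")
})

test_that("analytic signal gives unit envelope and linear phase for a tone", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  x <- cos(2 * pi * 10 * t)
  z <- analytic_signal(x)
  mid <- seq(fs, length(t) - fs)
  expect_lt(max(abs(Mod(z[mid]) - 1)), 0.01)
  dphi <- diff(unwrap_phase <- Arg(z[mid]))
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - 2 * pi * 10 / fs)), 0.01)
})

test_that("circular moving average wraps and preserves the mean", {
  x <- c(10, rep(0, 9))
  s <- circular_moving_average(x, 5)
  expect_equal(mean(s), mean(x))
  expect_equal(s[9], 2)                  # window reaching across the seam
  expect_equal(s[1], 2)
  expect_equal(s[5], 0)
  expect_error(circular_moving_average(x, 4), "width")
})

test_that("Rayleigh test separates uniform from concentrated phases", {
  set.seed(3)
  expect_gt(rayleigh_test(runif(300, 0, 2 * pi))$p, 0.05)
  expect_lt(rayleigh_test(rnorm(300, 1, 0.5))$p, 1e-10)
})

test_that("phase coupling recovers strength and preferred phase in all bands", {
  freqs <- c(delta = 2.5, theta = 8, beta = 20, low_gamma = 38, mid_gamma = 60)
  a <- unit_archetype("FFN", target_rate_hz = 25)
  u <- gen_unit(a, 300, seed = 4)
  for (band in names(freqs)) {
    rec <- gen_lfp(300, band_components = list(
                     list(band = band, amplitude = 1,
                          freq_hz = unname(freqs[band]))),
                   locked_units = list(list(spikes = u$spikes, band = band,
                                            preferred_phase_deg = 100,
                                            strength = 0.3)),
                   noise_amp = 0.1, seed = 8)
    pc <- spike_phase_coupling(rec$locked_spikes[[1]], rec$signal, band)
    expect_lt(abs(pc$mi - 0.3), 0.08)
    # preferred phase is the argmax of an 18-degree-binned histogram, so
    # allow the true phase's bin plus one bin of estimation error
    dphi <- abs(((pc$preferred_deg - 100 + 180) %% 360) - 180)
    expect_lt(dphi, 28)
    expect_lt(pc$rayleigh_p, 1e-4)
  }
})

test_that("unlocked spikes show no phase coupling", {
  a <- unit_archetype("FFN", target_rate_hz = 25)
  u <- gen_unit(a, 120, seed = 6)
  rec <- gen_lfp(120, band_components = list(
                   list(band = "theta", amplitude = 1, freq_hz = 8)),
                 noise_amp = 0.1, seed = 2)
  pc <- spike_phase_coupling(u$spikes, rec$signal, "theta")
  expect_gt(pc$rayleigh_p, 0.05)
  expect_lt(pc$mi, 0.1)
  pc0 <- spike_phase_coupling(u$spikes[1:10], rec$signal, "theta")
  expect_true(is.na(pc0$mi))             # below the spike-count floor
})

test_that("median reference is the per-sample channel median", {
  set.seed(1)
  m <- matrix(rnorm(50 * 5), 50, 5)
  expect_equal(lfp_median_reference(m), apply(m, 1, median))
})

test_that("whitened spectrum peaks at the oscillation frequency", {
  rec <- gen_lfp(30, band_components = list(
                   list(band = "theta", amplitude = 1, freq_hz = 8)),
                 noise_amp = 0.3, seed = 5)
  sp <- whitened_spectrum(rec$signal, fs = rec$fs)
  pk <- sp$freq_hz[which.max(sp$db)]
  expect_lt(abs(pk - 8), 0.5)
  expect_error(whitened_spectrum(rnorm(100), fs = 1250), "at least")
})

test_that("Granger causality points from driver to follower", {
  set.seed(12)
  fs <- 500
  n <- fs * 30
  x <- as.numeric(arima.sim(list(ar = 0.8), n))
  d <- round(0.016 * fs)                 # 16 ms coupling delay
  y <- 0.8 * c(rep(0, d), x[seq_len(n - d)]) + rnorm(n, 0, 0.5)
  g <- granger_pair(x, y, fs = fs)
  expect_gt(g$x_to_y$best_F, g$x_to_y$best_crit)
  expect_equal(g$x_to_y$best_lag_ms, 16)
  expect_lt(g$y_to_x$best_F, 2 * g$y_to_x$best_crit)
  expect_gt(g$x_to_y$best_F, 50 * g$y_to_x$best_F)
})

test_that("per-order F matches lmtest::grangertest exactly", {
  skip_if_not_installed("lmtest")
  set.seed(21)
  n <- 3000
  x <- as.numeric(arima.sim(list(ar = 0.5), n))
  y <- 0.4 * c(0, 0, x[seq_len(n - 2)]) + rnorm(n)
  g <- granger_pair(x, y, fs = 1000, lag_range_ms = c(2, 10))
  for (p in c(2, 5, 10)) {
    ref <- lmtest::grangertest(y ~ x, order = p)
    expect_equal(g$x_to_y$table$F[g$x_to_y$table$order == p],
                 ref$F[2], tolerance = 1e-8)
  }
})

test_that("Granger null false-positive rate is close to alpha", {
  fp <- vapply(1:100, function(s) {
    set.seed(s + 900)
    x <- as.numeric(arima.sim(list(ar = 0.6), 1500))
    y <- as.numeric(arima.sim(list(ar = 0.6), 1500))
    g <- granger_pair(x, y, fs = 1000, lag_range_ms = c(5, 5))
    g$x_to_y$best_F > g$x_to_y$best_crit
  }, logical(1))
  tol <- 3 * sqrt(0.05 * 0.95 / 100)
  expect_lt(abs(mean(fp) - 0.05), tol + 0.01)
})

test_that("signed correlograms match brute-force lagged Pearson products", {
  set.seed(30)
  fs <- 500
  n <- fs * 10
  x <- rnorm(n); y <- rnorm(n)
  map <- tf_lagged_xcorr(x, y, fs = fs, freqs_hz = c(10, 45))
  for (k in 1:2) {
    f0 <- c(10, 45)[k]
    # the map's DC gain is zero, so centering the inputs is immaterial
    xf <- bandpass(x, fs = fs, low_hz = f0 - 1, high_hz = f0 + 1)
    yf <- bandpass(y, fs = fs, low_hz = f0 - 1, high_hz = f0 + 1)
    denom <- sd(xf) * sd(yf) * n
    for (li in c(1, 26, 51, 76, 101)) {
      tau <- round(map$lag_ms[li] / 1000 * fs)
      if (tau >= 0)
        ref <- sum(xf[seq_len(n - tau)] * yf[seq_len(n - tau) + tau]) / denom
      else
        ref <- sum(xf[seq_len(n + tau) - tau] * yf[seq_len(n + tau)]) / denom
      # the map stores Re of the analytic cross-correlation; that equals the
      # plain lagged product up to a record-boundary term of order 1/n
      # (Hilbert-transform unitarity is global, not local), so the agreement
      # is approximate here and exact in the analytic-envelope test below
      expect_lt(abs(map$correlogram[k, li] - ref), 1e-3)
    }
  }
})

test_that("magnitudes are the analytic envelope of the correlogram", {
  set.seed(31)
  fs <- 500
  n <- fs * 10
  x <- rnorm(n); y <- rnorm(n)
  map <- tf_lagged_xcorr(x, y, fs = fs, freqs_hz = 45)
  f0 <- 45
  xf <- bandpass(x - mean(x), fs = fs, low_hz = f0 - 1, high_hz = f0 + 1)
  yf <- bandpass(y - mean(y), fs = fs, low_hz = f0 - 1, high_hz = f0 + 1)
  ax <- analytic_signal(xf); ay <- analytic_signal(yf)
  denom <- sd(xf) * sd(yf) * n
  for (li in c(11, 51, 91)) {
    tau <- round(map$lag_ms[li] / 1000 * fs)
    idx <- if (tau >= 0) seq_len(n - tau) else seq_len(n + tau) - tau
    ref <- Mod(sum(Conj(ax[idx]) * ay[idx + tau]) / 2) / denom
    expect_equal(map$raw[1, li], ref, tolerance = 1e-9)
  }
})

test_that("suppression cancels symmetric components exactly", {
  set.seed(32)
  fs <- 500
  x <- rnorm(fs * 8)
  map_same <- tf_lagged_xcorr(x, x, fs = fs, freqs_hz = c(5, 20, 60))
  expect_lt(max(map_same$suppressed), 1e-12)
  y <- rnorm(fs * 8)
  map <- tf_lagged_xcorr(x, y, fs = fs, freqs_hz = c(5, 20, 60))
  i0 <- which(map$lag_ms == 0)
  expect_true(all(map$suppressed[, i0] == 0))
  expect_true(all(map$suppressed >= 0))
  expect_true(all(map$suppressed <= map$raw + 1e-15))
})

test_that("a delayed narrowband component appears at its frequency with positive lag", {
  set.seed(33)
  fs <- 500
  n <- fs * 600         # long record: noise-band envelope fluctuations
  w <- fft(rnorm(n))    # scale as 1/sqrt(duration) and must stay below
  fax <- abs(c(seq(0, floor(n / 2)),     # the genuine suppressed signal
               seq(-ceiling(n / 2) + 1, -1)) * fs / n)
  x <- Re(fft(w * (fax >= 43 & fax <= 47), inverse = TRUE)) / n
  x <- x / sd(x)
  d <- round(0.030 * fs)
  y <- c(numeric(d), x[seq_len(n - d)]) + rnorm(n, 0, 0.2)
  x <- x + rnorm(n, 0, 0.2)
  map <- tf_lagged_xcorr(x, y, fs = fs)
  dom <- count_xcorr_domains(map)
  # with a single weak component the mean + 3 SD threshold sits low, so
  # near-threshold noise specks of about min_size cells can survive; assert
  # on the dominant domain, which carries the genuine delayed component
  expect_gte(dom$n_domains, 1)
  sizes <- tabulate(dom$labels[dom$labels > 0], nbins = dom$n_domains)
  main <- which.max(sizes)
  cells <- which(dom$labels == main, arr.ind = TRUE)
  expect_true(all(abs(map$freq_hz[cells[, 1]] - 45) <= 4))
  expect_true(all(map$lag_ms[cells[, 2]] > 0))
  # the map's global maximum lies inside that domain
  pk <- which(map$suppressed == max(map$suppressed), arr.ind = TRUE)
  expect_equal(unname(dom$labels[pk]), main)
  # and it dwarfs everything else
  if (dom$n_domains > 1)
    expect_gt(sizes[main], 3 * max(sizes[-main]))
})

test_that("silent bands yield zero correlograms, not noise", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs            # integer number of tone periods,
  x <- sin(2 * pi * 30 * t)              # so off-band spectral leakage is nil
  map <- tf_lagged_xcorr(x, x, fs = fs, freqs_hz = c(5, 30, 80))
  expect_true(all(map$raw[c(1, 3), ] == 0))
  expect_gt(max(map$raw[2, ]), 0.9)
})

test_that("domain counting thresholds at mean + 3 SD with 8-connectivity", {
  m <- matrix(0, 40, 40)
  m[5:9, 5:12] <- 1                       # 40 cells
  m[20:24, 20:27] <- 1                    # separate block
  m[25, 28] <- 1; m[26, 29:33] <- m[26, 29:33] + 1  # diagonal bridge
  m[35:38, 35:38] <- 1                    # 16 cells
  res <- count_xcorr_domains(m, z_thresh = 3, min_size = 10)
  expect_equal(res$n_domains, 3)          # the bridge merges block 2
  expect_equal(res$threshold, mean(m) + 3 * sd(m))
  # min_size filters specks
  m2 <- m; m2[1, 40] <- 1
  expect_equal(count_xcorr_domains(m2, min_size = 10)$n_domains, 3)
  expect_equal(count_xcorr_domains(m2, min_size = 1)$n_domains, 4)
})

test_that("label_components honors diagonal adjacency", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[4, 4] <- TRUE
  lab <- label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_false(lab[4, 4] == lab[1, 1])
  expect_equal(max(lab), 2)
})

test_that("artificial pair map shows exactly three domains at the true components", {
  fx <- s8_fixture()
  res <- count_xcorr_domains(fx$map)
  expect_equal(res$n_domains, 3)
  tr <- fx$pair$truth
  # each ground-truth component owns one domain at a positive lag
  for (f0 in c(5, tr$gamma1_freq_hz, tr$gamma2_freq_hz)) {
    fi <- which(abs(fx$map$freq_hz - f0) <= 3)
    sub <- res$labels[fi, , drop = FALSE]
    hit <- unique(sub[sub > 0])
    expect_equal(length(hit), 1)
    li <- which(res$labels == hit[1], arr.ind = TRUE)[, 2]
    expect_true(all(fx$map$lag_ms[li] > 0))
  }
})

test_that("the coincident square wave correlates at zero lag but is suppressed", {
  fx <- s8_fixture()
  i0 <- which(fx$map$lag_ms == 0)
  i50 <- which(fx$map$freq_hz == 50)
  expect_gt(fx$map$raw[i50, i0], 0.5)     # strong synchronous artifact
  expect_equal(fx$map$suppressed[i50, i0], 0)
  # without the artifact the raw zero-lag ridge at 50 Hz disappears
  pr0 <- gen_lfp_pair_s8(duration_s = 240, artifact_amp = 0, seed = 2)
  pr1 <- gen_lfp_pair_s8(duration_s = 240, seed = 2)
  m0 <- tf_lagged_xcorr(pr0$x, pr0$y, fs = pr0$fs, freqs_hz = 50)
  m1 <- tf_lagged_xcorr(pr1$x, pr1$y, fs = pr1$fs, freqs_hz = 50)
  j0 <- which(m0$lag_ms == 0)
  expect_lt(m0$raw[1, j0], 0.1)
  expect_gt(m1$raw[1, j0], 0.5)
})

test_that("delays outside the analysis window are rejected", {
  expect_error(gen_lfp_pair_s8(gamma2 = c(70, 150)), "delays")
  expect_error(gen_lfp_pair_s8(gamma1 = c(40, 90), max_lag_ms = 50), "window")
})

test_that("coherence-index extraction windows the suppressed map", {
  fx <- s8_fixture()
  tr <- fx$pair$truth
  on_target <- extract_coherence_index(fx$map, tr$gamma1_freq_hz + c(-3, 3),
                                       c(0, 100))
  off_target <- extract_coherence_index(fx$map, tr$gamma1_freq_hz + c(-3, 3),
                                        c(-100, -60))
  expect_gt(on_target, count_xcorr_domains(fx$map)$threshold)
  expect_gt(on_target, 3 * off_target)
  expect_error(extract_coherence_index(fx$map, c(300, 400), c(0, 10)), "empty")
})
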