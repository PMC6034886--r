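# Shared fixtures, computed once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# artificial two-channel pair and its suppressed lag x frequency map
s8_fixture <- function() {
  cached_fixture("s8", {
    pair <- gen_lfp_pair_s8(seed = 1)
    list(pair = pair, map = tf_lagged_xcorr(pair$x, pair$y, fs = pair$fs))
  })
}

# null maze session (condition-independent firing) and its 1,000-surrogate
# label-shuffle calibration
null_shuffle_fixture <- function() {
  cached_fixture("null_shuffle", {
    cfg <- session_config(n_trials = 40, seed = 101)
    ses <- gen_maze_session(cfg, list(maze_unit_spec(base_rate_hz = 3)))
    pos <- linearize_positions(ses$positions[, c("x_cm", "y_cm")])
    res <- shuffle_significance(ses$spikes[[1]], pos, ses$positions$t,
                                ses$trials, n_shuffles = 1000, seed = 11)
    list(session = ses, pos = pos, result = res)
  })
}

# standard maze session with one place/visual unit, shared across files
maze_fixture <- function() {
  cached_fixture("maze", {
    cfg <- session_config(n_trials = 80, seed = 7)
    units <- list(
      maze_unit_spec(base_rate_hz = 5, visual_mi = 0.3),
      maze_unit_spec(base_rate_hz = 0.5, field_center_pct = 40,
                     field_width_pct = 8, field_peak_hz = 8),
      maze_unit_spec(base_rate_hz = 5)
    )
    ses <- gen_maze_session(cfg, units)
    pos <- linearize_positions(ses$positions[, c("x_cm", "y_cm")])
    list(session = ses, pos = pos, t = ses$positions$t)
  })
}
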