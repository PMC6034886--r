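#' Place-field analysis
#'
#' Smoothed spatial rate maps (Gaussian kernel applied to the raw spike and
#' occupancy maps before division), Skaggs-style spatial information,
#' selectivity, sparsity, first-order spatial coherence, place-field
#' detection, and cross-condition field stability. Directions and conditions
#' are analyzed independently.
#'
#' @name place_fields
NULL

# discrete Gaussian kernel over bins, SD in bins, support +/- 4 SD
.gauss_kernel <- function(sd_bins) {
  r <- max(1, ceiling(4 * sd_bins))
  k <- stats::dnorm(-r:r, sd = sd_bins)
  k / sum(k)
}

# reflective-boundary convolution keeping total mass
.smooth_vec <- function(x, kernel) {
  r <- (length(kernel) - 1) / 2
  n <- length(x)
  padded <- c(rev(x[1:r]), x, rev(x[(n - r + 1):n]))
  as.numeric(stats::filter(padded, kernel, sides = 2))[(r + 1):(r + n)]
}

#' Smoothed occupancy-normalized rate map
#'
#' A Gaussian kernel (default SD 5 cm) is applied to the raw spike-count map
#' and to the raw occupancy map, and the smoothed rate map is the ratio of
#' the two smoothed maps.
#'
#' @param map an \code{\link{occupancy_rate_map}} result (raw counts and
#'   occupancy are used).
#' @param kernel_sd_cm Gaussian SD in cm.
#' @param track_length_cm track length (cm), used to convert the SD to bins.
#' @return the input map with added fields \code{smoothed_rate_hz},
#'   \code{smoothed_count}, \code{smoothed_occupancy_s},
#'   \code{bin_width_cm}.
#' @export
smoothed_rate_map <- function(map, kernel_sd_cm = 5, track_length_cm = 230) {
  if (all(map$occupancy_s == 0)) stop("occupancy is zero everywhere")
  edges <- map$bin_edges_pct
  bin_cm <- diff(edges[1:2]) / 100 * track_length_cm
  k <- .gauss_kernel(kernel_sd_cm / bin_cm)
  sc <- .smooth_vec(map$count, k)
  so <- .smooth_vec(map$occupancy_s, k)
  map$smoothed_count <- sc
  map$smoothed_occupancy_s <- so
  map$smoothed_rate_hz <- ifelse(so > 0, sc / so, NA_real_)
  map$bin_width_cm <- bin_cm
  map
}

#' Skaggs-style spatial coding metrics
#'
#' With occupancy probabilities \code{p_i} and bin rates \code{l_i} (mean
#' rate \code{L = sum(p_i l_i)}): information =
#' \code{sum(p_i (l_i/L) log2(l_i/L))} bits/spike; sparsity =
#' \code{(sum(p_i l_i))^2 / sum(p_i l_i^2)}; selectivity = \code{max(l)/L};
#' coherence = Pearson correlation of each bin's (unsmoothed) rate with the
#' mean of its first-order neighbors.
#'
#' @param rate_hz per-bin firing rates (unsmoothed for coherence; the same
#'   vector is used for all four metrics).
#' @param occupancy_s per-bin occupancy times.
#' @return list of class \code{"spatial_metrics"}: \code{information_bits},
#'   \code{selectivity}, \code{sparsity}, \code{coherence},
#'   \code{mean_rate_hz}.
#' @export
spatial_metrics <- function(rate_hz, occupancy_s) {
  ok <- occupancy_s > 0 & !is.na(rate_hz)
  l <- rate_hz[ok]
  p <- occupancy_s[ok] / sum(occupancy_s[ok])
  L <- sum(p * l)
  if (L <= 0) stop("mean rate is zero; metrics undefined")
  rel <- l / L
  info <- sum(p * rel * log2(rel), na.rm = TRUE)   # 0 log 0 = 0
  sparsity <- L^2 / sum(p * l^2)
  sel <- max(l) / L
  n <- length(rate_hz)
  nb <- vapply(seq_len(n), function(i) {
    j <- c(i - 1, i + 1)
    j <- j[j >= 1 & j <= n]
    mean(rate_hz[j], na.rm = TRUE)
  }, numeric(1))
  okc <- is.finite(rate_hz) & is.finite(nb)
  coh <- if (sum(okc) > 2 && stats::sd(rate_hz[okc]) > 0 &&
             stats::sd(nb[okc]) > 0)
    stats::cor(rate_hz[okc], nb[okc]) else NA_real_
  structure(list(information_bits = info, selectivity = sel,
                 sparsity = sparsity, coherence = coh, mean_rate_hz = L),
            class = "spatial_metrics")
}

#' @export
print.spatial_metrics <- function(x, ...) {
  cat(sprintf("Spatial metrics: information %.2f bits/spike, selectivity %.2f, sparsity %.2f, coherence %s\n",
              x$information_bits, x$selectivity, x$sparsity,
              ifelse(is.na(x$coherence), "NA", sprintf("%.2f", x$coherence))))
  invisible(x)
}

#' Place-field detection criteria
#'
#' @param min_size_cm smallest field extent (cm).
#' @param rate_frac fraction of the peak rate delimiting the field.
#' @param min_peak_hz smallest in-maze peak rate.
#' @param min_coherence smallest spatial coherence.
#' @param min_spikes smallest in-field spike count.
#' @return named list of criteria.
#' @export
field_criteria <- function(min_size_cm = 15, rate_frac = 0.1,
                           min_peak_hz = 2, min_coherence = 0.7,
                           min_spikes = 50) {
  list(min_size_cm = min_size_cm, rate_frac = rate_frac,
       min_peak_hz = min_peak_hz, min_coherence = min_coherence,
       min_spikes = min_spikes)
}

#' Detect place fields on a smoothed rate map
#'
#' A field is a contiguous run of bins whose smoothed rate exceeds
#' \code{rate_frac} of the in-maze peak, at least \code{min_size_cm} long,
#' with peak rate above \code{min_peak_hz}, on a map whose spatial coherence
#' exceeds \code{min_coherence}. Fields with fewer than \code{min_spikes}
#' spikes, fields touching the ends of the analysis span (truncated or
#' containing the turning position), and overlapping fields (both members)
#' are discarded.
#'
#' @param smap a \code{\link{smoothed_rate_map}} result.
#' @param criteria a \code{\link{field_criteria}} list.
#' @param metrics optional precomputed \code{\link{spatial_metrics}}; computed
#'   from the raw map when NULL.
#' @return data frame (possibly empty): \code{start_bin}, \code{end_bin},
#'   \code{center_pct}, \code{size_cm}, \code{peak_hz}, \code{n_spikes}.
#' @export
detect_place_fields <- function(smap, criteria = field_criteria(),
                                metrics = NULL) {
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      center_pct = numeric(0), size_cm = numeric(0),
                      peak_hz = numeric(0), n_spikes = numeric(0))
  r <- smap$smoothed_rate_hz
  if (all(is.na(r))) return(empty)
  if (is.null(metrics))
    metrics <- spatial_metrics(smap$rate_hz, smap$occupancy_s)
  if (is.na(metrics$coherence) ||
      metrics$coherence <= criteria$min_coherence) return(empty)
  peak <- max(r, na.rm = TRUE)
  if (peak <= criteria$min_peak_hz) return(empty)
  above <- !is.na(r) & r > criteria$rate_frac * peak
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  n <- length(r)
  edges <- smap$bin_edges_pct
  fields <- list()
  for (i in which(runs$values)) {
    s <- starts[i]; e <- ends[i]
    size_cm <- (e - s + 1) * smap$bin_width_cm
    if (size_cm < criteria$min_size_cm) next
    if (s == 1 || e == n) next           # truncated / includes the turn
    nsp <- sum(smap$count[s:e])
    if (nsp < criteria$min_spikes) next
    pk <- max(r[s:e])
    center <- (edges[s] + edges[e + 1]) / 2
    fields[[length(fields) + 1]] <- data.frame(
      start_bin = s, end_bin = e, center_pct = center, size_cm = size_cm,
      peak_hz = pk, n_spikes = nsp)
  }
  if (!length(fields)) return(empty)
  out <- do.call(rbind, fields)
  # overlapping fields: drop both members of any overlap
  if (nrow(out) > 1) {
    overlap <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(out) - 1))
      for (j in (i + 1):nrow(out))
        if (out$start_bin[j] <= out$end_bin[i] &&
            out$end_bin[j] >= out$start_bin[i])
          overlap[c(i, j)] <- TRUE
    out <- out[!overlap, , drop = FALSE]
  }
  out
}

#' Cross-condition place-field stability
#'
#' Pearson correlation of the binned mean firing patterns in the two
#' conditions.
#'
#' @param map_uniform,map_striped rate maps on matched bins (smoothed rates
#'   are used when present, raw rates otherwise).
#' @return list with \code{rho}, \code{p}, \code{n_bins}.
#' @export
field_stability <- function(map_uniform, map_striped) {
  pick <- function(m) m$smoothed_rate_hz %||% m$rate_hz
  a <- pick(map_uniform); b <- pick(map_striped)
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    stop("constant rate map; stability undefined")
  ct <- stats::cor.test(a[ok], b[ok])
  list(rho = unname(ct$estimate), p = ct$p.value, n_bins = sum(ok))
}
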