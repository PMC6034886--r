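#' Synthetic histology images with known ground truth
#'
#' Renders grayscale images containing bright Gaussian somata and thin bright
#' axon polylines over a noisy background, with optional region and artifact
#' masks, returning the true soma coordinates and the rendered axon pixel
#' mask for end-to-end validation of the density pipeline.
#'
#' @name synthetic_images
NULL

#' Generate a synthetic density image
#'
#' @param n_somata number of somata to render.
#' @param n_axons number of axon segments.
#' @param size_px image side length in pixels; must divide into the
#'   \code{grid_dim} x \code{grid_dim} grid.
#' @param grid_dim density-grid size per side.
#' @param soma_width_px soma blob FWHM in pixels.
#' @param min_sep_px minimum center-to-center separation of somata.
#' @param soma_amp soma peak brightness above background.
#' @param axon_amp axon brightness above background.
#' @param bg_mean,bg_sd background intensity mean and SD.
#' @param region_mask optional logical exclusion mask (TRUE = excluded); no
#'   somata or axons are rendered there.
#' @param seed integer seed.
#' @return list of class \code{"density_image"}: \code{image} (matrix),
#'   \code{region_mask}, \code{soma_rc} (true centers, rows/cols),
#'   \code{axon_mask} (logical matrix of rendered axon pixels),
#'   \code{bg_mean}, \code{bg_sd}.
#' @export
gen_density_image <- function(n_somata = 200, n_axons = 0, size_px = 1280,
                              grid_dim = 10, soma_width_px = 14,
                              min_sep_px = 20, soma_amp = 1, axon_amp = 1,
                              bg_mean = 0.2, bg_sd = 0.02,
                              region_mask = NULL, seed = 1L) {
  if (size_px %% grid_dim != 0)
    stop("image side must divide into the grid")
  set.seed(as.integer(seed))
  img <- matrix(stats::rnorm(size_px^2, bg_mean, bg_sd), size_px, size_px)
  valid <- if (is.null(region_mask)) matrix(TRUE, size_px, size_px)
           else !region_mask

  sigma <- soma_width_px / (2 * sqrt(2 * log(2)))
  r <- ceiling(3 * sigma)
  margin <- r                       # keep the whole rendered patch in frame
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n_somata && tries < n_somata * 200) {
    tries <- tries + 1
    rc <- sample((margin + 1):(size_px - margin), 2, replace = TRUE)
    if (!valid[rc[1], rc[2]]) next
    if (nrow(centers) &&
        min(sqrt((centers[, 1] - rc[1])^2 + (centers[, 2] - rc[2])^2)) <
          min_sep_px) next
    centers <- rbind(centers, rc)
  }
  if (nrow(centers) < n_somata)
    stop("could not place somata at the requested separation")
  patch <- outer(-r:r, -r:r, function(a, b)
    exp(-(a^2 + b^2) / (2 * sigma^2)))
  for (i in seq_len(nrow(centers))) {
    rows <- (centers[i, 1] - r):(centers[i, 1] + r)
    cols <- (centers[i, 2] - r):(centers[i, 2] + r)
    img[rows, cols] <- img[rows, cols] + soma_amp * patch
  }

  axon_mask <- matrix(FALSE, size_px, size_px)
  for (a in seq_len(n_axons)) {
    p0 <- stats::runif(2, 1, size_px)
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, size_px / 8, size_px / 2)
    steps <- ceiling(len)
    rr <- round(seq(p0[1], p0[1] + len * cos(ang), length.out = steps))
    cc <- round(seq(p0[2], p0[2] + len * sin(ang), length.out = steps))
    ok <- rr >= 1 & rr <= size_px & cc >= 1 & cc <= size_px
    idx <- cbind(rr[ok], cc[ok])
    idx <- idx[valid[idx], , drop = FALSE]
    axon_mask[idx] <- TRUE
  }
  img[axon_mask] <- bg_mean + axon_amp
  if (!is.null(region_mask)) img[region_mask] <- 0

  structure(list(image = img, region_mask = region_mask,
                 soma_rc = data.frame(row = centers[, 1],
                                      col = centers[, 2]),
                 axon_mask = axon_mask, bg_mean = bg_mean, bg_sd = bg_sd),
            class = "density_image")
}

#' @export
print.density_image <- function(x, ...) {
  cat(sprintf("Synthetic density image: %dx%d px, %d somata, %d axon pixels\n",
              nrow(x$image), ncol(x$image), nrow(x$soma_rc),
              sum(x$axon_mask)))
  invisible(x)
}
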