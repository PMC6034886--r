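#' Automated histology density quantification
#'
#' Soma detection (blob-scale matched filtering with minimum-distance peak
#' selection), axon thresholding (mean + 4 SD of the nonmasked luminosity),
#' gridded density maps over 10 x 10 subregions with a valid-area floor, and
#' their correlation and quartile statistics. Images are grayscale matrices
#' (rows x columns, intensities in arbitrary units); masks are logical
#' matrices of the same shape where TRUE marks pixels to exclude.
#'
#' @name image_density
NULL

.valid_mask <- function(image, region_mask = NULL, artifact_mask = NULL) {
  v <- matrix(TRUE, nrow(image), ncol(image))
  if (!is.null(region_mask)) v <- v & !region_mask
  if (!is.null(artifact_mask)) v <- v & !artifact_mask
  v
}

#' Threshold BDA-labeled axon pixels
#'
#' The threshold is the mean + \code{n_sd} SD of the luminosity over the
#' nonmasked pixels only; pixels brighter than the threshold count as labeled
#' axons. Masked pixels are never flagged.
#'
#' @param image grayscale matrix.
#' @param region_mask,artifact_mask logical exclusion masks (TRUE = excluded).
#' @param n_sd threshold in SD units above the mean.
#' @return list with \code{binary} (logical matrix), \code{threshold},
#'   \code{n_pixels} (suprathreshold count).
#' @export
threshold_axons <- function(image, region_mask = NULL, artifact_mask = NULL,
                            n_sd = 4) {
  v <- .valid_mask(image, region_mask, artifact_mask)
  if (!any(v)) stop("image fully masked")
  px <- image[v]
  thr <- mean(px) + n_sd * stats::sd(px)
  if (is.na(thr)) thr <- mean(px)        # constant image: SD undefined
  bin <- image > thr & v
  list(binary = bin, threshold = thr, n_pixels = sum(bin))
}

# Laplacian-of-Gaussian kernel, sign-flipped so bright blobs respond positive
.log_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- expand.grid(x = -r:r, y = -r:r)
  v <- with(g, (x^2 + y^2 - 2 * sigma^2) / sigma^4 *
              exp(-(x^2 + y^2) / (2 * sigma^2)))
  k <- -matrix(v, 2 * r + 1, 2 * r + 1) * sigma^2   # scale-normalized
  k - mean(k)
}

#' Detect somata by blob-scale matched filtering
#'
#' Convolves the image with a scale-normalized Laplacian-of-Gaussian kernel
#' at \code{sigma = width_px / 2.355}, keeps local maxima separated by at
#' least \code{min_distance_px}, and thresholds the filter response at
#' \code{threshold} SD above its mean over the valid area. Masked regions are
#' excluded.
#'
#' @param image grayscale matrix (bright somata on darker background).
#' @param region_mask,artifact_mask logical exclusion masks.
#' @param width_px expected soma width (blob FWHM) in pixels.
#' @param min_distance_px minimum separation of detections.
#' @param threshold response threshold in SD units.
#' @return data frame with \code{row}, \code{col}, \code{response}; zero rows
#'   when nothing is detected.
#' @export
detect_somata <- function(image, region_mask = NULL, artifact_mask = NULL,
                          width_px = 14, min_distance_px = 7, threshold = 1) {
  v <- .valid_mask(image, region_mask, artifact_mask)
  k <- .log_kernel(width_px / 2.355)
  resp <- EBImage::filter2(image, k)
  brush <- EBImage::makeBrush(2 * min_distance_px + 1, shape = "disc")
  localmax <- EBImage::dilate(resp, brush)
  thr <- mean(resp[v]) + threshold * stats::sd(resp[v])
  hits <- which(resp >= localmax - 1e-12 & resp > thr & v, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(row = integer(0), col = integer(0),
                      response = numeric(0)))
  # greedy suppression: exactly tied plateau pixels (e.g. two equal blobs
  # closer than the minimum distance) all survive the dilation test, so the
  # separation rule must be enforced on the candidate list as well
  ord <- order(resp[hits], decreasing = TRUE)
  kept <- matrix(numeric(0), 0, 2)
  for (i in ord) {
    p <- hits[i, ]
    if (nrow(kept) &&
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) <
          min_distance_px^2) next
    kept <- rbind(kept, p)
  }
  data.frame(row = as.integer(kept[, 1]), col = as.integer(kept[, 2]),
             response = resp[kept])
}

#' Gridded density of detections or suprathreshold pixels
#'
#' Divides the image into a \code{grid_dim x grid_dim} grid of
#' \code{cell_px x cell_px} subregions and computes per-cell densities
#' normalized by the nonmasked area. Cells with fewer than
#' \code{min_valid_px} valid pixels are invalidated.
#'
#' @param x either a two-column detection table (\code{row}, \code{col}) or a
#'   logical/binary matrix of labeled pixels.
#' @param dim_px image dimensions \code{c(rows, cols)} (taken from \code{x}
#'   when it is a matrix).
#' @param region_mask,artifact_mask logical exclusion masks.
#' @param grid_dim grid size per side.
#' @param cell_px subregion side length in pixels; defaults to
#'   \code{dim_px / grid_dim}.
#' @param min_valid_px valid-pixel floor below which a cell is invalid.
#' @return list of class \code{"density_grid"}: \code{density} (grid_dim x
#'   grid_dim, NA where invalid), \code{count}, \code{valid_px},
#'   \code{valid} (logical).
#' @export
binned_density <- function(x, dim_px = NULL, region_mask = NULL,
                           artifact_mask = NULL, grid_dim = 10,
                           cell_px = NULL, min_valid_px = 2600) {
  if (is.matrix(x) && is.null(dim_px)) dim_px <- dim(x)
  stopifnot(!is.null(dim_px))
  if (is.null(cell_px)) cell_px <- dim_px[1] / grid_dim
  if (grid_dim * cell_px > dim_px[1] || grid_dim * cell_px > dim_px[2])
    stop("grid exceeds the image")
  cell_of <- function(i) pmin(grid_dim, (ceiling(i / cell_px)))
  v <- .valid_mask(matrix(0, dim_px[1], dim_px[2]), region_mask,
                   artifact_mask)
  idx <- which(v, arr.ind = TRUE)
  valid_px <- matrix(0, grid_dim, grid_dim)
  tab <- table(factor(cell_of(idx[, 1]), levels = 1:grid_dim),
               factor(cell_of(idx[, 2]), levels = 1:grid_dim))
  valid_px[] <- as.numeric(tab)
  count <- matrix(0, grid_dim, grid_dim)
  if (is.matrix(x)) {
    hit <- which((x > 0) & v, arr.ind = TRUE)
    if (nrow(hit)) {
      tc <- table(factor(cell_of(hit[, 1]), levels = 1:grid_dim),
                  factor(cell_of(hit[, 2]), levels = 1:grid_dim))
      count[] <- as.numeric(tc)
    }
  } else {
    keep <- x$row >= 1 & x$row <= dim_px[1] & x$col >= 1 & x$col <= dim_px[2]
    d <- x[keep, , drop = FALSE]
    if (nrow(d)) {
      ok <- v[cbind(d$row, d$col)]
      d <- d[ok, , drop = FALSE]
      if (nrow(d)) {
        tc <- table(factor(cell_of(d$row), levels = 1:grid_dim),
                    factor(cell_of(d$col), levels = 1:grid_dim))
        count[] <- as.numeric(tc)
      }
    }
  }
  valid <- valid_px >= min_valid_px
  dens <- ifelse(valid, count / valid_px, NA_real_)
  structure(list(density = dens, count = count, valid_px = valid_px,
                 valid = valid),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %dx%d cells, %d valid, mean density %.3g per px\n",
              nrow(x$density), ncol(x$density), sum(x$valid),
              mean(x$density, na.rm = TRUE)))
  invisible(x)
}

#' Correlation of two density grids
#'
#' Pearson correlation over jointly valid cells only.
#'
#' @param grid_a,grid_b \code{\link{binned_density}} results on matching
#'   grids.
#' @param min_cells minimum jointly valid cells.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
density_correlation <- function(grid_a, grid_b, min_cells = 10) {
  ok <- grid_a$valid & grid_b$valid
  if (sum(ok) < min_cells)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(grid_a$density[ok], grid_b$density[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Mean soma density per axon-density quartile
#'
#' Assigns jointly valid cells to quartiles of the axon (BDA) density and
#' compares the soma (cFos) densities of consecutive quartiles with
#' two-sample tests.
#'
#' @param cfos_grid,bda_grid \code{\link{binned_density}} results.
#' @param min_cells minimum jointly valid cells.
#' @param test "wilcoxon" or "t".
#' @return list with \code{quartile_mean}, \code{quartile_se} (length 4),
#'   \code{n_per_quartile}, \code{p_consecutive} (length 3), \code{flagged}
#'   (TRUE when ties empty a quartile).
#' @export
quartile_analysis <- function(cfos_grid, bda_grid, min_cells = 8,
                              test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  ok <- cfos_grid$valid & bda_grid$valid
  if (sum(ok) < min_cells) stop("too few jointly valid cells")
  b <- bda_grid$density[ok]; cf <- cfos_grid$density[ok]
  qs <- stats::quantile(b, c(0.25, 0.5, 0.75))
  if (any(duplicated(qs)))
    return(list(quartile_mean = rep(NA_real_, 4),
                quartile_se = rep(NA_real_, 4),
                n_per_quartile = rep(0L, 4),
                p_consecutive = rep(NA_real_, 3), flagged = TRUE))
  qi <- findInterval(b, qs) + 1L
  means <- tapply(cf, factor(qi, levels = 1:4), mean)
  ses <- tapply(cf, factor(qi, levels = 1:4),
                function(z) stats::sd(z) / sqrt(length(z)))
  ns <- tapply(cf, factor(qi, levels = 1:4), length)
  ns[is.na(ns)] <- 0
  pc <- vapply(1:3, function(i) {
    a <- cf[qi == i]; d <- cf[qi == i + 1]
    if (length(a) < 2 || length(d) < 2) return(NA_real_)
    if (test == "t") stats::t.test(a, d)$p.value
    else stats::wilcox.test(a, d, exact = FALSE)$p.value
  }, numeric(1))
  list(quartile_mean = as.numeric(means), quartile_se = as.numeric(ses),
       n_per_quartile = as.integer(ns), p_consecutive = pc,
       flagged = any(ns == 0))
}

#' Read and write grayscale TIFF images as matrices
#'
#' Thin wrappers over the tiff package; intensities are scaled to [0, 1] on
#' write.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @return \code{read_density_image} returns a numeric matrix in [0, 1].
#' @export
write_density_image <- function(image, path) {
  m <- image / max(image, 1e-12)
  tiff::writeTIFF(m, path)
  invisible(path)
}

#' @rdname write_density_image
#' @export
read_density_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}
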