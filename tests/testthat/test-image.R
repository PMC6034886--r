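test_that("axon threshold is mean + 4 SD of the nonmasked pixels", {
  img <- matrix(0.5, 100, 100)
  ta <- threshold_axons(img)
  expect_equal(ta$n_pixels, 0)           # SD = 0: threshold = mean
  set.seed(1)
  img <- matrix(rnorm(1e4, 0.2, 0.01), 100, 100)
  bright <- cbind(sample(100, 20), sample(100, 20))
  img[bright] <- 0.2 + 10 * 0.01 * 5     # far above mean + 4 SD
  ta <- threshold_axons(img)
  expect_equal(ta$n_pixels, nrow(unique(bright)))
  expect_true(all(ta$binary[unique(bright)]))
})

test_that("masked pixels never count as axons and never move the threshold", {
  set.seed(2)
  img <- matrix(rnorm(1e4, 0.2, 0.01), 100, 100)
  base <- threshold_axons(img)
  mask <- matrix(FALSE, 100, 100); mask[1:10, ] <- TRUE
  img2 <- img; img2[mask] <- 100         # brighten only masked pixels
  ta <- threshold_axons(img2, artifact_mask = mask)
  expect_equal(ta$threshold, threshold_axons(img, artifact_mask = mask)$threshold)
  expect_false(any(ta$binary[mask]))
  expect_error(threshold_axons(img, region_mask = matrix(TRUE, 100, 100)),
               "masked")
  expect_equal(base$threshold, mean(img) + 4 * sd(img))
})

test_that("soma detector finds nothing on blank images", {
  expect_equal(nrow(detect_somata(matrix(0.2, 300, 300))), 0)
})

test_that("200 rendered somata are detected within 200 +/- 10", {
  gi <- gen_density_image(n_somata = 200, seed = 1)
  det <- detect_somata(gi$image)
  expect_true(abs(nrow(det) - 200) <= 10)
  # detections sit on the true centers
  d2 <- as.matrix(dist(rbind(as.matrix(gi$soma_rc),
                             cbind(det$row, det$col))))
  nt <- nrow(gi$soma_rc)
  mind <- apply(d2[seq_len(nt), -seq_len(nt), drop = FALSE], 1, min)
  expect_gte(sum(mind <= 7), 190)
})

test_that("two blobs closer than the minimum distance give one detection", {
  img <- matrix(0, 200, 200)
  sig <- 14 / 2.355; r <- ceiling(3 * sig)
  patch <- outer(-r:r, -r:r, function(a, b) exp(-(a^2 + b^2) / (2 * sig^2)))
  for (cc in c(100, 105))
    img[(100 - r):(100 + r), (cc - r):(cc + r)] <-
      img[(100 - r):(100 + r), (cc - r):(cc + r)] + patch
  expect_equal(nrow(detect_somata(img)), 1)
})

test_that("detections never fall in masked regions", {
  mask <- matrix(FALSE, 640, 640); mask[, 321:640] <- TRUE
  gi <- gen_density_image(n_somata = 40, size_px = 640, region_mask = mask,
                          seed = 4)
  det <- detect_somata(gi$image, region_mask = mask)
  expect_true(all(det$col <= 320))
  expect_gt(nrow(det), 30)
})

test_that("empty and axon-only images validate the generator's ground truth", {
  gi <- gen_density_image(n_somata = 0, n_axons = 0, size_px = 320, seed = 5)
  expect_equal(nrow(gi$soma_rc), 0)
  # (no detection assertion here: the detector thresholds at 1 SD of its own
  # response, so on a pure-noise image it fires on noise maxima by design;
  # the flat-image zero case is covered above)
  ga <- gen_density_image(n_somata = 0, n_axons = 50, seed = 9)
  ta <- threshold_axons(ga$image)
  expect_lt(abs(ta$n_pixels / sum(ga$axon_mask) - 1), 0.1)
})

test_that("binned density normalizes by valid area with the pixel floor", {
  # uniform grid of detections: equal densities everywhere
  det <- expand.grid(row = seq(4, 636, by = 8), col = seq(4, 636, by = 8))
  g <- binned_density(det, dim_px = c(640, 640))
  expect_true(all(g$valid))
  expect_equal(length(unique(as.vector(g$density))), 1)
  expect_equal(sum(g$count), nrow(det))
  # fully masked cell is invalid
  mask <- matrix(FALSE, 640, 640)
  mask[1:64, 1:64] <- TRUE               # kill cell (1,1)
  gm <- binned_density(det, dim_px = c(640, 640), region_mask = mask)
  expect_false(gm$valid[1, 1])
  expect_true(is.na(gm$density[1, 1]))
})

test_that("cells under the 2,600 valid-pixel floor are invalidated", {
  det <- data.frame(row = 10, col = 10)
  mask <- matrix(FALSE, 1280, 1280)
  mask[1:128, 1:78] <- TRUE              # leaves 128 * 50 = 6400 valid
  g1 <- binned_density(det, dim_px = c(1280, 1280), region_mask = mask)
  expect_true(g1$valid[1, 1])
  mask[1:128, 1:108] <- TRUE             # leaves 128 * 20 = 2560 < 2600
  g2 <- binned_density(det, dim_px = c(1280, 1280), region_mask = mask)
  expect_false(g2$valid[1, 1])
  expect_error(binned_density(det, dim_px = c(50, 50), cell_px = 10), "grid")
})

test_that("half-masked cells report density on the valid area", {
  # 20 detections in the valid half of cell (1,1)
  det <- data.frame(row = rep(seq(36, 64, length.out = 5), 4),
                    col = rep(seq(4, 61, length.out = 4), each = 5))
  mask <- matrix(FALSE, 640, 640)
  mask[1:32, 1:64] <- TRUE               # top half of cell (1,1)
  g <- binned_density(det, dim_px = c(640, 640), region_mask = mask,
                      min_valid_px = 100)
  expect_equal(g$density[1, 1], 20 / (64 * 64 / 2))
  g0 <- binned_density(det, dim_px = c(640, 640), min_valid_px = 100)
  expect_equal(g$density[1, 1], 2 * g0$density[1, 1])
})

test_that("matrix and detection-table inputs agree", {
  set.seed(6)
  m <- matrix(FALSE, 640, 640)
  idx <- cbind(sample(640, 300, TRUE), sample(640, 300, TRUE))
  m[idx] <- TRUE
  gm <- binned_density(m)
  gd <- binned_density(data.frame(row = idx[, 1], col = idx[, 2]),
                       dim_px = c(640, 640))
  expect_equal(gm$count, gd$count)
})

test_that("density correlation recovers a shared spatial gradient", {
  set.seed(7)
  lam <- outer(1:10, 1:10, function(a, b) 5 + 3 * a)   # common gradient
  mk <- function() {
    g <- binned_density(data.frame(row = 1, col = 1), dim_px = c(1280, 1280))
    g$count[] <- rpois(100, lam)
    g$density <- g$count / g$valid_px
    g
  }
  dc <- density_correlation(mk(), mk())
  expect_gt(dc$r, 0.7)
  expect_lt(dc$p, 1e-10)
  expect_equal(dc$n, 100)
  # too few jointly valid cells
  ga <- mk(); ga$valid[] <- FALSE; ga$valid[1, 1:5] <- TRUE
  expect_true(is.na(density_correlation(ga, mk())$r))
})

test_that("quartile analysis orders means along a monotone relation", {
  set.seed(8)
  mkg <- function(dens) {
    g <- binned_density(data.frame(row = 1, col = 1), dim_px = c(1280, 1280))
    g$density[] <- dens
    g
  }
  b <- runif(100)
  qa <- quartile_analysis(mkg(2 * b + rnorm(100, 0, 0.05)), mkg(b))
  expect_equal(qa$n_per_quartile, rep(25L, 4))
  expect_true(all(diff(qa$quartile_mean) > 0))
  expect_true(all(qa$p_consecutive < 0.05))
  expect_false(qa$flagged)
  # heavy ties collapse quartiles and flag the result
  qa2 <- quartile_analysis(mkg(b), mkg(rep(1, 100)))
  expect_true(qa2$flagged)
})

test_that("tiff round trip preserves the scaled image", {
  gi <- gen_density_image(n_somata = 20, size_px = 320, seed = 10)
  tf <- tempfile(fileext = ".tif")
  on.exit(unlink(tf))
  write_density_image(gi$image, tf)
  back <- read_density_image(tf)
  expect_equal(dim(back), dim(gi$image))
  expect_lt(max(abs(back - gi$image / max(gi$image))), 1 / 100)
  expect_equal(nrow(detect_somata(back)), nrow(detect_somata(gi$image)))
})
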