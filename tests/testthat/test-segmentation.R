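test_that("normalisation maps linearly onto the 16-bit range", {
  const <- calibrated_image(matrix(7, 10, 10), 0.1)
  expect_true(all(normalize_image(const)$intensities == 0))

  m <- matrix(10, 4, 4); m[1, 1] <- 20; m[2, 2] <- 15
  nm <- normalize_image(calibrated_image(m, 0.1))
  expect_equal(nm$intensities[1, 1], 65535)
  expect_equal(nm$intensities[3, 3], 0)
  expect_equal(nm$intensities[2, 2], 32768)  # round-half-up

  twice <- normalize_image(nm)
  expect_identical(twice$intensities, nm$intensities)
})

test_that("band-pass filter responds to tubes, not constants", {
  const <- calibrated_image(matrix(5, 32, 32), 0.1)
  expect_true(all(bandpass_filter(const, 0.1, 1)$intensities == 0))

  imp <- matrix(0, 33, 33); imp[17, 17] <- 100
  r <- bandpass_filter(calibrated_image(imp, 0.1), 0.1, 1)$intensities
  expect_equal(which.max(r), which(matrix(seq_len(33^2), 33) == (16 * 33 + 17)))

  expect_error(bandpass_filter(const, 1, 0.5), "must be <")

  # a tube on a smooth gradient: centreline response beats the background
  g <- matrix(rep(seq(0, 40, length.out = 64), each = 64), 64, 64)
  tube <- g; tube[30:33, 10:54] <- tube[30:33, 10:54] + 60
  bp <- bandpass_filter(calibrated_image(tube, 0.1), 0.2, 1.2)$intensities
  centreline <- bp[31, 12:52]
  background <- bp[10, 12:52]
  expect_true(all(centreline > background))
})

test_that("cell segmentation finds separated cells and respects split flag", {
  out <- generate_mito_image(synthetic_image_spec(
    n_cells = 3, mito_per_cell = 5, image_size = c(300, 300),
    noise_sd = 0, seed = 5))
  labels <- segment_cells(out$image, default_params())
  # oracle: connected components of the ground-truth cell mask
  truth_cc <- EBImage::bwlabel(EBImage::Image((out$truth$cell_labels > 0) * 1))
  expect_equal(max(labels), max(truth_cc))
  expect_equal(max(labels), 3L)

  blank <- calibrated_image(matrix(3, 64, 64), 0.1)
  expect_equal(max(segment_cells(blank, default_params())), 0L)

  # two discs fused by a thin neck: split_enabled separates them
  fused <- matrix(0, 90, 170)
  g <- expand.grid(r = 1:90, c = 1:170)
  fused[sqrt((g$r - 45)^2 + (g$c - 48)^2) <= 32] <- 100
  fused[sqrt((g$r - 45)^2 + (g$c - 122)^2) <= 32] <- 100
  fused[43:47, 48:122] <- 100
  img <- calibrated_image(fused + 1, 0.1)
  expect_equal(max(segment_cells(img, default_params(split_enabled = TRUE))), 2L)
  expect_equal(max(segment_cells(img, default_params(split_enabled = FALSE))), 1L)
})

test_that("mitochondrial segmentation recovers disjoint capsules", {
  out <- noiseless_fixture(seed = 17, n_mito = 5)
  cells <- segment_cells(out$image, default_params())
  mito <- segment_mitochondria(out$image, default_params(), cells)
  expect_equal(max(mito), nrow(out$truth$objects))

  # shape mismatch is an error
  expect_error(segment_mitochondria(out$image, default_params(),
                                    matrix(1L, 10, 10)), "shapes differ")
})

test_that("objects outside cell masks and tiny specks are excluded", {
  m <- matrix(0, 80, 80)
  g <- expand.grid(r = 1:80, c = 1:80)
  # one bright blob inside the "cell", one outside, plus a 2-px speck inside
  m[sqrt((g$r - 40)^2 + (g$c - 30)^2) <= 4] <- 200
  m[sqrt((g$r - 15)^2 + (g$c - 70)^2) <= 4] <- 200
  m[44:45, 40] <- 200
  img <- calibrated_image(m, 0.1)
  cells <- matrix(0L, 80, 80)
  cells[g$r[sqrt((g$r - 40)^2 + (g$c - 33)^2) <= 20] +
          (g$c[sqrt((g$r - 40)^2 + (g$c - 33)^2) <= 20] - 1L) * 80L] <- 1L
  p <- default_params(threshold_method = "fixed", fixed_threshold = 30,
                      min_object_area_um2 = 0.1, split_enabled = FALSE)
  mito <- segment_mitochondria(img, p, cells)
  expect_equal(max(mito), 1L)  # outside blob and tiny speck both gone
  # the kept object sits inside the cell
  expect_true(all(cells[mito > 0] == 1L))

  # with the tiny-object filter disabled the speck survives
  p2 <- default_params(threshold_method = "fixed", fixed_threshold = 30,
                       min_object_area_um2 = 0, split_enabled = FALSE)
  expect_equal(max(segment_mitochondria(img, p2, cells)), 2L)
})

test_that("raising a fixed threshold never increases the foreground", {
  out <- noiseless_fixture(seed = 23)
  cells <- matrix(1L, nrow(out$image$intensities), ncol(out$image$intensities))
  fg <- vapply(c(10, 30, 60, 90), function(th) {
    p <- default_params(threshold_method = "fixed", fixed_threshold = th,
                        min_object_area_um2 = 0, split_enabled = FALSE)
    sum(segment_mitochondria(out$image, p, cells) > 0)
  }, numeric(1))
  expect_true(all(diff(fg) <= 0))
})

test_that("watershed split separates the dumbbell and conserves pixels", {
  mask <- dumbbell_mask(r = 8L)
  labels <- split_touching(mask, prominence_um = 0.3, pixel_size_um = 0.1)
  expect_equal(max(labels), 2L)
  expect_identical(labels > 0, mask > 0)

  # independent oracle: the distance transform has two prominent maxima
  d <- brute_distmap(mask)
  pk <- which(d == max(d), arr.ind = TRUE)
  p1 <- pk[1, ]; p2 <- pk[nrow(pk), ]
  expect_gt(sqrt(sum((p1 - p2)^2)), 8)        # one peak per disc
  saddle <- brute_saddle(d, p1, p2)
  prom_px <- min(d[p1[1], p1[2]], d[p2[1], p2[2]]) - saddle
  expect_gt(prom_px, 0.3 / 0.1)  # both maxima clear the requested prominence

  # prominence above the peak height merges everything back to one label
  expect_equal(max(split_touching(mask, prominence_um = 2, pixel_size_um = 0.1)), 1L)

  # a single disc has one maximum and passes through unchanged
  dm <- disc_mask(10L)
  expect_equal(max(split_touching(dm, 0.15, 0.1)), 1L)
})

test_that("split label count is monotone as prominence decreases", {
  mask <- dumbbell_mask(r = 8L)
  proms <- c(1.2, 0.8, 0.5, 0.3, 0.15, 0.05)
  counts <- vapply(proms, function(p) max(split_touching(mask, p, 0.1)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("micrometre parameters are resolution-invariant", {
  out <- noiseless_fixture(seed = 31, n_mito = 5)
  cells <- segment_cells(out$image, default_params())
  n1 <- max(segment_mitochondria(out$image, default_params(), cells))

  # same scene sampled at 2x resolution: pixel replication, half pixel size
  up <- kronecker(out$image$intensities, matrix(1, 2, 2))
  img2 <- calibrated_image(up, out$image$pixel_size_um / 2)
  cells2 <- segment_cells(img2, default_params())
  n2 <- max(segment_mitochondria(img2, default_params(), cells2))
  expect_equal(n1, n2)
})

test_that("MFI is a per-label mean with exact merge identity", {
  m <- matrix(0, 20, 20)
  m[2:5, 2:5] <- 50; m[10:15, 10:13] <- 150
  lab <- matrix(0L, 20, 20)
  lab[2:5, 2:5] <- 1L; lab[10:15, 10:13] <- 2L
  img <- calibrated_image(m, 0.1)
  tab <- measure_mfi(img, lab)
  expect_equal(tab$mean_intensity, c(50, 150))
  expect_equal(tab$n_pixels, c(16L, 24L))

  merged <- lab; merged[merged == 2L] <- 1L
  mtab <- measure_mfi(img, merged)
  expect_equal(mtab$mean_intensity,
               sum(tab$total_intensity) / sum(tab$n_pixels))

  # uniform region
  u <- calibrated_image(matrix(100, 20, 20), 0.1)
  expect_equal(measure_mfi(u, lab)$mean_intensity, c(100, 100))

  # empty label map -> empty table, not an error
  expect_equal(nrow(measure_mfi(img, matrix(0L, 20, 20))), 0L)
})
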