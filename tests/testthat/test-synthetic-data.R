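test_that("image generator produces the requested objects deterministically", {
  spec <- synthetic_image_spec(n_cells = 1, mito_per_cell = 5,
                               allow_touching = FALSE, seed = 7)
  a <- generate_mito_image(spec)
  expect_equal(nrow(a$truth$objects), 5L)
  expect_equal(n_distinct <- length(unique(a$truth$mito_labels[a$truth$mito_labels > 0])), 5L)

  b <- generate_mito_image(spec)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$truth$mito_labels, b$truth$mito_labels)
  expect_identical(a$truth$objects, b$truth$objects)

  d <- generate_mito_image(synthetic_image_spec(n_cells = 1, mito_per_cell = 5,
                                                seed = 8))
  expect_false(identical(a$image$intensities, d$image$intensities))
})

test_that("length mix drives the drawn classes", {
  all_short <- generate_mito_image(synthetic_image_spec(
    length_mix = c(1, 0, 0), mito_per_cell = 8, seed = 3))
  expect_true(all(all_short$truth$objects$length_um < 1))

  all_long <- generate_mito_image(synthetic_image_spec(
    length_mix = c(0, 0, 1), mito_per_cell = 4, seed = 3))
  expect_true(all(all_long$truth$objects$length_um > 3))
})

test_that("ground truth is internally consistent", {
  for (s in c(11, 12, 13)) {
    out <- generate_mito_image(synthetic_image_spec(
      n_cells = 2, mito_per_cell = 6, image_size = c(256, 256), seed = s))
    tr <- out$truth
    # every truth id appears in the label map, and inside its owning cell
    for (i in seq_len(nrow(tr$objects))) {
      pix <- which(tr$mito_labels == tr$objects$object_id[i], arr.ind = TRUE)
      expect_gt(nrow(pix), 0)
      owner <- tr$cell_labels[pix]
      expect_true(all(owner %in% c(0L, tr$objects$cell_id[i])))
      expect_gt(mean(owner == tr$objects$cell_id[i]), 0.5)
    }
    # total true area cannot exceed the physical image area
    px <- out$image$pixel_size_um
    expect_lte(sum(tr$objects$area_um2),
               prod(dim(out$image$intensities)) * px^2)
  }
})

test_that("empirical length-class fractions match the spec mix", {
  mix <- c(0.25, 0.45, 0.30)
  out <- generate_mito_image(synthetic_image_spec(
    n_cells = 40, mito_per_cell = 8, image_size = c(1000, 1000),
    length_mix = mix, noise_sd = 0, seed = 21))
  obj <- out$truth$objects
  n <- nrow(obj)
  expect_gte(n, 300)
  emp <- c(mean(obj$length_um < 1),
           mean(obj$length_um >= 1 & obj$length_um <= 3),
           mean(obj$length_um > 3))
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(emp - mix) <= 3 * se))
})

test_that("generator rejects invalid specs and impossible placements", {
  expect_error(synthetic_image_spec(length_mix = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(synthetic_image_spec(pixel_size_um = 0), "pixel_size_um")
  expect_error(synthetic_image_spec(noise_sd = -1), "noise_sd")
  # far too many long tubes for one small cell -> placement failure names it
  expect_error(
    generate_mito_image(synthetic_image_spec(
      n_cells = 1, mito_per_cell = 40, length_mix = c(0, 0, 1),
      image_size = c(256, 256), seed = 1)),
    "placement failure.*cell 1")
})

test_that("time-series generator follows the cosine truth", {
  flat <- generate_timeseries(rhythm_sim_spec(mesor = 10, amplitude = 0,
                                              noise_sd = 0))
  expect_true(all(flat$value == 10))

  ts <- generate_timeseries(rhythm_sim_spec(mesor = 10, amplitude = 3,
                                            acrophase_h = 8, noise_sd = 0,
                                            times_h = seq(0, 48, by = 4)))
  expect_equal(unique(ts$value[ts$time_h == 8]), 13)
  # noiseless values lie exactly on the cosine curve
  mu <- 10 + 3 * cos(2 * pi * (ts$time_h - 8) / 24)
  expect_lt(max(abs(ts$value - mu)), 1e-9 * 3)

  # noisy mean within 3 SE of the design-mean
  spec <- rhythm_sim_spec(mesor = 10, amplitude = 2, acrophase_h = 6,
                          noise_sd = 1, replicates = 3, seed = 1)
  noisy <- generate_timeseries(spec)
  design_mean <- mean(10 + 2 * cos(2 * pi * (noisy$time_h - 6) / 24))
  se <- 1 / sqrt(nrow(noisy))
  expect_lt(abs(mean(noisy$value) - design_mean), 3 * se)

  expect_error(rhythm_sim_spec(noise_sd = -0.1), "noise_sd")
  expect_identical(generate_timeseries(spec), generate_timeseries(spec))
})

test_that("OCR generator reproduces the phase profile", {
  tr <- generate_ocr_trace(ocr_sim_spec(rates = c(100, 40, 160, 20),
                                        measurements_per_phase = 3,
                                        noise_sd = 0))
  expect_equal(nrow(tr), 12L)
  expect_equal(tr$ocr, rep(c(100, 40, 160, 20), each = 3))
  expect_equal(unname(attr(tr, "injections")), c(1, 4, 7, 10))

  spec <- ocr_sim_spec(rates = c(100, 40, 160, 20),
                       measurements_per_phase = 3, noise_sd = 5, seed = 2)
  expect_identical(generate_ocr_trace(spec), generate_ocr_trace(spec))
  noisy <- generate_ocr_trace(spec)
  means <- tapply(noisy$ocr, noisy$phase, mean)
  expect_true(all(abs(means - c(100, 40, 160, 20)) <= 3 * 5 / sqrt(3)))

  expect_error(ocr_sim_spec(measurements_per_phase = 0), "at least 1")
  expect_error(ocr_sim_spec(rates = c(-1, 2, 3, 4)), "non-negative")
})
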