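img_for <- function(mask, px = 0.1)
  calibrated_image(mask * 100 + 1, px)

measure_mask <- function(mask, px = 0.1) {
  lab <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  measure_objects(lab, img_for(mask, px), matrix(1L, nrow(mask), ncol(mask)))
}

test_that("shape descriptors behave on analytic shapes", {
  disc <- measure_mask(disc_mask(20L))
  expect_gte(disc$circularity, 0.9)
  expect_lte(disc$circularity, 1.0)
  expect_gte(disc$aspect_ratio, 1.0)
  expect_lte(disc$aspect_ratio, 1.1)

  sq <- measure_mask(square_mask(20L))
  expect_lt(abs(sq$circularity - pi / 4), 0.08)
  expect_equal(sq$area_um2, 400 * 0.01)
})

test_that("capsule length recovers the generator ground truth", {
  out <- noiseless_fixture(seed = 41, n_mito = 6)
  cells <- segment_cells(out$image, default_params())
  mito <- segment_mitochondria(out$image, default_params(), cells)
  recs <- measure_objects(mito, out$image, cells)
  expect_equal(nrow(recs), nrow(out$truth$objects))
  tol <- out$image$pixel_size_um + out$spec$psf_sigma_um   # 1 px + psf
  expect_true(all(abs(sort(recs$length_um) -
                        sort(out$truth$objects$length_um)) <= tol))
  # cell assignment: everything belongs to the single cell
  expect_true(all(recs$cell_id == 1L))
  # feret of a capsule is also close to the end-to-end truth
  expect_true(all(abs(sort(recs$feret_um) -
                        sort(out$truth$objects$length_um)) <= 2 * tol))
})

test_that("length classes partition records with closed-mid boundaries", {
  r <- data.frame(object_id = 1:4, cell_id = 1L,
                  length_um = c(0.8, 1.0, 3.0, 3.2))
  cls <- classify_by_length(r)$records$length_class
  expect_equal(as.character(cls), c("short", "mid", "mid", "long"))
  expect_true(all(table(cls) == c(1, 2, 1)))  # exactly one class each

  r2 <- data.frame(object_id = 1:4, cell_id = 1L,
                   length_um = c(0.5, 2.0, 3.5, 4.0))
  cf <- classify_by_length(r2)$cell_fractions
  expect_equal(c(cf$frac_short, cf$frac_mid, cf$frac_long),
               c(0.25, 0.25, 0.50))
  expect_equal(cf$fission_score, 0.25)
  expect_equal(cf$fusion_score, 0.50)
  expect_equal(cf$n_short + cf$n_mid + cf$n_long, cf$n_mito)

  expect_error(classify_by_length(data.frame(object_id = 1, cell_id = 1,
                                             length_um = -1)), "negative")
})

test_that("per-cell summaries use medians and conserve total area", {
  one <- data.frame(object_id = 1L, cell_id = 3L, area_um2 = 2,
                    aspect_ratio = 1.5, length_um = 1.2, circularity = 0.8)
  s1 <- summarize_cell(one)
  expect_equal(s1$median_area_um2, 2)
  expect_equal(s1$median_length_um, 1.2)
  expect_equal(s1$n_mito, 1L)

  four <- data.frame(object_id = 1:4, cell_id = 1L,
                     area_um2 = c(1, 2, 3, 100),
                     aspect_ratio = c(1, 2, 3, 4),
                     length_um = c(1, 1, 1, 1),
                     circularity = c(0.5, 0.6, 0.7, 0.8))
  s4 <- summarize_cell(four)
  expect_equal(s4$median_area_um2, 2.5)         # robust to the outlier
  expect_equal(s4$total_area_um2, sum(four$area_um2))

  empty <- summarize_cell(four[0, ], cell_id = 9L)
  expect_equal(empty$n_mito, 0L)
  expect_true(is.na(empty$median_area_um2))

  expect_error(summarize_cell(data.frame(object_id = 1:2, cell_id = c(1, 2),
                                         area_um2 = 1, aspect_ratio = 1,
                                         length_um = 1, circularity = 1)),
               "multiple cells")
})

test_that("summarize_cells retains cells without mitochondria", {
  recs <- data.frame(object_id = 1:2, cell_id = c(1L, 1L),
                     area_um2 = c(1, 2), aspect_ratio = c(1, 1),
                     length_um = c(0.5, 2), circularity = c(1, 0.8))
  tab <- summarize_cells(recs, all_cell_ids = 1:3)
  expect_equal(tab$cell_id, 1:3)
  expect_equal(tab$n_mito, c(2L, 0L, 0L))
  expect_true(all(is.na(tab$median_length_um[2:3])))
})

test_that("length measurement is stable across resolution", {
  out <- noiseless_fixture(seed = 47, n_mito = 5)
  lab <- out$truth$mito_labels
  recs1 <- measure_objects(lab, out$image, out$truth$cell_labels)
  up <- kronecker(lab, matrix(1L, 2, 2))
  img2 <- calibrated_image(kronecker(out$image$intensities, matrix(1, 2, 2)),
                           out$image$pixel_size_um / 2)
  recs2 <- measure_objects(up, img2, kronecker(out$truth$cell_labels,
                                               matrix(1L, 2, 2)))
  expect_true(all(abs(sort(recs1$length_um) - sort(recs2$length_um)) <
                    out$image$pixel_size_um))
})

test_that("shifting the length mix towards fission raises the short fraction", {
  short_frac <- function(mix, seed) {
    out <- generate_mito_image(synthetic_image_spec(
      n_cells = 1, mito_per_cell = 8, length_mix = mix,
      noise_sd = 0, seed = seed))
    cells <- segment_cells(out$image, default_params())
    mito <- segment_mitochondria(out$image, default_params(), cells)
    recs <- measure_objects(mito, out$image, cells)
    mean(classify_by_length(recs)$records$length_class == "short")
  }
  seeds <- 1:40
  fused <- vapply(seeds, function(s) short_frac(c(0.1, 0.3, 0.6), s), numeric(1))
  fissioned <- vapply(seeds, function(s) short_frac(c(0.6, 0.3, 0.1), s + 500),
                      numeric(1))
  wins <- sum(fissioned > fused)
  # sign test: under no effect wins ~ Binomial(n, 1/2)
  p <- stats::binom.test(wins, length(seeds), alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("measured median length tracks the ground truth across cells", {
  out <- generate_mito_image(synthetic_image_spec(
    n_cells = 50, mito_per_cell = 6, image_size = c(1024, 1024),
    noise_sd = 0, seed = 53))
  cells <- segment_cells(out$image, default_params())
  mito <- segment_mitochondria(out$image, default_params(), cells)
  recs <- measure_objects(mito, out$image, cells)
  meas <- tapply(recs$length_um, recs$cell_id, stats::median)
  truth <- tapply(out$truth$objects$length_um, out$truth$objects$cell_id,
                  stats::median)
  # map segmented cell ids to truth cell ids by majority pixel overlap
  seg_ids <- as.integer(names(meas))
  truth_of <- vapply(seg_ids, function(id) {
    under <- out$truth$cell_labels[cells == id]
    under <- under[under > 0]
    as.integer(names(which.max(table(under))))
  }, integer(1))
  rho <- stats::cor(as.numeric(meas), as.numeric(truth[as.character(truth_of)]),
                    method = "spearman")
  expect_gt(rho, 0.9)
})
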