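# hand-drawn fixture: a 40-px-wide vertical axis with single-pixel hairs of
# known length sticking out horizontally
drawn_hair_mask <- function(hair_px = 60L, n_hairs = 3L, nr = 400L, nc = 400L) {
  m <- matrix(0L, nr, nc)
  m[20:380, 200:239] <- 1L
  rows <- seq(80, 320, length.out = n_hairs)
  for (r in round(rows)) m[r, 240:(239 + hair_px)] <- 1L
  m
}

test_that("a drawn hair of 60 px at 4800 dpi measures 0.3175 mm", {
  cal <- calibrate(4800)
  hm <- detect_hairs(drawn_hair_mask(60L), cal)
  expect_equal(hm$n_hairs, 3L)
  for (len in hm$hair_lengths_mm)
    expect_lt(abs(len - 60 * 25.4 / 4800),
              max(0.1 * 0.3175, 2 * cal$mm_per_px))
})

test_that("hair detection enforces resolution and axis preconditions", {
  cal_low <- calibrate(1200)
  expect_error(detect_hairs(drawn_hair_mask(), cal_low),
               "resolution insufficient")
  cal <- calibrate(4800)
  expect_error(detect_hairs(matrix(0L, 50, 50), cal), "empty mask")
  # a mask of only hair-thin structure has no axis
  thin <- matrix(0L, 100, 100); thin[50, 10:90] <- 1L
  expect_error(detect_hairs(thin, cal), "no axis")
})

test_that("hair count and density match generator truth", {
  hf <- hair_frame_fixture()
  born <- subset(truth_hair_events(hf$truth), birth_day <= 6)
  cal <- calibrate(4800)
  hm <- detect_hairs(hf$full, cal)
  expect_equal(hm$n_hairs, nrow(born))
  dens_truth <- nrow(born) / truth_total_length_mm(hf$truth, 6)
  expect_lt(abs(hm$density_per_mm - dens_truth) / dens_truth, 0.1)

  # hairless system: density 0 (hairs never rendered)
  frh <- render_frame(grow_root_system(
    rsa_params(frame_width_mm = 8, frame_height_mm = 8, horizon_days = 6,
               taproot_rate_mm_per_day = 0.8, lateral1_rate_mm_per_day = 0.6,
               taproot_diam_mm = c(0.45, 0.35), lateral1_diam_mm = c(0.3, 0.2),
               n_lateral1 = 1L, lateral2_density_per_mm = 0,
               root_lifespan_mean_days = Inf, hair_density_per_mm = 0,
               sow_xy_mm = c(4, 1)), seed = 11),
    6, render_config(dpi = 4800, seed = 3))
  hm0 <- detect_hairs(frh$mask, cal)
  expect_equal(hm0$n_hairs, 0L)
  expect_equal(hm0$density_per_mm, 0)
})

test_that("density is invariant to 90-degree rotation and monotone in the width filter", {
  full <- hair_frame_fixture()$full
  cal <- calibrate(4800)
  hm <- detect_hairs(full, cal)
  rot <- t(full)[ncol(full):1, , drop = FALSE]
  hm_rot <- detect_hairs(rot, cal)
  expect_equal(hm_rot$n_hairs, hm$n_hairs)
  expect_equal(hm_rot$density_per_mm, hm$density_per_mm, tolerance = 0.02)

  counts <- vapply(c(0.025, 0.04, 0.06),
                   function(w) detect_hairs(full, cal,
                                            hair_max_width_mm = w)$n_hairs,
                   integer(1))
  expect_true(all(diff(counts) >= 0L))
})

test_that("random hair subsampling clamps, repeats under seed, and is unbiased", {
  m <- structure(list(hair_lengths_mm = c(0.3, 0.5, 0.7),
                      n_hairs = 3L, axis_length_mm = 5,
                      density_per_mm = 0.6, mean_length_mm = 0.5),
                 class = "hair_measure")
  s <- sample_hair_lengths(m, k = 5, seed = 1)
  expect_equal(s$k_used, 3L)                       # clamp to population
  expect_setequal(s$sampled_lengths_mm, m$hair_lengths_mm)

  m12 <- structure(list(hair_lengths_mm = seq(0.2, 0.9, length.out = 12)),
                   class = "hair_measure")
  s1 <- sample_hair_lengths(m12, seed = 42)
  s2 <- sample_hair_lengths(m12, seed = 42)
  expect_identical(s1, s2)

  # the 5-hair sampled mean converges to the population mean across seeds
  means <- vapply(1:100, function(sd) sample_hair_lengths(m12, 5, sd)$sampled_mean_mm,
                  numeric(1))
  expect_lt(abs(mean(means) - mean(m12$hair_lengths_mm)) /
              mean(m12$hair_lengths_mm), 0.05)

  expect_error(sample_hair_lengths(structure(list(hair_lengths_mm = numeric(0)),
                                             class = "hair_measure")),
               "no hairs")
})
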