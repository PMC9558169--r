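ribbon_mask <- function(nr, nc, rows, cols) {
  m <- matrix(0L, nr, nc); m[rows, cols] <- 1L; m
}

test_that("skeletonization of simple shapes matches analytic expectations", {
  cal <- calibrate(1200)
  expect_equal(nrow(skeletonize_mask(matrix(0L, 20, 20), cal)$nodes), 0L)

  # 5-px-wide straight ribbon: single unbranched path, median radius 2.5 px
  m <- ribbon_mask(50, 480, 23:27, 4:476)
  g <- skeletonize_mask(m, cal, prune_len_mm = 0.5)
  deg <- rhizotrack:::node_degree(nrow(g$nodes), g$edges)
  expect_equal(sum(deg == 1L), 2L)          # exactly two endpoints
  expect_true(all(deg <= 2L))               # no branches after pruning
  expect_equal(unname(median(g$nodes$radius_px)), 2.5, tolerance = 0.5)
  expect_equal(max(g$component), 1L)
})

test_that("measured traits follow their defining formulas", {
  cal <- calibrate(1200)
  # empty graph: all traits zero, and the zero couplings hold
  t0 <- measure_traits(skeletonize_mask(matrix(0L, 10, 10), cal), cal,
                       frame_geometry(680))
  expect_equal(t0$RL_cm, 0); expect_equal(t0$AD_mm, 0)
  expect_equal(t0$RSA_cm2, 0); expect_equal(t0$RLD_cm_per_cm3, 0)

  # 473-px ribbon at 1200 dpi is 1.00 cm long
  m <- ribbon_mask(50, 480, 23:27, 4:476)
  tt <- measure_traits(skeletonize_mask(m, cal, 0.5), cal)
  expect_equal(tt$RL_cm, 473 * 25.4 / 1200 / 10, tolerance = 0.02)
  # 5 px wide = 5 * 25.4/1200 mm diameter
  expect_equal(tt$AD_mm, 5 * 25.4 / 1200, tolerance = 0.2)

  # RLD = RL / (A x DOF): 85 cm in 680 cm^2 at 0.25 cm depth = 0.5
  g <- skeletonize_mask(m, cal, 0.5)
  tt2 <- measure_traits(g, cal, frame_geometry(680, 0.25))
  expect_equal(tt2$RLD_cm_per_cm3, tt2$RL_cm / (680 * 0.25))
  expect_equal(85 / (680 * 0.25), 0.5)

  expect_error(frame_geometry(-1), "A must be")
  expect_error(frame_geometry(680, 0), "DOF")
})

test_that("root length is stable under rotation and dpi rescaling", {
  tr <- grow_root_system(desk_params(), seed = 42)
  cfg <- desk_render(7)
  fr <- render_frame(tr, 9, cfg)
  cal <- calibrate(cfg$dpi)
  rl <- function(m, cc = cal) measure_traits(skeletonize_mask(m, cc, 1), cc)$RL_cm

  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  a <- rl(fr$mask); b <- rl(rot90(fr$mask))
  expect_lt(abs(b - a) / a, 0.01)

  # 45-degree ribbon vs axis-aligned ribbon of equal length
  n <- 301
  diag_m <- matrix(0L, n, n)
  for (off in -2:2) {
    idx <- cbind(pmin(pmax(seq_len(n) + off, 1), n), seq_len(n))
    diag_m[idx] <- 1L
  }
  flat_m <- ribbon_mask(60, n, 28:32, seq_len(n))
  len_flat <- rl(flat_m)
  len_diag <- rl(diag_m) / sqrt(2)
  expect_lt(abs(len_diag - len_flat) / len_flat, 0.02)

  # doubling the rendering dpi changes RL by < 3%
  cfg2 <- render_config(dpi = 600, seed = 7)
  fr2 <- render_frame(tr, 9, cfg2)
  rl2 <- rl(fr2$mask, calibrate(600))
  expect_lt(abs(rl2 - a) / a, 0.03)
})

test_that("diameter recovery on constant-width ribbons is within 1 px", {
  cal <- calibrate(300)
  for (w in c(3, 7, 11)) {
    half <- (w - 1) / 2
    m <- ribbon_mask(60, 300, (30 - half):(30 + half), 10:290)
    tt <- measure_traits(skeletonize_mask(m, cal, 1), cal)
    expect_lt(abs(tt$AD_mm - w * cal$mm_per_px),
              max(0.1 * w * cal$mm_per_px, cal$mm_per_px))
  }
})

test_that("RLD scales inversely with depth of soil", {
  cal <- calibrate(300)
  m <- ribbon_mask(60, 300, 28:32, 10:290)
  g <- skeletonize_mask(m, cal, 1)
  full <- measure_traits(g, cal, frame_geometry(100, 0.25))$RLD_cm_per_cm3
  half <- measure_traits(g, cal, frame_geometry(100, 0.125))$RLD_cm_per_cm3
  expect_equal(half, 2 * full)
})

test_that("trait series tracks the day axis and grows monotonically", {
  tr <- grow_root_system(desk_params(n_lateral1 = 4L,
                                     root_lifespan_mean_days = Inf),
                         seed = 6)
  gs <- generate_series(tr, seq(2, 10, by = 2), desk_render(3))
  ts <- traits_for_series(gs$series, gs$masks, prune_len_mm = 1)
  expect_equal(nrow(ts), 5L)
  expect_equal(ts$day, seq(2, 10, by = 2))
  expect_true(all(diff(ts$RL_cm) >= 0))      # no senescence: growth only
  expect_true(all(ts$RLD_cm_per_cm3 >= 0))

  # all-empty masks give all-zero traits
  empty <- lapply(gs$masks, function(m) m * 0L)
  ts0 <- traits_for_series(gs$series, empty)
  expect_true(all(ts0$RL_cm == 0))
  expect_true(all(ts0$AD_mm == 0))

  expect_error(traits_for_series(gs$series, gs$masks[1:3]),
               "do not match|one mask per")
})
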