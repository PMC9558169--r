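test_that("grow_root_system echoes parameters and is deterministic", {
  p <- desk_params(n_lateral1 = 10L)
  tr <- grow_root_system(p, seed = 4)
  ord <- vapply(tr$roots, `[[`, character(1), "order")
  expect_equal(sum(ord == "lateral1"), 10L)
  expect_equal(sum(ord == "taproot"), 1L)

  tr2 <- grow_root_system(p, seed = 4)
  expect_identical(tr, tr2)
  tr3 <- grow_root_system(p, seed = 5)
  expect_false(identical(tr, tr3))

  expect_error(rsa_params(horizon_days = 0), "horizon")
  expect_error(rsa_params(taproot_rate_mm_per_day = -1), "rates")
})

test_that("truth length follows the closed-form rate x time law", {
  # taproot only, 5 mm/day, emerging at sowing: after the 10th observed day
  # it has grown 10 days' worth of length
  p <- rsa_params(frame_width_mm = 40, frame_height_mm = 80,
                  horizon_days = 9, taproot_rate_mm_per_day = 5,
                  n_lateral1 = 0L, lateral2_density_per_mm = 0,
                  root_lifespan_mean_days = Inf, hair_density_per_mm = 0,
                  sow_xy_mm = c(20, 5))
  tr <- grow_root_system(p, seed = 1)
  expect_equal(truth_total_length_mm(tr, 9), 50)
  expect_equal(truth_total_length_mm(tr, 0), 5)   # one day's growth when visible
  # length never decreases and is capped at the planned total
  lens <- vapply(0:9, truth_total_length_mm, numeric(1), truth = tr)
  expect_true(all(diff(lens) >= 0))
  expect_equal(max(lens), tr$roots[["R1"]]$total_len_mm)
})

test_that("per-root diameters taper monotonically tip-ward", {
  tr <- grow_root_system(desk_params(), seed = 11)
  for (r in tr$roots) {
    expect_gte(r$diam_base_mm, r$diam_tip_mm)
    s <- seq(0, r$total_len_mm, length.out = 7)
    d <- vapply(s, rhizotrack:::root_diam_at, numeric(1), root = r)
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("rendered frames honour emergence days and are deterministic", {
  tr <- grow_root_system(desk_params(n_lateral1 = 3L), seed = 8)
  cfg <- desk_render(21)

  # day before any emergence: empty mask (shift all emergences later)
  tr0 <- tr
  for (n in names(tr0$roots)) tr0$roots[[n]]$emergence_day <- 5
  fr0 <- render_frame(tr0, 2, cfg)
  expect_equal(sum(fr0$mask), 0)

  expect_error(render_frame(tr, -1, cfg), "sowing")

  fr <- render_frame(tr, 8, cfg)
  fr2 <- render_frame(tr, 8, cfg)
  expect_identical(fr$image, fr2$image)
  expect_identical(fr$mask, fr2$mask)

  # senescent roots stay in the mask but flip palette ordering:
  # live pixels brighter than senescent pixels brighter than soil mean
  g <- (fr$image[, , 1] + fr$image[, , 2] + fr$image[, , 3]) / 3
  sen <- fr$mask == 1L & fr$live == 0L
  if (sum(sen) > 50 && sum(fr$live) > 50) {
    expect_gt(median(g[fr$live == 1L]), median(g[sen]))
    expect_gt(median(g[sen]), median(g[fr$mask == 0L]))
  }
})

test_that("rendered skeleton length matches analytic truth within 5%", {
  tr <- grow_root_system(desk_params(), seed = 13)
  cfg <- desk_render(31)
  cal <- calibrate(cfg$dpi)
  for (d in c(6, 10)) {
    fr <- render_frame(tr, d, cfg)
    g <- skeletonize_mask(fr$mask, cal, prune_len_mm = 1)
    rl_cm <- measure_traits(g, cal)$RL_cm
    truth_cm <- truth_total_length_mm(tr, d) / 10
    expect_lt(abs(rl_cm - truth_cm) / truth_cm, 0.05)
  }
})

test_that("generate_series produces aligned frames and truth tables", {
  tr <- grow_root_system(desk_params(n_lateral1 = 3L,
                                     root_lifespan_mean_days = Inf),
                         seed = 2)
  gs <- generate_series(tr, 1:5, desk_render(9))
  expect_equal(length(gs$series$records), 5L)
  expect_equal(gs$series$days, 1:5)
  expect_equal(gs$truth_rl$day, 1:5)
  # growth only (no senescence): truth RL non-decreasing
  expect_true(all(diff(gs$truth_rl$RL_mm) >= 0))
  # one event row per root
  expect_equal(nrow(gs$root_events), length(tr$roots))
  expect_error(generate_series(tr, c(3, 2, 1), desk_render(9)), "increasing")
})

test_that("series written to disk reload identically through the catalog", {
  dir <- withr::local_tempdir()
  tr <- grow_root_system(desk_params(n_lateral1 = 2L), seed = 3)
  gs <- generate_series(tr, c(2, 4), desk_render(5), dir = dir, pot_id = 7)
  s <- load_series(dir, frame_width_cm = 3, frame_height_cm = 4.5)
  expect_equal(s$pot_id, 7L)
  expect_equal(s$days, c(2L, 4L))
  px <- read_frame(s$records[[1]])
  expect_equal(dim(px), dim(gs$series$records[[1]]$pixels))
  expect_equal(max(abs(px - gs$series$records[[1]]$pixels)), 0,
               tolerance = 1 / 255)   # 8-bit PNG quantization
  # truth masks round trip exactly
  m <- read_mask(file.path(dir, "masks", "pot07_d002_300dpi.png"))
  expect_identical(m, gs$masks[["2"]])
})
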