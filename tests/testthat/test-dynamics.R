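test_that("net growth rate of RLD divides by the true day gap", {
  ts <- data.frame(day = c(10, 11), RLD_cm_per_cm3 = c(0.5, 0.5))
  expect_equal(rld_ngr(ts)$RLD_NGR_cm_per_cm3_day, c(NA, 0))

  ts2 <- data.frame(day = c(10, 12), RLD_cm_per_cm3 = c(0.50, 0.56))
  out <- rld_ngr(ts2)
  expect_equal(out$d[2], 2)
  expect_equal(out$RLD_NGR_cm_per_cm3_day[2], 0.03)

  # declining RLD gives negative net growth (net senescence)
  ts3 <- data.frame(day = 1:3, RLD_cm_per_cm3 = c(0.4, 0.3, 0.25))
  expect_true(all(rld_ngr(ts3)$RLD_NGR_cm_per_cm3_day[-1] < 0))

  expect_error(rld_ngr(ts2[1, ]), "at least 2")
  expect_error(rld_ngr(data.frame(day = c(3, 3),
                                  RLD_cm_per_cm3 = c(1, 2))), "duplicate")
})

test_that("NGR telescopes to the net RLD change and shifts with the day axis", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    days <- sort(sample(1:40, n))
    rld <- cumsum(rnorm(n, 0.02, 0.05))
    ts <- data.frame(day = days, RLD_cm_per_cm3 = rld)
    out <- rld_ngr(ts)
    expect_equal(sum(out$RLD_NGR_cm_per_cm3_day[-1] * out$d[-1]),
                 rld[n] - rld[1], tolerance = 1e-12)
    # uniform day shift leaves the rates unchanged
    ts_shift <- transform(ts, day = day + 7)
    expect_equal(rld_ngr(ts_shift)$RLD_NGR_cm_per_cm3_day,
                 out$RLD_NGR_cm_per_cm3_day)
  }
})

test_that("growth_rate forms finite differences with gap handling", {
  trk <- data.frame(day = c(1, 2), length_cm = c(1, 3), diameter_mm = c(1, 1))
  gr <- growth_rate(trk)
  expect_equal(gr$length_rate_cm_day, 2)
  expect_equal(gr$diameter_rate_mm_day, 0)

  trk2 <- data.frame(day = c(1, 3), length_cm = c(1, 2), diameter_mm = c(1, 2))
  gr2 <- growth_rate(trk2)
  expect_equal(gr2$d, 2)
  expect_equal(gr2$length_rate_cm_day, 0.5)

  expect_error(growth_rate(trk[1, ]), "at least 2")
})

test_that("tracking a single root recovers its elongation rate", {
  p <- rsa_params(frame_width_mm = 20, frame_height_mm = 45,
                  horizon_days = 10, taproot_rate_mm_per_day = 3,
                  n_lateral1 = 0L, lateral2_density_per_mm = 0,
                  taproot_diam_mm = c(0.8, 0.5),
                  root_lifespan_mean_days = Inf, hair_density_per_mm = 0,
                  sow_xy_mm = c(10, 4))
  tr <- grow_root_system(p, seed = 3)
  gs <- generate_series(tr, 1:10, desk_render(77))
  nr <- nrow(gs$masks[[1]]); nc <- ncol(gs$masks[[1]])
  seedreg <- matrix(0L, nr, nc); seedreg[30:70, 100:140] <- 1L

  trk <- track_root(gs$series, gs$masks, seedreg)
  expect_false(attr(trk, "truncated"))
  expect_equal(trk$day, 1:10)
  rates <- growth_rate(trk)$length_rate_cm_day
  expect_true(all(abs(rates - 0.3) / 0.3 < 0.1))

  # determinism
  trk2 <- track_root(gs$series, gs$masks, seedreg)
  expect_identical(as.data.frame(trk), as.data.frame(trk2))

  # an empty seed region errors
  expect_error(track_root(gs$series, gs$masks, seedreg * 0L), "no root pixels")

  # a root that vanishes truncates and flags the track
  masks_cut <- gs$masks
  for (k in 7:10) masks_cut[[k]] <- masks_cut[[k]] * 0L
  trk3 <- track_root(gs$series, masks_cut, seedreg)
  expect_true(attr(trk3, "truncated"))
  expect_equal(max(trk3$day), 6)
})
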