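test_that("series registration recovers constructed translations", {
  tr <- grow_root_system(desk_params(n_lateral1 = 4L,
                                     root_lifespan_mean_days = Inf),
                         seed = 2)
  f1 <- render_frame(tr, 6, desk_render(9))$image
  shift_img <- function(img, dr, dc) {
    out <- img
    for (ch in 1:3)
      out[, , ch] <- rhizotrack:::shift_matrix(round(img[, , ch] * 1e4),
                                               dr, dc) / 1e4
    out
  }
  f2 <- shift_img(f1, 3, -2)
  f3 <- shift_img(f1, -5, 4)
  offs <- align_series(list(f1, f2, f3))
  expect_equal(offs$dr, c(0L, 3L, -5L))
  expect_equal(offs$dc, c(0L, -2L, 4L))

  # identical frames: zero offsets; reversed series negates them
  expect_true(all(align_series(list(f1, f1, f1))$dr == 0L))
  offs_rev <- align_series(list(f2, f1))
  expect_equal(offs_rev$dr[2], -offs$dr[2])
  expect_equal(offs_rev$dc[2], -offs$dc[2])

  # uncorrelated noise falls below the confidence floor: zero with warning
  set.seed(1)
  n1 <- array(runif(50 * 50 * 3), c(50, 50, 3))
  n2 <- array(runif(50 * 50 * 3), c(50, 50, 3))
  expect_warning(o <- align_series(list(n1, n2), min_corr = 0.9), "confidence")
  expect_equal(o$dr[2], 0L)
})

test_that("root status is judged by median brightness with a live boundary", {
  img <- array(0.9, c(10, 10, 3))
  roi <- matrix(1L, 10, 10)
  expect_equal(classify_status(img, roi), "live")
  expect_equal(classify_status(img * 0.3, roi), "senescent")
  # the boundary value counts as live
  expect_equal(classify_status(array(0.6, c(5, 5, 3)), matrix(1L, 5, 5)), "live")
  expect_error(classify_status(img, roi * 0L), "empty ROI")
})

test_that("hair tortuosity separates straight from curled paths", {
  straight <- cbind(seq(0, 1, length.out = 20), 0)
  hs <- hair_status(straight)
  expect_equal(hs$status, "intact")
  expect_equal(hs$tortuosity, 1, tolerance = 1e-9)

  th <- seq(0, pi, length.out = 100)
  semi <- cbind(cos(th), sin(th))
  hs2 <- hair_status(semi)
  expect_equal(hs2$tortuosity, pi / 2, tolerance = 1e-3)
  expect_equal(hs2$status, "distorted")              # pi/2 > 1.5
  expect_equal(hair_status(semi, threshold = 2)$status, "intact")

  expect_error(hair_status(semi[1:2, ]), "degenerate")
})

test_that("events recover truth emergence and senescence on synthetic series", {
  cal <- calibrate(300)
  tr <- grow_root_system(desk_params(lateral2_rate = 1), seed = 21)
  gs <- generate_series(tr, 1:12, desk_render(1021))
  nr <- nrow(gs$masks[[1]]); nc <- ncol(gs$masks[[1]])
  rois <- truth_rois(tr, nr, nc, cal)
  ev <- extract_events(gs$series, gs$masks, rois, min_area_px = 15)
  tev <- truth_events(tr)
  tev <- tev[match(ev$subject_id, tev$subject_id), ]

  expect_true(all(ev$emergence_day == tev$emergence_day))
  ok_end <- (ev$censored & tev$censored) |
    (!ev$censored & !tev$censored & abs(ev$end_day - tev$end_day) <= 1)
  expect_true(mean(ok_end) >= 0.8)
  # censored subjects end at the last observed day
  expect_true(all(ev$end_day[ev$censored] == 12))
  expect_true(all(is.na(ev$lifespan_days[ev$censored])))

  # determinism
  ev2 <- extract_events(gs$series, gs$masks, rois, min_area_px = 15)
  expect_identical(ev, ev2)

  # never-populated ROI is dropped with a warning
  far <- matrix(0L, nr, nc); far[1:6, 1:6] <- 1L
  expect_warning(
    ev3 <- extract_events(gs$series, gs$masks, c(rois, list(ghost = far)),
                          min_area_px = 15),
    "never populated")
  expect_false("ghost" %in% ev3$subject_id)
})

test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  # deaths at 5, 10, 15 without censoring
  km <- kaplan_meier(data.frame(time = c(5, 10, 15), event = TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km_median(km), 10)

  # deaths at 4 and 8 with one subject censored at 6
  km2 <- kaplan_meier(data.frame(time = c(4, 8, 6),
                                 event = c(TRUE, TRUE, FALSE)))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_equal(km_median(km2), 8)

  # everyone dies on the same day
  km3 <- kaplan_meier(data.frame(time = rep(7, 9), event = TRUE))
  expect_equal(km3$survival, 0)
  expect_equal(km_median(km3), 7)

  # event-table input (emergence/end/censored) is equivalent
  km4 <- kaplan_meier(data.frame(emergence_day = c(5, 5, 5),
                                 end_day = c(10, 15, 20),
                                 censored = c(FALSE, FALSE, TRUE)))
  expect_equal(km4$time, c(5, 10))

  expect_error(kaplan_meier(data.frame(time = numeric(0), event = logical(0))),
               "no events")
  expect_error(kaplan_meier(data.frame(time = c(0, 0),
                                       event = c(FALSE, FALSE))),
               "censored at day 0")
})

test_that("product-limit estimate equals the independent reference on small samples", {
  skip_if_not_installed("survival")
  set.seed(99)
  for (i in 1:300) {
    n <- sample(1:5, 1)
    t <- sample(1:6, n, replace = TRUE)
    e <- runif(n) < 0.7
    if (!any(e)) next
    km <- kaplan_meier(data.frame(time = t, event = e))
    ref <- summary(survival::survfit(survival::Surv(t, e) ~ 1),
                   times = km$time)$surv
    expect_equal(km$survival, ref, tolerance = 1e-12)
    # with no censoring the curve is the empirical survivor fraction
    km_all <- kaplan_meier(data.frame(time = t, event = TRUE))
    emp <- vapply(km_all$time, function(tt) mean(t > tt), numeric(1))
    expect_equal(km_all$survival, emp, tolerance = 1e-12)
  }
})

test_that("uncensored KM median equals the order-statistic median rule", {
  set.seed(7)
  for (i in 1:50) {
    t <- sample(1:30, sample(2:40, 1), replace = TRUE)
    km <- kaplan_meier(data.frame(time = t, event = TRUE))
    # smallest event time with S(t) <= 0.5, computed by brute force
    tt <- sort(unique(t))
    s <- vapply(tt, function(x) mean(t > x), numeric(1))
    expect_equal(km_median(km), tt[which(s <= 0.5)[1]])
  }
})

test_that("group comparison reports median differences and a valid log-rank test", {
  a <- data.frame(time = c(10, 20, 30, 40), event = TRUE)
  g0 <- compare_groups(a, a)
  expect_equal(g0$median_diff, 0)
  expect_equal(g0$chisq, 0)

  b <- transform(a, time = time + 10)
  g1 <- compare_groups(a, b)
  expect_equal(g1$median_diff, 10)

  skip_if_not_installed("survival")
  set.seed(4)
  ta <- rexp(60, 1 / 20); tb <- rexp(60, 1 / 40)
  g2 <- compare_groups(data.frame(time = ta, event = TRUE),
                       data.frame(time = tb, event = TRUE))
  ref <- survival::survdiff(survival::Surv(c(ta, tb)) ~ rep(1:2, each = 60))
  expect_equal(g2$chisq, ref$chisq, tolerance = 1e-9)
  expect_lt(g2$p_value, 0.05)

  expect_error(compare_groups(a, data.frame(time = c(3, 4),
                                            event = c(TRUE, FALSE))),
               "at least 2 uncensored")
})

test_that("simulated exponential lifespans recover the theoretical median", {
  # the KM median of n = 300 exponential lifespans has a sampling sd of
  # about 8% of m*ln2, so average the medians of replicate samples
  set.seed(123)
  m <- 20
  meds <- vapply(1:10, function(i)
    km_median(kaplan_meier(data.frame(time = rexp(300, 1 / m),
                                      event = TRUE))),
    numeric(1))
  expect_lt(abs(mean(meds) - m * log(2)) / (m * log(2)), 0.1)
})
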