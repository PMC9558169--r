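# Shared desk-scale study conditions and lazily cached fixtures.
#
# Morphology fixture: a 30 x 45 mm scanned window rendered at 300 dpi over a
# 12-day horizon, with the field-scale growth model scaled to desk size
# (taproot 3 mm/day, six first-order laterals at 2 mm/day, exponential root
# lifespans of mean 6 days so that emergence, senescence and censoring all
# occur inside the horizon).
#
# Hair fixture: an 8 x 8 mm window at 4800 dpi, one lateral bearing hairs at
# 3 per mm over a 6-day horizon.

desk_params <- function(n_lateral1 = 6L, horizon_days = 12,
                        root_lifespan_mean_days = 6,
                        lateral2_rate = 1, hair_density = 0) {
  rsa_params(
    frame_width_mm = 30, frame_height_mm = 45, horizon_days = horizon_days,
    taproot_rate_mm_per_day = 3, lateral1_rate_mm_per_day = 2,
    lateral2_rate_mm_per_day = lateral2_rate,
    taproot_diam_mm = c(1.0, 0.5), lateral1_diam_mm = c(0.5, 0.3),
    lateral2_diam_mm = c(0.3, 0.2), n_lateral1 = n_lateral1,
    root_lifespan_mean_days = root_lifespan_mean_days,
    hair_density_per_mm = hair_density, sow_xy_mm = c(15, 4))
}

desk_render <- function(seed) render_config(dpi = 300, seed = seed)

hair_params <- function(hair_lifespan_mean_days = Inf) {
  rsa_params(
    frame_width_mm = 8, frame_height_mm = 8, horizon_days = 6,
    taproot_rate_mm_per_day = 0.8, lateral1_rate_mm_per_day = 0.6,
    taproot_diam_mm = c(0.45, 0.35), lateral1_diam_mm = c(0.3, 0.2),
    n_lateral1 = 1L, lateral2_density_per_mm = 0,
    root_lifespan_mean_days = Inf, hair_density_per_mm = 3,
    hair_lifespan_mean_days = hair_lifespan_mean_days, sow_xy_mm = c(4, 1))
}

# circular ROI of radius `radius_mm` centred `at_mm` along a root's polyline
lateral_roi <- function(root, nr, nc, cal, at_mm = 1.6, radius_mm = 0.7) {
  at <- rhizotrack:::polyline_at(root$polyline, root$cumlen, at_mm)
  rr <- round(at$point[2] / cal$mm_per_px)
  cc <- round(at$point[1] / cal$mm_per_px)
  roi <- matrix(0L, nr, nc)
  rad <- round(radius_mm / cal$mm_per_px)
  rs <- max(1, rr - rad):min(nr, rr + rad)
  cs <- max(1, cc - rad):min(nc, cc + rad)
  roi[rs, cs][outer((rs - rr)^2, (cs - cc)^2, `+`) <= rad^2] <- 1L
  roi
}

truth_rois <- function(truth, nr, nc, cal, order = "lateral1") {
  lats <- Filter(function(r) r$order == order, truth$roots)
  rois <- lapply(lats, lateral_roi, nr = nr, nc = nc, cal = cal)
  names(rois) <- names(lats)
  rois
}

# fixtures built once per test run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 20 training + 10 held-out frames from independent desk-scale scenes
seg_frames_fixture <- function() {
  fixture("seg_frames", function() {
    gen <- function(seeds, days) {
      frames <- list(); masks <- list(); k <- 0L
      for (s in seeds) {
        tr <- grow_root_system(desk_params(), seed = s)
        cfg <- desk_render(100 + s)
        for (d in days) {
          k <- k + 1L
          fr <- render_frame(tr, d, cfg)
          frames[[k]] <- fr$image
          masks[[k]] <- fr$mask
        }
      }
      list(frames = frames, masks = masks)
    }
    list(train = gen(1:10, c(6, 11)), holdout = gen(11:15, c(7, 12)))
  })
}

hair_frame_fixture <- function() {
  fixture("hair_frame", function() {
    tr <- grow_root_system(hair_params(), seed = 11)
    fr <- render_frame(tr, 6, render_config(dpi = 4800, seed = 3))
    list(truth = tr, frame = fr, full = (fr$mask | fr$hair_mask) + 0L)
  })
}

trained_model_fixture <- function() {
  fixture("trained_model", function() {
    sf <- seg_frames_fixture()
    train_seg_model(sf$train$frames, sf$train$masks,
                    seg_model_config(seed = 7))
  })
}
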