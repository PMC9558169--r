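#' @title Synthetic rhizotron image series with exact ground truth
#' @name synthetic_rhizo
#' @description
#' A seeded generator that grows a schematic root system (taproot, first- and
#' second-order laterals, root hairs) as piecewise-linear polylines in the
#' frame plane, assigns every root an emergence day, an elongation rate and an
#' exponentially distributed lifespan, and renders scanner-like frames: dark
#' speckled soil, bright live roots, darker smooth senescent roots, and fine
#' hairs that only resolve at hair-grade resolution. Because geometry and
#' timing are known exactly, total root length, diameters, hair counts and
#' lifespan events all have closed-form truth values, which the test suite
#' uses as oracles for segmentation, trait extraction, dynamics and survival
#' analysis.
NULL

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters of the synthetic root system
#'
#' Defaults describe a cotton-like taproot system in a 20 x 34 cm rhizotron
#' frame observed daily over 110 days: a fast taproot (20 mm/day), about a
#' dozen first-order laterals at 4 mm/day emerging behind the advancing tip,
#' sparser second-order laterals, root lifespans drawn from an exponential
#' distribution with mean 35 days, and hairs at ~3 per mm of lateral axis with
#' lengths of 0.2-0.9 mm and a mean lifespan of 25 days. Tests use the same
#' model at smaller frame sizes and horizons.
#'
#' @param frame_width_mm,frame_height_mm frame size in mm.
#' @param horizon_days last observed day after sowing.
#' @param taproot_rate_mm_per_day,lateral1_rate_mm_per_day,lateral2_rate_mm_per_day
#'   elongation rates.
#' @param taproot_diam_mm,lateral1_diam_mm,lateral2_diam_mm length-2 vectors
#'   (base, tip) of the linear diameter taper; tip never exceeds base.
#' @param n_lateral1 number of first-order laterals (exact).
#' @param lateral2_density_per_mm expected second-order laterals per mm of
#'   first-order axis (Poisson).
#' @param branch_angle_deg mean branching angle off the parent axis.
#' @param heading_jitter_deg per-step direction jitter (sd, degrees).
#' @param step_mm polyline step length.
#' @param root_lifespan_mean_days mean of the exponential root lifespan;
#'   `Inf` disables senescence.
#' @param hair_density_per_mm hairs per mm of lateral axis (Poisson).
#' @param hair_len_range_mm hair length band (uniform).
#' @param hair_width_mm rendered hair width.
#' @param hair_lifespan_mean_days mean of the exponential hair lifespan
#'   (days from appearance to distortion); `Inf` disables distortion.
#' @param min_clearance_mm roots steer to keep their centrelines at least
#'   this far from previously grown roots (beyond their shared junction), so
#'   the rendered system stays essentially occlusion-free and the
#'   closed-form truth length remains a faithful oracle for the mask.
#' @param emergence_lag_days days between the parent tip passing a branch
#'   point and the branch (or hair) becoming visible.
#' @param sow_xy_mm sowing position (x from left, y from top), mm.
#' @return a list of class `rsa_params`.
#' @export
rsa_params <- function(frame_width_mm = 200, frame_height_mm = 340,
                       horizon_days = 110,
                       taproot_rate_mm_per_day = 20,
                       lateral1_rate_mm_per_day = 4,
                       lateral2_rate_mm_per_day = 1.5,
                       taproot_diam_mm = c(1.2, 0.5),
                       lateral1_diam_mm = c(0.5, 0.28),
                       lateral2_diam_mm = c(0.3, 0.18),
                       n_lateral1 = 12,
                       lateral2_density_per_mm = 0.03,
                       branch_angle_deg = 55,
                       heading_jitter_deg = 7,
                       step_mm = 1.5,
                       root_lifespan_mean_days = 35,
                       hair_density_per_mm = 3,
                       hair_len_range_mm = c(0.2, 0.9),
                       hair_width_mm = 0.02,
                       hair_lifespan_mean_days = 25,
                       min_clearance_mm = 1.0,
                       emergence_lag_days = 1,
                       sow_xy_mm = c(frame_width_mm / 2, 10)) {
  p <- as.list(environment())
  if (p$horizon_days <= 0) stop("horizon_days must be > 0")
  rates <- c(p$taproot_rate_mm_per_day, p$lateral1_rate_mm_per_day,
             p$lateral2_rate_mm_per_day)
  if (any(rates <= 0)) stop("elongation rates must be > 0")
  for (d in list(p$taproot_diam_mm, p$lateral1_diam_mm, p$lateral2_diam_mm))
    if (length(d) != 2L || any(d <= 0) || d[2] > d[1])
      stop("diameter taper must be (base, tip) with 0 < tip <= base")
  structure(p, class = "rsa_params")
}

# polyline of given total length starting at `start` (x, y mm) with initial
# heading (radians; y grows downward), jittered per step, relaxing toward
# vertical (gravitropism) and steered back when approaching the frame
# margin. The downward pull keeps neighbouring roots roughly parallel, so
# the rendered system stays essentially occlusion-free and the closed-form
# truth length remains a faithful oracle for the mask.
make_polyline <- function(start, heading, total_len, step_mm, jitter_sd,
                          frame_mm, margin_mm, gravitropism = 0.03,
                          avoid = NULL, clear_mm = 1.0, free_mm = 2.5) {
  n <- max(1L, ceiling(total_len / step_mm))
  pts <- matrix(NA_real_, n + 1L, 2L)
  pts[1L, ] <- start
  h <- heading
  remaining <- total_len
  centre <- frame_mm / 2
  travelled <- 0
  for (i in seq_len(n)) {
    len_i <- min(step_mm, remaining)
    remaining <- remaining - len_i
    h <- h + rnorm(1L, 0, jitter_sd) +
      gravitropism * (((pi / 2 - h + pi) %% (2 * pi)) - pi)
    p <- pts[i, ]
    for (try in 1:36) {
      q <- p + len_i * c(cos(h), sin(h))
      inside <- q[1] >= margin_mm && q[1] <= frame_mm[1] - margin_mm &&
                q[2] >= margin_mm && q[2] <= frame_mm[2] - margin_mm
      blocked <- FALSE
      if (!inside) {
        # rotate toward the frame centre in 15 degree increments
        to_centre <- atan2(centre[2] - p[2], centre[1] - p[1])
        dh <- ((to_centre - h + pi) %% (2 * pi)) - pi
        h <- h + sign(dh + 1e-9) * (15 * pi / 180)
        next
      }
      if (!is.null(avoid) && travelled + len_i > free_mm) {
        d2 <- (avoid[, 1] - q[1])^2 + (avoid[, 2] - q[2])^2
        k <- which.min(d2)
        blocked <- d2[k] < clear_mm^2
        if (blocked) {
          # rotate away from the nearest already-grown root
          to_obs <- atan2(avoid[k, 2] - p[2], avoid[k, 1] - p[1])
          dh <- ((to_obs - h + pi) %% (2 * pi)) - pi
          h <- h - sign(dh + 1e-9) * (15 * pi / 180)
          next
        }
      }
      break
    }
    pts[i + 1L, ] <- q
    travelled <- travelled + len_i
  }
  pts
}

# resample a polyline at roughly `by_mm` spacing (for the occupancy map)
polyline_points <- function(pts, by_mm = 0.5) {
  cum <- polyline_cumlen(pts)
  ss <- seq(0, cum[length(cum)], by = by_mm)
  t(vapply(ss, function(s) polyline_at(pts, cum, s)$point, numeric(2)))
}

polyline_cumlen <- function(pts) {
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# point and tangent angle at arc position s on a polyline
polyline_at <- function(pts, cum, s) {
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  f <- if (cum[i + 1L] > cum[i]) (s - cum[i]) / (cum[i + 1L] - cum[i]) else 0
  p <- pts[i, ] + f * (pts[i + 1L, ] - pts[i, ])
  list(point = p, angle = atan2(pts[i + 1L, 2] - pts[i, 2],
                                pts[i + 1L, 1] - pts[i, 1]))
}

# day on which a root's visible length first reaches arc position s;
# a root emerged on day e has length rate*(t - e + 1) on day t >= e
day_reaching <- function(root, s) root$emergence_day - 1 + s / root$rate_mm_per_day

# local diameter from the linear base-to-tip taper at arc position s
root_diam_at <- function(root, s) {
  root$diam_base_mm - (root$diam_base_mm - root$diam_tip_mm) *
    min(max(s / root$total_len_mm, 0), 1)
}

root_len_at <- function(root, day) {
  if (day < root$emergence_day) return(0)
  t_end <- if (is.na(root$senescence_day)) day else min(day, root$senescence_day)
  min(root$rate_mm_per_day * (t_end - root$emergence_day + 1), root$total_len_mm)
}

#' Grow a synthetic root system
#'
#' Deterministic given `seed`. The taproot emerges at the sowing point on day
#' 0 heading downward; exactly `n_lateral1` first-order laterals branch off at
#' uniformly drawn positions along it, becoming visible once the taproot tip
#' has passed their branch point; second-order laterals arise as a Poisson
#' process along each first-order lateral. Every root carries a per-point
#' diameter taper, an elongation rate, an exponential lifespan (possibly
#' censored at the horizon) and, on laterals, a Poisson set of hairs with
#' uniform lengths and exponential lifespans.
#'
#' @param params an [rsa_params()] list.
#' @param seed integer seed fixing all randomness.
#' @return a `root_system_truth`: list of per-root truth records plus the
#'   parameters; see [truth_total_length_mm()], [truth_events()],
#'   [truth_hair_events()].
#' @export
grow_root_system <- function(params = rsa_params(), seed = 1L) {
  stopifnot(inherits(params, "rsa_params"))
  with_seed(seed, {
    frame_mm <- c(params$frame_width_mm, params$frame_height_mm)
    jit <- params$heading_jitter_deg * pi / 180
    horizon <- params$horizon_days
    roots <- list()

    lifespan_draw <- function() {
      if (is.infinite(params$root_lifespan_mean_days)) return(NA_real_)
      round(rexp(1L, 1 / params$root_lifespan_mean_days)) + 1
    }

    occupied <- NULL   # points of already-grown roots; new roots steer clear

    new_root <- function(root_id, order, parent_id, attach_s, start, heading,
                         rate, diam, emergence_day) {
      if (emergence_day > horizon) return(NULL)
      # the exponential lifespan model applies to lateral roots; the taproot
      # persists through the experiment (it is never a survival subject)
      life <- if (order == "taproot") NA_real_ else lifespan_draw()
      senescence <- if (is.na(life) || emergence_day + life > horizon)
        NA_real_ else emergence_day + life
      end_day <- if (is.na(senescence)) horizon else senescence
      total_len <- rate * (end_day - emergence_day + 1)
      pts <- make_polyline(start, heading, total_len, params$step_mm, jit,
                           frame_mm, margin_mm = 2 * diam[1],
                           avoid = occupied,
                           clear_mm = params$min_clearance_mm)
      occupied <<- rbind(occupied, polyline_points(pts))
      cum <- polyline_cumlen(pts)
      list(root_id = root_id, order = order, parent_id = parent_id,
           attach_s = attach_s, polyline = pts, cumlen = cum,
           total_len_mm = cum[length(cum)],
           diam_base_mm = diam[1], diam_tip_mm = diam[2],
           rate_mm_per_day = rate,
           emergence_day = emergence_day, senescence_day = senescence,
           hairs = NULL)
    }

    tap <- new_root("R1", "taproot", NA_character_, NA_real_,
                    params$sow_xy_mm, pi / 2 + rnorm(1L, 0, jit),
                    params$taproot_rate_mm_per_day, params$taproot_diam_mm,
                    emergence_day = 0)
    roots[[tap$root_id]] <- tap

    # first-order laterals at uniform positions along the taproot
    n1 <- params$n_lateral1
    if (n1 > 0) {
      # regularly spaced branch points with mild jitter: lateral initiation
      # follows the root's internal patterning rather than a pure Poisson
      # process, and neighbouring laterals stay distinguishable
      lo <- 2; hi <- max(3, tap$total_len_mm * 0.85)
      spacing <- (hi - lo) / n1
      s1 <- lo + spacing * (seq_len(n1) - 0.5) +
        rnorm(n1, 0, 0.15 * spacing)
      s1 <- sort(pmin(pmax(s1, lo), hi))
      # strict side alternation along the taproot keeps neighbouring
      # laterals from crossing, as in phyllotaxis-like branching patterns
      side <- rep_len(c(1, -1), n1)
      for (i in seq_len(n1)) {
        at <- polyline_at(tap$polyline, tap$cumlen, s1[i])
        e <- ceiling(day_reaching(tap, s1[i])) + params$emergence_lag_days
        ang <- at$angle + side[i] *
          (params$branch_angle_deg + rnorm(1L, 0, 6)) * pi / 180
        rate <- params$lateral1_rate_mm_per_day * runif(1L, 0.75, 1.25)
        # branch from the parent surface so truth length never double
        # counts the shared junction pixels
        base <- at$point + (root_diam_at(tap, s1[i]) / 2) * c(cos(ang), sin(ang))
        r <- new_root(sprintf("R1.%d", i), "lateral1", tap$root_id, s1[i],
                      base, ang, rate, params$lateral1_diam_mm, e)
        if (!is.null(r)) roots[[r$root_id]] <- r
      }
    }

    # second-order laterals: Poisson process along each first-order lateral
    for (pid in names(roots)) {
      pr <- roots[[pid]]
      if (pr$order != "lateral1") next
      n2 <- rpois(1L, params$lateral2_density_per_mm * pr$total_len_mm)
      if (n2 == 0) next
      s2 <- sort(runif(n2, 1, max(2, pr$total_len_mm * 0.9)))
      for (j in seq_len(n2)) {
        at <- polyline_at(pr$polyline, pr$cumlen, s2[j])
        e <- ceiling(day_reaching(pr, s2[j])) + params$emergence_lag_days
        ang <- at$angle + sample(c(-1, 1), 1L) *
          (params$branch_angle_deg + rnorm(1L, 0, 10)) * pi / 180
        rate <- params$lateral2_rate_mm_per_day * runif(1L, 0.75, 1.25)
        base <- at$point + (root_diam_at(pr, s2[j]) / 2) * c(cos(ang), sin(ang))
        r <- new_root(sprintf("%s.%d", pid, j), "lateral2", pid, s2[j],
                      base, ang, rate, params$lateral2_diam_mm, e)
        if (!is.null(r)) roots[[r$root_id]] <- r
      }
    }

    # hairs on laterals
    for (rid in names(roots)) {
      r <- roots[[rid]]
      if (r$order == "taproot") next
      nh <- rpois(1L, params$hair_density_per_mm * r$total_len_mm)
      if (nh == 0) next
      sh <- sort(runif(nh, 0.5, r$total_len_mm))
      # strictly alternating sides with mild angle jitter keep neighbouring
      # hair silhouettes separable, as in a clean 2-D profile view
      hairs <- lapply(seq_len(nh), function(k) {
        birth <- ceiling(day_reaching(r, sh[k])) + params$emergence_lag_days
        life <- if (is.infinite(params$hair_lifespan_mean_days)) NA_real_ else
          round(rexp(1L, 1 / params$hair_lifespan_mean_days)) + 1
        dist_day <- if (is.na(life) || birth + life > horizon) NA_real_ else birth + life
        list(hair_id = sprintf("%s.h%d", rid, k), anchor_s = sh[k],
             length_mm = runif(1L, params$hair_len_range_mm[1],
                               params$hair_len_range_mm[2]),
             side = if (k %% 2L == 0L) 1 else -1,
             angle_jitter = rnorm(1L, 0, 8 * pi / 180),
             birth_day = birth, distortion_day = dist_day)
      })
      hairs <- Filter(function(h) h$birth_day <= horizon, hairs)
      roots[[rid]]$hairs <- hairs
    }

    structure(list(roots = roots, sow_day = 0L, params = params, seed = seed),
              class = "root_system_truth")
  })
}

#' @export
print.root_system_truth <- function(x, ...) {
  ord <- vapply(x$roots, `[[`, character(1), "order")
  cat(sprintf("root_system_truth: %d roots (%d taproot, %d lateral1, %d lateral2), horizon %d d, seed %d\n",
              length(x$roots), sum(ord == "taproot"), sum(ord == "lateral1"),
              sum(ord == "lateral2"), x$params$horizon_days, x$seed))
  invisible(x)
}

#' Closed-form total root length of the truth at a given day
#'
#' A root emerged on day `e` with rate `r` has visible length
#' `min(r * (t - e + 1), full length)` on day `t >= e`; senescent roots stop
#' elongating but remain visible. The sum over roots is the exact oracle for
#' measured total root length.
#'
#' @param truth a [grow_root_system()] result.
#' @param day integer day after sowing.
#' @return length in mm.
#' @export
truth_total_length_mm <- function(truth, day) {
  sum(vapply(truth$roots, root_len_at, numeric(1), day = day))
}

#' Per-root visible lengths (mm) at a given day
#' @inheritParams truth_total_length_mm
#' @export
truth_root_lengths_mm <- function(truth, day) {
  vapply(truth$roots, root_len_at, numeric(1), day = day)
}

#' Length-weighted mean root diameter of the truth at a given day
#'
#' Integrates the linear base-to-tip taper over each root's visible arc
#' length.
#' @inheritParams truth_total_length_mm
#' @return diameter in mm (0 when nothing is visible).
#' @export
truth_mean_diameter_mm <- function(truth, day) {
  num <- 0; den <- 0
  for (r in truth$roots) {
    L <- root_len_at(r, day)
    if (L <= 0) next
    # mean of the taper over [0, L] of a root whose full length is total_len
    f <- L / r$total_len_mm
    dmean <- r$diam_base_mm - (r$diam_base_mm - r$diam_tip_mm) * f / 2
    num <- num + dmean * L
    den <- den + L
  }
  if (den == 0) 0 else num / den
}

#' Per-root emergence/senescence event table of the truth
#'
#' @inheritParams truth_total_length_mm
#' @return data.frame: `subject_id`, `order`, `emergence_day`, `end_day`,
#'   `censored` (alive at the horizon), `lifespan_days` (NA when censored).
#' @export
truth_events <- function(truth) {
  horizon <- truth$params$horizon_days
  do.call(rbind, lapply(truth$roots, function(r) {
    cens <- is.na(r$senescence_day)
    end <- if (cens) horizon else r$senescence_day
    data.frame(subject_id = r$root_id, order = r$order,
               emergence_day = r$emergence_day, end_day = end,
               censored = cens,
               lifespan_days = if (cens) NA_real_ else end - r$emergence_day,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Per-hair birth/distortion event table of the truth
#' @inheritParams truth_total_length_mm
#' @export
truth_hair_events <- function(truth) {
  horizon <- truth$params$horizon_days
  rows <- list()
  for (r in truth$roots) for (h in r$hairs) {
    cens <- is.na(h$distortion_day)
    end <- if (cens) horizon else h$distortion_day
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = h$hair_id, parent_id = r$root_id,
      length_mm = h$length_mm, birth_day = h$birth_day, end_day = end,
      censored = cens,
      lifespan_days = if (cens) NA_real_ else end - h$birth_day,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(rows) == 0L)
    return(data.frame(subject_id = character(), parent_id = character(),
                      length_mm = numeric(), birth_day = numeric(),
                      end_day = numeric(), censored = logical(),
                      lifespan_days = numeric()))
  do.call(rbind, rows)
}

#' Rendering configuration for synthetic frames
#'
#' Palettes follow the visual criteria used when scoring root status by eye:
#' newly emerged live roots are near-white, senescent roots turn a dark
#' smooth brown that stays brighter than the mean soil background but well
#' below live tissue, and the soil is a dark speckled texture with occasional
#' bright grains (the classical thresholder's main source of false
#' positives).
#'
#' @param dpi rendering resolution.
#' @param soil_rgb mean soil colour.
#' @param soil_speckle_contrast amplitude of the coarse soil texture.
#' @param speckle_scale_mm correlation length of the soil texture.
#' @param bright_speck_per_cm2 density of bright mineral grains.
#' @param live_rgb,senescent_rgb root palettes.
#' @param hair_brightness grey level of rendered hairs.
#' @param noise_sd per-pixel Gaussian noise (per-day stream).
#' @param hair_dpi_threshold hairs are rendered only at or above this dpi.
#' @param seed seed fixing soil texture and noise.
#' @export
render_config <- function(dpi = 300,
                          soil_rgb = c(0.26, 0.21, 0.17),
                          soil_speckle_contrast = 0.10,
                          speckle_scale_mm = 0.7,
                          bright_speck_per_cm2 = 6,
                          live_rgb = c(0.93, 0.91, 0.86),
                          senescent_rgb = c(0.45, 0.31, 0.21),
                          hair_brightness = 0.75,
                          noise_sd = 0.025,
                          hair_dpi_threshold = HAIR_DPI_DEFAULT,
                          seed = 1L) {
  stopifnot(dpi > 0,
            mean(live_rgb) > mean(senescent_rgb),
            mean(senescent_rgb) > mean(soil_rgb))
  structure(as.list(environment()), class = "render_config")
}

# smooth value-noise soil texture plus bright grains; deterministic in seed
soil_background <- function(nr, nc, cal, cfg) {
  with_seed(cfg$seed, {
    scale_px <- max(2, round(mm_to_px(cfg$speckle_scale_mm, cal)))
    gr <- ceiling(nr / scale_px) + 2L
    gc <- ceiling(nc / scale_px) + 2L
    coarse <- matrix(runif(gr * gc, -1, 1), gr, gc)
    tex <- bilinear_upsample(coarse, nr, nc, scale_px)
    base <- array(0, c(nr, nc, 3L))
    for (ch in 1:3)
      base[, , ch] <- cfg$soil_rgb[ch] * (1 + cfg$soil_speckle_contrast * tex)
    # bright grains
    area_cm2 <- (nr * nc) * (cal$mm_per_px / 10)^2
    n_speck <- rpois(1L, cfg$bright_speck_per_cm2 * area_cm2)
    if (n_speck > 0) {
      sr <- sample.int(nr, n_speck, replace = TRUE)
      sc <- sample.int(nc, n_speck, replace = TRUE)
      rad <- pmax(1, round(mm_to_px(runif(n_speck, 0.08, 0.3), cal)))
      val <- runif(n_speck, 0.7, 0.95)
      for (i in seq_len(n_speck)) {
        rr <- max(1, sr[i] - rad[i]):min(nr, sr[i] + rad[i])
        cc <- max(1, sc[i] - rad[i]):min(nc, sc[i] + rad[i])
        d2 <- outer((rr - sr[i])^2, (cc - sc[i])^2, `+`)
        hit <- d2 <= rad[i]^2
        for (ch in 1:3) {
          blk <- base[rr, cc, ch]
          blk[hit] <- val[i] * c(1, 0.97, 0.9)[ch]
          base[rr, cc, ch] <- blk
        }
      }
    }
    base
  })
}

bilinear_upsample <- function(coarse, nr, nc, scale_px) {
  ri <- (seq_len(nr) - 1) / scale_px + 1
  ci <- (seq_len(nc) - 1) / scale_px + 1
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  a <- coarse[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- coarse[cbind(rep(r0 + 1L, nc), rep(c0, each = nr))]
  cc_ <- coarse[cbind(rep(r0, nc), rep(c0 + 1L, each = nr))]
  d <- coarse[cbind(rep(r0 + 1L, nc), rep(c0 + 1L, each = nr))]
  fr_m <- rep(fr, nc); fc_m <- rep(fc, each = nr)
  v <- a * (1 - fr_m) * (1 - fc_m) + b * fr_m * (1 - fc_m) +
       cc_ * (1 - fr_m) * fc_m + d * fr_m * fc_m
  matrix(v, nr, nc)
}

# rasterize the first `len_mm` of a polyline as a ribbon of tapered width;
# returns logical matrix. Diameters are quantized to odd pixel brushes.
rasterize_root <- function(root, len_mm, nr, nc, cal) {
  out <- matrix(FALSE, nr, nc)
  if (len_mm <= 0) return(out)
  cum <- root$cumlen
  len_mm <- min(len_mm, cum[length(cum)])
  # sample points along the visible arc
  spacing_mm <- cal$mm_per_px * 0.6
  ss <- seq(0, len_mm, by = spacing_mm)
  if (ss[length(ss)] < len_mm) ss <- c(ss, len_mm)
  pts <- vapply(ss, function(s) polyline_at(root$polyline, cum, s)$point,
                numeric(2))
  # linear taper over the FULL planned length so diameter is monotone tip-ward
  dmm <- root$diam_base_mm -
    (root$diam_base_mm - root$diam_tip_mm) * ss / root$total_len_mm
  dpx <- pmax(1L, round(mm_to_px(dmm, cal)))
  dpx <- dpx + (dpx %% 2L == 0L)       # odd brush sizes
  rowi <- pmin(pmax(round(pts[2, ] / cal$mm_per_px), 1L), nr)
  coli <- pmin(pmax(round(pts[1, ] / cal$mm_per_px), 1L), nc)
  for (d in sort(unique(dpx))) {
    sel <- dpx == d
    pts_m <- matrix(0L, nr, nc)
    pts_m[cbind(rowi[sel], coli[sel])] <- 1L
    if (d == 1L) out <- out | (pts_m == 1L)
    else out <- out | (EBImage::dilate(pts_m, EBImage::makeBrush(d, "disc")) > 0)
  }
  out
}

# hair centreline path in mm, starting at the parent root SURFACE so that
# hair length_mm is the visible protruding length; distorted hairs curl into
# a sinusoid whose arc length exceeds the chord by a tortuosity of about 1.9
hair_path_mm <- function(root, hair, distorted = FALSE, n = 24L) {
  at <- polyline_at(root$polyline, root$cumlen, hair$anchor_s)
  ang <- at$angle + hair$side * pi / 2 + hair$angle_jitter
  dirv <- c(cos(ang), sin(ang))
  norm <- c(-dirv[2], dirv[1])
  # local parent radius from the linear taper
  dloc <- root$diam_base_mm - (root$diam_base_mm - root$diam_tip_mm) *
    hair$anchor_s / root$total_len_mm
  base <- at$point + dirv * (dloc / 2)
  L <- hair$length_mm
  if (!distorted) {
    t <- seq(0, L, length.out = n)
    return(cbind(base[1] + dirv[1] * t, base[2] + dirv[2] * t))
  }
  chord <- 0.6 * L
  amp <- 0.38 * chord / pi          # slope 2*pi*amp/(chord/2) ~ 2.4
  t <- seq(0, chord, length.out = n)
  off <- amp * sin(2 * pi * t / (chord / 2))
  cbind(base[1] + dirv[1] * t + norm[1] * off,
        base[2] + dirv[2] * t + norm[2] * off)
}

rasterize_path <- function(path_mm, width_px, nr, nc, cal) {
  seg <- sqrt(rowSums(diff(path_mm)^2))
  cum <- c(0, cumsum(seg))
  ss <- seq(0, cum[length(cum)], by = cal$mm_per_px * 0.5)
  pts <- vapply(ss, function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(path_mm) - 1L)
    f <- if (cum[i + 1L] > cum[i]) (s - cum[i]) / (cum[i + 1L] - cum[i]) else 0
    path_mm[i, ] + f * (path_mm[i + 1L, ] - path_mm[i, ])
  }, numeric(2))
  rowi <- pmin(pmax(round(pts[2, ] / cal$mm_per_px), 1L), nr)
  coli <- pmin(pmax(round(pts[1, ] / cal$mm_per_px), 1L), nc)
  m <- matrix(0L, nr, nc)
  m[cbind(rowi, coli)] <- 1L
  w <- max(1L, width_px); w <- w + (w %% 2L == 0L)
  if (w > 1L) m <- (EBImage::dilate(m, EBImage::makeBrush(w, "disc")) > 0) + 0L
  m
}

#' Render one synthetic scanner frame
#'
#' Draws every root that has emerged by `day` over the seeded soil
#' background: live roots in the bright live palette, roots past their
#' senescence day in the darker senescent palette (still present in the
#' mask — segmentation is colour-agnostic, liveness is a separate label).
#' Hairs are rendered, and reported in `hair_mask`, only when the rendering
#' dpi reaches the hair-resolution threshold; distorted hairs curl.
#'
#' @param truth a [grow_root_system()] result.
#' @param day integer day after sowing (>= sowing day).
#' @param config a [render_config()].
#' @return list with `image` (H x W x 3 array), `mask` (roots), `hair_mask`,
#'   `live` (matrix marking pixels of live roots), `day`, `dpi`.
#' @export
render_frame <- function(truth, day, config = render_config()) {
  if (day < truth$sow_day) stop("day precedes sowing")
  cal <- calibrate(config$dpi)
  p <- truth$params
  nr <- max(2L, round(mm_to_px(p$frame_height_mm, cal)))
  nc <- max(2L, round(mm_to_px(p$frame_width_mm, cal)))
  img <- soil_background(nr, nc, cal, config)
  mask <- matrix(0L, nr, nc)
  live <- matrix(0L, nr, nc)
  render_hairs <- config$dpi >= config$hair_dpi_threshold
  hair_mask <- matrix(0L, nr, nc)

  for (r in truth$roots) {
    L <- root_len_at(r, day)
    if (L <= 0) next
    rib <- rasterize_root(r, L, nr, nc, cal)
    is_live <- is.na(r$senescence_day) || day < r$senescence_day
    pal <- if (is_live) config$live_rgb else config$senescent_rgb
    idx <- which(rib)
    mask[idx] <- 1L
    if (is_live) live[idx] <- 1L else live[idx] <- 0L
    npix <- nr * nc
    for (ch in 1:3) img[idx + (ch - 1L) * npix] <- pal[ch]
    if (render_hairs && length(r$hairs)) {
      wpx <- max(1L, round(mm_to_px(p$hair_width_mm, cal)))
      for (h in r$hairs) {
        if (h$birth_day > day) next
        distorted <- !is.na(h$distortion_day) && day >= h$distortion_day
        hm <- rasterize_path(hair_path_mm(r, h, distorted), wpx, nr, nc, cal)
        hidx <- which(hm == 1L & mask == 0L)
        hair_mask[hidx] <- 1L
        for (ch in 1:3) img[hidx + (ch - 1L) * npix] <-
          config$hair_brightness * config$live_rgb[ch] / max(config$live_rgb)
      }
    }
  }
  # per-day sensor noise on a stream independent of the soil texture
  img <- with_seed(config$seed * 100003L %% .Machine$integer.max + day, {
    pmin(pmax(img + array(rnorm(length(img), 0, config$noise_sd), dim(img)), 0), 1)
  })
  list(image = img, mask = mask, hair_mask = hair_mask, live = live,
       day = day, dpi = config$dpi)
}

#' Generate a full synthetic image series with truth tables
#'
#' Renders one frame per requested day and assembles (i) an `image_series`
#' whose records hold the rendered pixels (and file paths when `dir` is
#' given), (ii) the per-frame truth masks, and (iii) truth tables: per-day
#' closed-form total root length, per-root events and per-hair events.
#'
#' @param truth a [grow_root_system()] result.
#' @param days increasing integer days to render.
#' @param config a [render_config()].
#' @param dir optional directory; when given, frames are written as
#'   `pot01_d<DAY>_<DPI>dpi.png` with truth masks under `masks/` and truth
#'   tables as CSV.
#' @param pot_id pot identifier used in file names.
#' @return list with `series`, `masks`, `hair_masks`, `truth_rl`
#'   (day, RL_mm), `root_events`, `hair_events`.
#' @export
generate_series <- function(truth, days, config = render_config(), dir = NULL,
                            pot_id = 1L) {
  if (length(days) == 0L || any(diff(days) <= 0))
    stop("`days` must be non-empty and strictly increasing")
  p <- truth$params
  frames <- lapply(days, render_frame, truth = truth, config = config)
  masks <- lapply(frames, `[[`, "mask")
  hair_masks <- lapply(frames, `[[`, "hair_mask")
  names(masks) <- names(hair_masks) <- as.character(days)

  records <- lapply(seq_along(days), function(i) {
    rec <- image_record(path = NA_character_, pot_id = as.integer(pot_id),
                        day = days[i], dpi = config$dpi,
                        hair_dpi_threshold = config$hair_dpi_threshold)
    rec$pixels <- frames[[i]]$image
    rec
  })
  series <- new_image_series(as.integer(pot_id), records,
                             frame_width_cm = p$frame_width_mm / 10,
                             frame_height_cm = p$frame_height_mm / 10)
  truth_rl <- data.frame(day = days,
                         RL_mm = vapply(days, truth_total_length_mm,
                                        numeric(1), truth = truth))
  out <- list(series = series, masks = masks, hair_masks = hair_masks,
              truth_rl = truth_rl,
              root_events = truth_events(truth),
              hair_events = truth_hair_events(truth))
  if (!is.null(dir)) {
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(days)) {
      fn <- sprintf("pot%02d_d%03d_%ddpi.png", as.integer(pot_id), days[i],
                    config$dpi)
      write_frame(frames[[i]]$image, file.path(dir, fn))
      out$series$records[[i]]$path <- file.path(dir, fn)
      write_mask(masks[[i]], file.path(dir, "masks", fn))
    }
    write.csv(truth_rl, file.path(dir, "truth_rl.csv"), row.names = FALSE)
    write.csv(out$root_events, file.path(dir, "truth_root_events.csv"),
              row.names = FALSE)
    write.csv(out$hair_events, file.path(dir, "truth_hair_events.csv"),
              row.names = FALSE)
  }
  out
}
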