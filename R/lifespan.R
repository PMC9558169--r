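#' @title Root and root-hair lifespan analysis
#' @name lifespan
#' @description
#' A root's lifespan is the number of days between its first appearance in
#' the series and the day its appearance turns senescent: roots brown (their
#' median brightness drops below the live threshold), hairs distort (their
#' skeleton path becomes tortuous — twisted and bent). Subjects still alive
#' at the last observed frame are right-censored. Lifespans are summarised
#' with the Kaplan-Meier product-limit estimator, implemented here from
#' first principles; groups are compared by median difference and the
#' standard log-rank test.
NULL

#' Register a series by per-frame integer translation
#'
#' Estimates, for every frame, the integer-pixel translation that maximises
#' the normalised cross-correlation with the first frame (scanner-fixed pots
#' drift by translation only). Offsets are searched within `max_shift_px`;
#' when the correlation peak falls below `min_corr` the frame is left
#' unshifted with a warning.
#'
#' @param series an `image_series`, or a list of RGB arrays / matrices.
#' @param max_shift_px search radius in pixels.
#' @param min_corr confidence floor on the normalised correlation peak.
#' @return data.frame with one row per frame: `day`, `dr`, `dc`, `corr`.
#' @export
align_series <- function(series, max_shift_px = 20L, min_corr = 0.2) {
  frames <- if (inherits(series, "image_series"))
    lapply(series$records, read_frame) else series
  if (length(frames) < 2L) stop("need at least 2 frames to align")
  days <- if (inherits(series, "image_series")) series$days else seq_along(frames)
  ref <- grayscale(frames[[1]])
  ref0 <- ref - mean(ref)
  fref <- fft(ref0)
  nr <- nrow(ref); nc <- ncol(ref)
  out <- data.frame(day = days, dr = 0L, dc = 0L, corr = 1)
  for (i in seq_along(frames)[-1L]) {
    g <- grayscale(frames[[i]])
    g0 <- g - mean(g)
    cc <- Re(fft(fref * Conj(fft(g0)), inverse = TRUE)) / length(ref0)
    cc <- cc / (sd(ref0) * sd(g0) * (length(ref0) - 1))
    # circular lags: row lag dr means frame i is shifted down by dr
    wrap <- function(v, n) ifelse(v > n / 2, v - n, v)
    rows_lag <- wrap(seq_len(nr) - 1L, nr)
    cols_lag <- wrap(seq_len(nc) - 1L, nc)
    ok <- abs(rows_lag) <= max_shift_px
    okc <- abs(cols_lag) <= max_shift_px
    sub <- cc[ok, okc, drop = FALSE]
    peak <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    corr <- max(sub)
    if (corr < min_corr) {
      warning("alignment confidence below floor for frame ", i,
              " (corr = ", round(corr, 3), "); using zero offset",
              call. = FALSE)
      next
    }
    out$dr[i] <- -rows_lag[ok][peak[1L]]
    out$dc[i] <- -cols_lag[okc][peak[2L]]
    out$corr[i] <- corr
  }
  out
}

#' Classify a root region as live or senescent by brightness
#'
#' Newly emerged roots are near-white; senescent roots are dark brown or
#' black. The median brightness of the root pixels inside the region decides:
#' at or above `live_min_brightness` the root is live (the boundary value
#' counts as live).
#'
#' @param image RGB array or grayscale matrix.
#' @param mask_roi binary matrix marking the root pixels to judge.
#' @param live_min_brightness brightness threshold in `[0, 1]`.
#' @return `"live"` or `"senescent"`.
#' @export
classify_status <- function(image, mask_roi, live_min_brightness = 0.6) {
  mask_roi <- as_binary_mask(mask_roi)
  if (sum(mask_roi) == 0L) stop("empty ROI")
  g <- grayscale(image)
  if (median(g[mask_roi == 1L]) >= live_min_brightness) "live" else "senescent"
}

#' Classify a hair skeleton path as intact or distorted by tortuosity
#'
#' Tortuosity is the path length divided by the endpoint chord distance: a
#' straight hair has tortuosity 1, a semicircular one pi/2. Hairs above the
#' threshold count as distorted (twisted and bent).
#'
#' @param path n x 2 matrix of ordered path coordinates (any consistent
#'   units), n >= 3.
#' @param threshold tortuosity above which the hair is distorted.
#' @return list with `status` (`"intact"`/`"distorted"`) and `tortuosity`.
#' @export
hair_status <- function(path, threshold = 1.5) {
  path <- as.matrix(path)
  if (nrow(path) < 3L) stop("degenerate path: need at least 3 nodes")
  arc <- sum(sqrt(rowSums(diff(path)^2)))
  chord <- sqrt(sum((path[nrow(path), ] - path[1L, ])^2))
  tort <- if (chord == 0) Inf else arc / chord
  list(status = if (tort > threshold) "distorted" else "intact",
       tortuosity = tort)
}

# ordered coordinates of the longest endpoint-to-endpoint path in a
# skeleton graph (used to assess hair shape inside an ROI)
skeleton_longest_path <- function(g) {
  n <- nrow(g$nodes)
  if (n == 0L) return(NULL)
  adj <- adjacency_list(n, g$edges)
  deg <- node_degree(n, g$edges)
  ends <- which(deg <= 1L)
  if (length(ends) == 0L) ends <- 1L
  best <- NULL; best_len <- -1
  for (s in ends) {
    # BFS tracking distance and parent
    dist <- rep(-1, n); parent <- rep(0L, n)
    dist[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (j in seq_along(nb$node)) {
        u <- nb$node[j]
        if (dist[u] < 0) {
          dist[u] <- dist[v] + nb$len[j]; parent[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    far <- which.max(dist)
    if (dist[far] > best_len) {
      best_len <- dist[far]
      path <- far
      while (parent[path[1L]] != 0L) path <- c(parent[path[1L]], path)
      best <- path
    }
  }
  cbind(x = g$nodes$col[best], y = g$nodes$row[best])
}

#' Extract emergence/senescence events across a registered series
#'
#' For every subject region of interest: the emergence day is the first day
#' on which the registered mask populates the ROI with at least
#' `min_area_px` root pixels; the end day is the first subsequent day on
#' which the subject is scored senescent — by brightness
#' ([classify_status()]) for roots, by skeleton tortuosity ([hair_status()])
#' for hairs. Subjects never scored senescent are right-censored at the last
#' observed day; ROIs never populated are dropped with a warning.
#'
#' @param series an `image_series`.
#' @param masks per-frame binary masks (day order); for hair subjects these
#'   should include hair pixels.
#' @param rois named list of binary ROI matrices, one per subject.
#' @param subject_type single type or vector along `rois`: `"lateral_root"`,
#'   `"hair_order1"` or `"hair_order2"`.
#' @param offsets optional [align_series()] result used to register masks
#'   and images to the first frame.
#' @param min_area_px emergence threshold on ROI root pixels.
#' @param live_min_brightness passed to [classify_status()].
#' @param tortuosity_threshold passed to [hair_status()].
#' @return data.frame: `subject_id`, `subject_type`, `emergence_day`,
#'   `end_day`, `censored`, `lifespan_days` (NA when censored).
#' @export
extract_events <- function(series, masks, rois,
                           subject_type = "lateral_root",
                           offsets = NULL, min_area_px = 10L,
                           live_min_brightness = 0.6,
                           tortuosity_threshold = 1.5) {
  days <- series$days
  if (length(masks) != length(days)) stop("need one mask per frame")
  types <- rep(subject_type, length.out = length(rois))
  masks <- lapply(masks, as_binary_mask)
  images <- lapply(series$records, read_frame)
  if (!is.null(offsets)) {
    masks <- lapply(seq_along(masks), function(i)
      shift_matrix(masks[[i]], -offsets$dr[i], -offsets$dc[i]))
    images <- lapply(seq_along(images), function(i) {
      im <- images[[i]]
      if (offsets$dr[i] == 0L && offsets$dc[i] == 0L) return(im)
      for (ch in seq_len(dim(im)[3]))
        im[, , ch] <- shift_matrix(im[, , ch], -offsets$dr[i], -offsets$dc[i])
      im
    })
  }
  cal <- calibrate(series$dpi)
  rows <- list()
  for (si in seq_along(rois)) {
    roi <- as_binary_mask(rois[[si]])
    sid <- if (!is.null(names(rois))) names(rois)[si] else sprintf("S%03d", si)
    pop <- vapply(masks, function(m) sum(m & roi), integer(1))
    first <- which(pop >= min_area_px)
    if (length(first) == 0L) {
      warning("subject ", sid, " never populated its ROI; dropped",
              call. = FALSE)
      next
    }
    e_day <- days[first[1L]]
    end_day <- NA_real_
    for (i in seq(first[1L], length(days))) {
      if (pop[i] < 1L) next
      roi_mask <- (masks[[i]] & roi) + 0L
      senesc <- if (types[si] == "lateral_root") {
        classify_status(images[[i]], roi_mask, live_min_brightness) == "senescent"
      } else {
        g <- skeletonize_mask(roi_mask, cal, prune_len_mm = 0)
        pth <- skeleton_longest_path(g)
        !is.null(pth) && nrow(pth) >= 3L &&
          hair_status(pth, tortuosity_threshold)$status == "distorted"
      }
      if (senesc) { end_day <- days[i]; break }
    }
    censored <- is.na(end_day)
    if (censored) end_day <- days[length(days)]
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sid, subject_type = types[si], emergence_day = e_day,
      end_day = end_day, censored = censored,
      lifespan_days = if (censored) NA_real_ else end_day - e_day,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no subject ever populated its ROI")
  do.call(rbind, rows)
}

#' Propose subject ROIs from newly appearing mask components
#'
#' Scans the registered mask series for connected components that appear on
#' a day without overlapping the (dilated) previous-day mask, and turns each
#' into a circular ROI around its centroid. This automates subject selection
#' for [extract_events()] when no manual regions are available.
#'
#' @param masks per-frame binary masks, registered, in day order.
#' @param min_area_px ignore new components smaller than this.
#' @param roi_radius_px radius of the proposed circular ROI.
#' @param dilate_px tolerance dilation of the previous-day mask.
#' @return named list of binary ROI matrices.
#' @export
propose_rois <- function(masks, min_area_px = 25L, roi_radius_px = 12L,
                         dilate_px = 3L) {
  masks <- lapply(masks, as_binary_mask)
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  brush <- EBImage::makeBrush(2L * dilate_px + 1L, "disc")
  rois <- list()
  prev <- matrix(0L, nr, nc)
  for (i in seq_along(masks)) {
    grown <- if (sum(prev) > 0) (EBImage::dilate(prev, brush) > 0) + 0L else prev
    new_px <- masks[[i]] & !grown
    if (sum(new_px) >= min_area_px) {
      lab <- EBImage::bwlabel(new_px + 0L)
      sizes <- tabulate(lab[lab > 0])
      for (comp in which(sizes >= min_area_px)) {
        idx <- which(lab == comp)
        rr <- round(mean(((idx - 1L) %% nr) + 1L))
        cc <- round(mean(((idx - 1L) %/% nr) + 1L))
        roi <- matrix(0L, nr, nc)
        rs <- max(1L, rr - roi_radius_px):min(nr, rr + roi_radius_px)
        cs <- max(1L, cc - roi_radius_px):min(nc, cc + roi_radius_px)
        d2 <- outer((rs - rr)^2, (cs - cc)^2, `+`)
        roi[rs, cs][d2 <= roi_radius_px^2] <- 1L
        rois[[sprintf("d%03d_c%02d", i, comp)]] <- roi
      }
    }
    prev <- masks[[i]]
  }
  rois
}

#' Kaplan-Meier product-limit survival curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event (death)
#' times `t_i`, with `d_i` deaths among `n_i` subjects still at risk;
#' censored subjects leave the risk set after their censoring time. With no
#' censoring this reduces exactly to the empirical survivor fraction. The
#' median lifespan is the smallest event time at which `S(t)` drops to 0.5
#' or below, undefined (NA) when the curve never reaches 0.5.
#'
#' @param events data.frame with either (`emergence_day`, `end_day`,
#'   `censored`) or (`time`, `event`) columns.
#' @return a `survival_curve`: data.frame `time`, `n_risk`, `n_event`,
#'   `n_censored`, `survival`, with attribute `median`.
#' @export
kaplan_meier <- function(events) {
  te <- events_to_times(events)
  if (length(te$time) == 0L) stop("no events")
  if (all(!te$event & te$time == 0))
    stop("all lifespans censored at day 0: nothing to estimate")
  tt <- sort(unique(te$time[te$event]))
  n_risk <- vapply(tt, function(t) sum(te$time >= t), numeric(1))
  d <- vapply(tt, function(t) sum(te$time == t & te$event), numeric(1))
  cens <- vapply(tt, function(t) sum(te$time == t & !te$event), numeric(1))
  s <- cumprod(1 - d / n_risk)
  curve <- data.frame(time = tt, n_risk = n_risk, n_event = d,
                      n_censored = cens, survival = s)
  # float-tolerant comparison so that S(t) computed as a cumulative product
  # still counts as reaching one half exactly
  med <- if (any(s <= 0.5 + 1e-9)) tt[which(s <= 0.5 + 1e-9)[1L]] else NA_real_
  structure(curve, median = med, class = c("survival_curve", "data.frame"))
}

events_to_times <- function(events) {
  if (all(c("time", "event") %in% names(events))) {
    list(time = events$time, event = as.logical(events$event))
  } else if (all(c("emergence_day", "end_day", "censored") %in% names(events))) {
    list(time = events$end_day - events$emergence_day,
         event = !events$censored)
  } else stop("events need (time, event) or (emergence_day, end_day, censored)")
}

#' Median lifespan of a survival curve
#' @param curve a [kaplan_meier()] result.
#' @export
km_median <- function(curve) attr(curve, "median")

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d event times, median lifespan %s\n",
              nrow(x),
              if (is.na(attr(x, "median"))) "undefined (S > 0.5 throughout)"
              else paste0(attr(x, "median"), " d")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a survival curve as a step function
#' @param x a `survival_curve`.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics abline
#' @export
plot.survival_curve <- function(x, ...) {
  plot(stats::stepfun(x$time, c(1, x$survival)), do.points = FALSE,
       xlab = "days", ylab = "S(t)", ylim = c(0, 1), ...)
  abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Compare two lifespan groups: median difference and log-rank test
#'
#' @param events_a,events_b event tables as accepted by [kaplan_meier()];
#'   each group needs at least 2 uncensored events.
#' @return list with `median_a`, `median_b`, `median_diff` (NA when either
#'   median is undefined), `chisq`, `df`, `p_value` of the standard
#'   log-rank test.
#' @export
compare_groups <- function(events_a, events_b) {
  ta <- events_to_times(events_a); tb <- events_to_times(events_b)
  if (sum(ta$event) < 2L || sum(tb$event) < 2L)
    stop("each group needs at least 2 uncensored events")
  ka <- kaplan_meier(events_a); kb <- kaplan_meier(events_b)
  med_a <- km_median(ka); med_b <- km_median(kb)

  time <- c(ta$time, tb$time)
  event <- c(ta$event, tb$event)
  grp <- rep(c(0L, 1L), c(length(ta$time), length(tb$time)))
  tt <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event); d1 <- sum(time == t & event & grp == 1L)
    if (n < 2L || d == 0L) next
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  list(median_a = med_a, median_b = med_b,
       median_diff = if (is.na(med_a) || is.na(med_b)) NA_real_
                     else med_b - med_a,
       chisq = chisq, df = 1L, p_value = pchisq(chisq, 1L, lower.tail = FALSE))
}
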