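#' @title Growth dynamics of trait time series
#' @name dynamics
#' @description
#' Net growth rate of root length density and per-root elongation /
#' diameter-change rates. The net growth rate over consecutive observations
#' is `RLD_NGR = (RLD_n - RLD_{n-1}) / d`, with `d` the actual elapsed days
#' (daily imaging gives `d = 1`, but gaps are honoured); negative values
#' indicate net senescence exceeding elongation.
NULL

#' Net growth rate of root length density
#'
#' @param trait_series data.frame with columns `day` and `RLD_cm_per_cm3`
#'   (as produced by [traits_for_series()]).
#' @return data.frame `day`, `RLD_cm_per_cm3`, `d` (day gap) and
#'   `RLD_NGR_cm_per_cm3_day`, the latter two `NA` on the first row.
#' @export
rld_ngr <- function(trait_series) {
  if (!all(c("day", "RLD_cm_per_cm3") %in% names(trait_series)))
    stop("trait_series needs columns day and RLD_cm_per_cm3")
  ts <- trait_series[order(trait_series$day), , drop = FALSE]
  if (nrow(ts) < 2L) stop("need at least 2 rows to form a growth rate")
  if (anyDuplicated(ts$day)) stop("duplicate days in trait series")
  d <- c(NA_real_, diff(ts$day))
  ngr <- c(NA_real_, diff(ts$RLD_cm_per_cm3)) / d
  data.frame(day = ts$day, RLD_cm_per_cm3 = ts$RLD_cm_per_cm3, d = d,
             RLD_NGR_cm_per_cm3_day = ngr)
}

# translate a binary matrix by integer (dr, dc), zero-filling
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Track one root through a registered series
#'
#' Starting from a seed region containing part of one root on the first day,
#' the connected mask component overlapping the region is measured each day;
#' the component found on day `n`, dilated by `dilate_margin_px`, becomes the
#' search region for day `n + 1`. If the root disappears from the masks the
#' track is truncated and flagged.
#'
#' @param series an `image_series`.
#' @param masks per-frame binary masks (day order).
#' @param seed_region binary matrix marking the seed region on the first day.
#' @param offsets optional per-day integer translations (data.frame with
#'   `dr`, `dc`, as from [align_series()]) used to register the masks.
#' @param dilate_margin_px dilation of the previous component when searching
#'   the next day.
#' @param prune_len_mm passed to [skeletonize_mask()].
#' @return a `root_track` data.frame (`day`, `length_cm`, `diameter_mm`)
#'   with attribute `truncated` (TRUE if the root vanished before the last
#'   day).
#' @export
track_root <- function(series, masks, seed_region, offsets = NULL,
                       dilate_margin_px = 7, prune_len_mm = 0.5) {
  days <- series$days
  if (length(masks) != length(days)) stop("need one mask per frame")
  cal <- calibrate(series$dpi)
  if (!is.null(offsets)) {
    masks <- lapply(seq_along(masks), function(i)
      shift_matrix(as_binary_mask(masks[[i]]), -offsets$dr[i], -offsets$dc[i]))
  }
  region <- as_binary_mask(seed_region)
  if (sum(masks[[1]] & region) == 0L)
    stop("seed region contains no root pixels on the first day")
  brush <- EBImage::makeBrush(2L * dilate_margin_px + 1L, "disc")
  rows <- vector("list", length(days))
  truncated <- FALSE
  for (i in seq_along(days)) {
    m <- as_binary_mask(masks[[i]])
    lab <- EBImage::bwlabel(m)
    hit <- setdiff(unique(lab[region == 1L & m == 1L]), 0)
    if (length(hit) == 0L) { truncated <- TRUE; break }
    comp <- (matrix(lab, nrow(m), ncol(m)) %in% hit) + 0L
    dim(comp) <- dim(m)
    g <- skeletonize_mask(comp, cal, prune_len_mm)
    tt <- measure_traits(g, cal)
    rows[[i]] <- data.frame(day = days[i], length_cm = tt$RL_cm,
                            diameter_mm = tt$AD_mm)
    region <- (EBImage::dilate(comp, brush) > 0) + 0L
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "truncated") <- truncated
  class(out) <- c("root_track", class(out))
  out
}

#' Per-day growth rates of a tracked root
#'
#' Finite differences of length and diameter divided by the actual day gap.
#'
#' @param track a [track_root()] result (columns `day`, `length_cm`,
#'   `diameter_mm`).
#' @return data.frame `day`, `d`, `length_rate_cm_day`,
#'   `diameter_rate_mm_day` from the second observation onward.
#' @export
growth_rate <- function(track) {
  if (nrow(track) < 2L) stop("need at least 2 days to form a rate")
  d <- diff(track$day)
  data.frame(day = track$day[-1L], d = d,
             length_rate_cm_day = diff(track$length_cm) / d,
             diameter_rate_mm_day = diff(track$diameter_mm) / d)
}
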