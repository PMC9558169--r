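#' @title Root hair quantification from high-resolution masks
#' @name root_hair
#' @description
#' At hair-grade resolution (4800 dpi by default) individual root hairs
#' resolve as thin skeleton branches rooted on the much wider root axis.
#' Hairs and axis are separated by local width: skeleton nodes whose local
#' diameter reaches `axis_min_width_mm` form the axis, branches thinner than
#' `hair_max_width_mm` with a path length inside the plausibility band are
#' counted as hairs. Density is hairs per mm of axis skeleton length.
NULL

#' Detect and measure root hairs on a high-resolution mask
#'
#' @param mask binary mask containing the root axis and its hairs.
#' @param calibration a [calibrate()] result; an error is raised when the
#'   resolution is below `hair_dpi_threshold` (hairs are not resolvable).
#' @param axis_min_width_mm skeleton nodes at least this wide form the root
#'   axis.
#' @param hair_max_width_mm hair branches must stay thinner than this.
#' @param hair_len_range_mm plausibility band for hair path lengths, mm.
#' @param hair_dpi_threshold minimum dpi at which hair detection is
#'   meaningful.
#' @return a `hair_measure` list: `n_hairs`, `axis_length_mm`,
#'   `density_per_mm`, `hair_lengths_mm`, `mean_length_mm`.
#' @export
detect_hairs <- function(mask, calibration,
                         axis_min_width_mm = 0.08,
                         hair_max_width_mm = 0.04,
                         hair_len_range_mm = c(0.05, 1.5),
                         hair_dpi_threshold = HAIR_DPI_DEFAULT) {
  if (calibration$dpi < hair_dpi_threshold)
    stop("resolution insufficient for hairs: ", calibration$dpi, " dpi < ",
         hair_dpi_threshold, " dpi")
  g <- skeletonize_mask(mask, calibration, prune_len_mm = 0)
  if (nrow(g$nodes) == 0L) stop("no axis found: empty mask")
  diam_mm <- 2 * g$nodes$radius_mm
  axis <- diam_mm >= axis_min_width_mm
  if (!any(axis)) stop("no axis found: no skeleton wider than ",
                       axis_min_width_mm, " mm")
  on_axis <- axis[g$edges$from] & axis[g$edges$to]
  # the medial axis sprouts a short internal branch toward every hair
  # attachment (length about the local radius); prune those spurs from the
  # axis subgraph so axis length reflects the main axis only
  axis_ids <- which(axis)
  remap <- integer(length(axis)); remap[axis_ids] <- seq_along(axis_ids)
  sub <- structure(list(
    nodes = g$nodes[axis_ids, , drop = FALSE],
    edges = data.frame(from = remap[g$edges$from[on_axis]],
                       to = remap[g$edges$to[on_axis]],
                       len_mm = g$edges$len_mm[on_axis])), class = "skeleton_graph")
  spur_len <- 1.3 * max(g$nodes$radius_mm[axis_ids])
  sub <- prune_spurs(sub, spur_len)
  axis_length_mm <- chain_corrected_length_mm(sub, calibration)
  if (axis_length_mm <= 0) stop("no axis found: axis has zero length")

  # connected components of the off-axis skeleton
  off <- !axis
  off_edge <- off[g$edges$from] & off[g$edges$to]
  n <- nrow(g$nodes)
  sub_edges <- g$edges[off_edge, , drop = FALSE]
  comp <- rep(NA_integer_, n)
  comp[off] <- subgraph_components(which(off), sub_edges)
  # components touching the axis through at least one mixed edge
  mixed <- xor(axis[g$edges$from], axis[g$edges$to])
  touching <- unique(stats::na.omit(c(comp[g$edges$from[mixed]],
                                      comp[g$edges$to[mixed]])))
  thin <- diam_mm < hair_max_width_mm
  thin_edge <- thin[g$edges$from] & thin[g$edges$to]
  hair_lengths <- numeric(0)
  for (cid in touching) {
    in_comp <- !is.na(comp) & comp == cid
    keep <- thin_edge & in_comp[g$edges$from] & in_comp[g$edges$to]
    len <- subgraph_length_mm(g, keep, calibration)
    if (len >= hair_len_range_mm[1] && len <= hair_len_range_mm[2])
      hair_lengths <- c(hair_lengths, len)
  }
  structure(list(
    n_hairs = length(hair_lengths),
    axis_length_mm = axis_length_mm,
    density_per_mm = length(hair_lengths) / axis_length_mm,
    hair_lengths_mm = hair_lengths,
    mean_length_mm = if (length(hair_lengths)) mean(hair_lengths) else NA_real_
  ), class = "hair_measure")
}

#' @export
print.hair_measure <- function(x, ...) {
  cat(sprintf("hair_measure: %d hairs on %.2f mm axis (%.2f per mm), mean length %.3f mm\n",
              x$n_hairs, x$axis_length_mm, x$density_per_mm,
              if (is.na(x$mean_length_mm)) NA else x$mean_length_mm))
  invisible(x)
}

# chain-resampled total length of a skeleton (sub)graph in mm; avoids the
# staircase over-count of raw {1, sqrt(2)} step weights on oblique paths
chain_corrected_length_mm <- function(g, calibration) {
  if (nrow(g$edges) == 0L) return(0)
  chains <- skeleton_chains(g)
  sum(chain_lengths_px(g, chains)) * calibration$mm_per_px
}

# chain-corrected length over an edge subset of a larger graph
subgraph_length_mm <- function(g, edge_keep, calibration) {
  e <- g$edges[edge_keep, , drop = FALSE]
  if (nrow(e) == 0L) return(0)
  ids <- sort(unique(c(e$from, e$to)))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  sub <- structure(list(nodes = g$nodes[ids, , drop = FALSE],
                        edges = data.frame(from = remap[e$from],
                                           to = remap[e$to],
                                           len_mm = e$len_mm)),
                   class = "skeleton_graph")
  chain_corrected_length_mm(sub, calibration)
}

# connected components over a node subset given its internal edges;
# returns labels aligned with `nodes` (a vector of node ids)
subgraph_components <- function(nodes, edges) {
  idx <- integer(max(nodes, 1L)); idx[nodes] <- seq_along(nodes)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  if (nrow(edges) > 0L) for (i in seq_len(nrow(edges))) {
    a <- find(idx[edges$from[i]]); b <- find(idx[edges$to[i]])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  match(roots, unique(roots))
}

#' Random subsample of hair lengths
#'
#' Emulates the manual protocol of measuring a handful of randomly chosen
#' hairs: `k` hairs (default 5) are sampled without replacement — all of them
#' when fewer than `k` are present — and the sampled mean is reported next to
#' the full-population mean.
#'
#' @param measure a [detect_hairs()] result.
#' @param k number of hairs to sample.
#' @param seed RNG seed for the draw.
#' @return list with `sampled_lengths_mm`, `sampled_mean_mm`,
#'   `population_mean_mm`, `k_used`.
#' @export
sample_hair_lengths <- function(measure, k = 5L, seed = 1L) {
  lens <- measure$hair_lengths_mm
  if (length(lens) == 0L) stop("no hairs to sample")
  k_used <- min(k, length(lens))
  picked <- with_seed(seed, sample(seq_along(lens), k_used))
  list(sampled_lengths_mm = lens[picked],
       sampled_mean_mm = mean(lens[picked]),
       population_mean_mm = mean(lens),
       k_used = k_used)
}
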