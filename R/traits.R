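#' @title Skeleton-based root morphology
#' @name root_traits
#' @description
#' Morphology is measured on the medial axis of the binary root mask: the mask
#' is thinned to a one-pixel 8-connected skeleton, each skeleton node carries a
#' local radius from the Euclidean distance transform, and traits are summed
#' over skeleton edges. Total root length (RL, cm) is the summed edge length
#' with diagonal steps weighted sqrt(2); average diameter (AD, mm) is the mean
#' node diameter; surface area (RSA, cm^2) and volume (RV, cm^3) treat each
#' edge as a cylinder of the local diameter; root length density
#' (RLD, cm/cm^3) divides RL by the observed soil volume `A x DOF`.
NULL

#' Frame geometry for root length density
#'
#' @param A_cm2 observed frame area in cm^2.
#' @param DOF_cm depth of soil visible against the panel, cm. Roots are only
#'   scored within a thin slab behind the transparent face; the default is
#'   0.25 cm (2.5 mm).
#' @return a `frame_geometry` object.
#' @export
frame_geometry <- function(A_cm2, DOF_cm = 0.25) {
  if (!is.numeric(A_cm2) || A_cm2 <= 0) stop("frame area A must be > 0")
  if (!is.numeric(DOF_cm) || DOF_cm <= 0) stop("depth-of-soil DOF must be > 0")
  structure(list(A_cm2 = A_cm2, DOF_cm = DOF_cm), class = "frame_geometry")
}

#' Skeletonize a binary root mask into a measured graph
#'
#' Applies topology-preserving thinning, attaches a local radius to every
#' skeleton node (Euclidean distance transform minus half a pixel, i.e. the
#' distance from the pixel centre to the mask boundary), links 8-neighbouring
#' skeleton pixels into edges of length 1 or sqrt(2) pixels, and prunes spur
#' branches shorter than `prune_len_mm`. Diagonal edges that are shortcuts
#' across an orthogonally-connected pair are dropped so staircase paths are
#' not double counted.
#'
#' @param mask binary matrix.
#' @param calibration a [calibrate()] result.
#' @param prune_len_mm spurs (endpoint-to-junction paths) shorter than this
#'   are removed; use a value below the hair length band when hairs must be
#'   preserved.
#' @return a `skeleton_graph` with `nodes` (row, col, radius_px, radius_mm),
#'   `edges` (from, to, len_mm) and `component` labels per node. An empty mask
#'   yields an empty graph.
#' @export
skeletonize_mask <- function(mask, calibration, prune_len_mm = 0.5) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0L) return(empty_skeleton_graph())
  skel <- guo_hall_thin(mask)
  edt <- EBImage::distmap(mask)
  g <- pixel_graph(skel, edt, calibration)
  g <- prune_spurs(g, prune_len_mm)
  g$component <- graph_components(nrow(g$nodes), g$edges)
  g$calibration <- calibration
  g
}

empty_skeleton_graph <- function() {
  structure(list(
    nodes = data.frame(row = integer(), col = integer(),
                       radius_px = numeric(), radius_mm = numeric()),
    edges = data.frame(from = integer(), to = integer(), len_mm = numeric()),
    component = integer(), calibration = NULL
  ), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges),
              if (length(x$component)) max(x$component) else 0L))
  invisible(x)
}

# build node/edge tables from a thinned mask and its distance transform
pixel_graph <- function(skel, edt, calibration) {
  nr <- nrow(skel); nc <- ncol(skel)
  on <- which(skel == 1L)
  id <- matrix(0L, nr, nc)
  id[on] <- seq_along(on)
  rows <- ((on - 1L) %% nr) + 1L
  cols <- ((on - 1L) %/% nr) + 1L
  radius_px <- pmax(edt[on] - 0.5, 0.5)

  S <- skel == 1L
  shift <- function(M, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    r1 <- max(1, 1 + dr); r2 <- min(nr, nr + dr)
    c1 <- max(1, 1 + dc); c2 <- min(nc, nc + dc)
    out[r1:r2, c1:c2] <- M[(r1:r2) - dr, (c1:c2) - dc]
    out
  }
  edge_from_offset <- function(dr, dc, mediators) {
    # pixel p has neighbour at (r+dr, c+dc); both skeleton
    nb <- shift(S, -dr, -dc)         # TRUE where neighbour exists
    ok <- S & nb
    if (!is.null(mediators)) {
      med <- Reduce(`|`, lapply(mediators, function(m) {
        shift(S, -m[1], -m[2])
      }))
      ok <- ok & !med                # drop diagonal shortcut across a corner
    }
    p <- which(ok)
    if (length(p) == 0L) return(NULL)
    pr <- ((p - 1L) %% nr) + 1L; pc <- ((p - 1L) %/% nr) + 1L
    q <- (pr + dr) + (pc + dc - 1L) * nr
    data.frame(from = id[p], to = id[q],
               len_px = sqrt(dr^2 + dc^2))
  }
  el <- rbind(
    edge_from_offset(0L, 1L, NULL),
    edge_from_offset(1L, 0L, NULL),
    edge_from_offset(1L, 1L, list(c(0L, 1L), c(1L, 0L))),
    edge_from_offset(-1L, 1L, list(c(0L, 1L), c(-1L, 0L)))
  )
  if (is.null(el)) el <- data.frame(from = integer(), to = integer(), len_px = numeric())
  el$len_mm <- el$len_px * calibration$mm_per_px
  structure(list(
    nodes = data.frame(row = rows, col = cols, radius_px = radius_px,
                       radius_mm = radius_px * calibration$mm_per_px),
    edges = el[, c("from", "to", "len_mm")],
    component = integer(0), calibration = calibration
  ), class = "skeleton_graph")
}

node_degree <- function(n_nodes, edges) {
  tabulate(c(edges$from, edges$to), nbins = n_nodes)
}

# iteratively remove endpoint-to-junction paths shorter than prune_len_mm
prune_spurs <- function(g, prune_len_mm) {
  if (prune_len_mm <= 0 || nrow(g$nodes) == 0L) return(g)
  repeat {
    n <- nrow(g$nodes)
    if (n == 0L || nrow(g$edges) == 0L) break
    deg <- node_degree(n, g$edges)
    adj <- adjacency_list(n, g$edges)
    endpoints <- which(deg == 1L)
    if (length(endpoints) == 0L) break
    drop <- rep(FALSE, n)
    for (e in endpoints) {
      if (drop[e]) next
      path <- e; len <- 0; prev <- 0L; cur <- e
      repeat {
        nbr <- adj[[cur]]
        nxt <- nbr$node[nbr$node != prev]
        w <- nbr$len[nbr$node != prev]
        if (length(nxt) != 1L) break     # junction or isolated end
        len <- len + w[1]
        if (len >= prune_len_mm) break
        prev <- cur; cur <- nxt[1]
        if (deg[cur] >= 3L) break        # reached a junction: spur complete
        path <- c(path, cur)
        if (deg[cur] == 1L) break        # whole component shorter than prune
      }
      ends_at_junction <- deg[cur] >= 3L
      if (len < prune_len_mm && ends_at_junction) drop[path] <- TRUE
    }
    if (!any(drop)) break
    keep <- which(!drop)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    g$nodes <- g$nodes[keep, , drop = FALSE]
    rownames(g$nodes) <- NULL
    ek <- !(drop[g$edges$from] | drop[g$edges$to])
    g$edges <- g$edges[ek, , drop = FALSE]
    g$edges$from <- remap[g$edges$from]
    g$edges$to <- remap[g$edges$to]
    rownames(g$edges) <- NULL
  }
  g
}

adjacency_list <- function(n_nodes, edges) {
  adj <- rep(list(list(node = integer(0), len = numeric(0))), n_nodes)
  if (nrow(edges) == 0L) return(adj)
  both <- data.frame(a = c(edges$from, edges$to),
                     b = c(edges$to, edges$from),
                     len = rep(edges$len_mm, 2L))
  sp <- split(both[, c("b", "len")], both$a)
  for (k in names(sp)) {
    i <- as.integer(k)
    adj[[i]] <- list(node = sp[[k]]$b, len = sp[[k]]$len)
  }
  adj
}

graph_components <- function(n_nodes, edges) {
  if (n_nodes == 0L) return(integer(0))
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$from[i]); rb <- find(edges$to[i])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n_nodes), find, integer(1))
  match(roots, unique(roots))
}

# Decompose a skeleton graph into maximal chains between breakpoints
# (nodes of degree != 2). Returns per-chain node sequences and edge ids.
skeleton_chains <- function(g) {
  n <- nrow(g$nodes)
  ne <- nrow(g$edges)
  if (ne == 0L) return(list())
  # adjacency with edge ids
  adj_n <- vector("list", n); adj_e <- vector("list", n)
  for (i in seq_len(ne)) {
    a <- g$edges$from[i]; b <- g$edges$to[i]
    adj_n[[a]] <- c(adj_n[[a]], b); adj_e[[a]] <- c(adj_e[[a]], i)
    adj_n[[b]] <- c(adj_n[[b]], a); adj_e[[b]] <- c(adj_e[[b]], i)
  }
  deg <- lengths(adj_n)
  visited <- logical(ne)
  chains <- list()
  walk <- function(start, first_nb, first_edge) {
    nodes <- c(start, first_nb); eids <- first_edge
    visited[first_edge] <<- TRUE
    prev <- start; cur <- first_nb
    while (deg[cur] == 2L) {
      k <- which(!visited[adj_e[[cur]]])
      if (length(k) == 0L) break
      e <- adj_e[[cur]][k[1L]]
      nxt <- adj_n[[cur]][k[1L]]
      visited[e] <<- TRUE
      nodes <- c(nodes, nxt); eids <- c(eids, e)
      prev <- cur; cur <- nxt
    }
    list(nodes = nodes, edges = eids)
  }
  for (v in which(deg != 2L)) {
    for (j in seq_along(adj_e[[v]])) {
      e <- adj_e[[v]][j]
      if (!visited[e]) chains[[length(chains) + 1L]] <-
          walk(v, adj_n[[v]][j], e)
    }
  }
  # pure cycles (every node degree 2)
  for (e in which(!visited)) {
    if (visited[e]) next
    chains[[length(chains) + 1L]] <- walk(g$edges$from[e], g$edges$to[e], e)
  }
  chains
}

# Corrected length of each chain: thinning leaves staircase jitter that the
# {1, sqrt(2)} step weights over-count at oblique angles, so the chain is
# resampled every `k` nodes and chord distances are summed.
chain_lengths_px <- function(g, chains, k = 5L) {
  vapply(chains, function(ch) {
    idx <- ch$nodes
    if (length(idx) < 2L) return(0)
    pick <- unique(c(seq(1L, length(idx), by = k), length(idx)))
    r <- g$nodes$row[idx[pick]]; cc <- g$nodes$col[idx[pick]]
    sum(sqrt(diff(r)^2 + diff(cc)^2))
  }, numeric(1))
}

#' Measure root traits on a skeleton graph
#'
#' @param graph a [skeletonize_mask()] result.
#' @param calibration a [calibrate()] result (defaults to the calibration
#'   stored in the graph).
#' @param geometry a [frame_geometry()]; when supplied, root length density
#'   `RLD = RL / (A x DOF)` is filled in.
#' @param day optional integer day-after-sowing carried into the result.
#' @return one-row data.frame with `RL_cm`, `AD_mm`, `RSA_cm2`, `RV_cm3`,
#'   `RLD_cm_per_cm3` (NA without geometry) and `day`.
#' @export
measure_traits <- function(graph, calibration = graph$calibration,
                           geometry = NULL, day = NA_integer_) {
  if (!is.null(geometry) &&
      (geometry$A_cm2 <= 0 || geometry$DOF_cm <= 0))
    stop("invalid frame geometry")
  if (nrow(graph$edges) == 0L) {
    rl <- 0; ad <- 0; rsa <- 0; rv <- 0
  } else {
    # chain-resampled lengths correct the staircase over-count of the raw
    # {1, sqrt(2)} steps at oblique angles; each chain's correction factor
    # also rescales its edges inside the cylinder sums
    chains <- skeleton_chains(graph)
    corr_px <- chain_lengths_px(graph, chains)
    rl <- sum(corr_px) * calibration$mm_per_px / 10            # cm
    ad <- mean(2 * graph$nodes$radius_mm)                      # mm
    edge_scale <- rep(1, nrow(graph$edges))
    for (ci in seq_along(chains)) {
      raw <- sum(graph$edges$len_mm[chains[[ci]]$edges])
      if (raw > 0)
        edge_scale[chains[[ci]]$edges] <-
          corr_px[ci] * calibration$mm_per_px / raw
    }
    # per-edge cylinder using the mean local radius of its endpoints
    r_edge_cm <- (graph$nodes$radius_mm[graph$edges$from] +
                  graph$nodes$radius_mm[graph$edges$to]) / 2 / 10
    l_edge_cm <- graph$edges$len_mm * edge_scale / 10
    rsa <- pi * sum(2 * r_edge_cm * l_edge_cm)                 # cm^2
    rv <- pi * sum(r_edge_cm^2 * l_edge_cm)                    # cm^3
  }
  rld <- if (is.null(geometry)) NA_real_ else rl / (geometry$A_cm2 * geometry$DOF_cm)
  data.frame(day = as.integer(day), RL_cm = rl, AD_mm = ad,
             RSA_cm2 = rsa, RV_cm3 = rv, RLD_cm_per_cm3 = rld)
}

#' Trait time series for an image series
#'
#' Skeletonizes one mask per frame and measures traits, returning a table
#' sorted by day (a `TraitSeries`).
#'
#' @param series an `image_series`.
#' @param masks list of binary masks, one per frame in day order, or named by
#'   day.
#' @param geometry a [frame_geometry()]; defaults to the series frame area
#'   with the standard 0.25 cm depth of soil.
#' @param prune_len_mm passed to [skeletonize_mask()].
#' @return data.frame with one row per day and the columns of
#'   [measure_traits()].
#' @export
traits_for_series <- function(series, masks,
                              geometry = frame_geometry(frame_area_cm2(series)),
                              prune_len_mm = 0.5) {
  days <- series$days
  if (!is.null(names(masks))) {
    if (!setequal(names(masks), as.character(days)))
      stop("mask days do not match series days")
    masks <- masks[as.character(days)]
  } else if (length(masks) != length(days)) {
    stop("need one mask per frame: series has ", length(days),
         " frames, got ", length(masks), " masks")
  }
  cal <- calibrate(series$dpi)
  out <- do.call(rbind, lapply(seq_along(days), function(i) {
    g <- skeletonize_mask(masks[[i]], cal, prune_len_mm)
    measure_traits(g, cal, geometry, day = days[i])
  }))
  out[order(out$day), , drop = FALSE]
}
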