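## Channel search: widest (maximin-bottleneck) path on the clearance grid ---

## BFS flood fill over the 26-connected voxel graph restricted to `pass`
## (logical over linear indices). Returns TRUE as soon as any `targets`
## voxel is reached from `from`.
.reaches <- function(pass, dims, from, targets) {
  targets <- targets[pass[targets]]
  if (length(targets) == 0L) return(FALSE)
  if (!pass[from]) return(FALSE)
  target_mask <- logical(length(pass))
  target_mask[targets] <- TRUE
  if (target_mask[from]) return(TRUE)
  visited <- logical(length(pass))
  visited[from] <- TRUE
  frontier <- from
  while (length(frontier) > 0L) {
    ijk <- .vox_ijk(frontier, dims)
    nxt <- integer(0)
    for (o in seq_len(nrow(.offsets26))) {
      ni <- ijk[, 1] + .offsets26[o, 1]
      nj <- ijk[, 2] + .offsets26[o, 2]
      nk <- ijk[, 3] + .offsets26[o, 3]
      ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
        nk >= 1L & nk <= dims[3]
      if (!any(ok)) next
      idx <- .vox_idx(cbind(ni[ok], nj[ok], nk[ok]), dims)
      idx <- idx[pass[idx] & !visited[idx]]
      if (length(idx) > 0L) {
        if (any(target_mask[idx])) return(TRUE)
        visited[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  FALSE
}

## Largest clearance threshold t (among voxel clearance values) such that
## `from` connects to `targets` through voxels with clearance >= t.
## Binary search over the sorted unique clearance levels.
.maximin_bottleneck <- function(clear_vec, dims, from, targets, probe) {
  levels <- sort(unique(clear_vec[clear_vec >= probe]))
  if (length(levels) == 0L) return(NA_real_)
  ## feasibility at the lowest level first
  if (!.reaches(clear_vec >= levels[1], dims, from, targets))
    return(NA_real_)
  lo <- 1L
  hi <- length(levels)
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (.reaches(clear_vec >= levels[mid], dims, from, targets)) lo <- mid
    else hi <- mid - 1L
  }
  levels[lo]
}

## Shortest (Euclidean arc length) voxel path from `from` to the nearest of
## `targets` within the subgraph clearance >= thresh. igraph Dijkstra.
.shortest_voxel_path <- function(clear_vec, dims, spacing, from, targets,
                                 thresh) {
  keep <- which(clear_vec >= thresh)
  if (!(from %in% keep)) stop("internal: seed below path threshold")
  vid <- integer(length(clear_vec))
  vid[keep] <- seq_along(keep)
  ijk <- .vox_ijk(keep, dims)
  edges <- vector("list", 13L)
  wts <- vector("list", 13L)
  pos_off <- .offsets26[.offsets26[, 1] > 0 |
                          (.offsets26[, 1] == 0 & .offsets26[, 2] > 0) |
                          (.offsets26[, 1] == 0 & .offsets26[, 2] == 0 &
                             .offsets26[, 3] > 0), , drop = FALSE]
  for (o in seq_len(nrow(pos_off))) {
    ni <- ijk[, 1] + pos_off[o, 1]
    nj <- ijk[, 2] + pos_off[o, 2]
    nk <- ijk[, 3] + pos_off[o, 3]
    ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
      nk >= 1L & nk <= dims[3]
    if (!any(ok)) next
    nidx <- .vox_idx(cbind(ni[ok], nj[ok], nk[ok]), dims)
    src <- vid[keep[ok]]
    dst <- vid[nidx]
    m <- dst > 0L
    if (!any(m)) next
    edges[[o]] <- rbind(src[m], dst[m])
    wts[[o]] <- rep(spacing * sqrt(sum(pos_off[o, ]^2)), sum(m))
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_graph(as.vector(el), n = length(keep), directed = FALSE)
  w <- unlist(wts)
  tv <- vid[intersect(targets, keep)]
  if (length(tv) == 0L) stop("internal: no target voxel above threshold")
  d <- igraph::distances(g, v = vid[from], to = tv, weights = w)
  best <- tv[which.min(d[1, ])]
  sp <- igraph::shortest_paths(g, from = vid[from], to = best, weights = w)
  keep[as.integer(sp$vpath[[1]])]
}

## Exact clearance (distance to nearest vdW surface) of points against an
## obstacle table; used to re-evaluate local radii on the smoothed centreline.
.clearance_at <- function(points, obstacles, cap = Inf) {
  if (nrow(obstacles) == 0L)
    return(rep(cap, nrow(points)))
  om <- as.matrix(obstacles[, c("x", "y", "z")])
  orad <- obstacles$vdw_radius
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt((om[, 1] - points[i, 1])^2 + (om[, 2] - points[i, 2])^2 +
                (om[, 3] - points[i, 3])^2) - orad
    min(min(d), cap)
  }, numeric(1))
}

.moving_average <- function(m, window) {
  if (window <= 1L || nrow(m) < 3L) return(m)
  half <- (window - 1L) %/% 2L
  out <- m
  n <- nrow(m)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i, ] <- colMeans(m[lo:hi, , drop = FALSE])
  }
  ## keep the termini anchored
  out[1, ] <- m[1, ]
  out[n, ] <- m[n, ]
  out
}

.make_tunnel_path <- function(points, local_radius, segments, spacing,
                              search_bottleneck = NA_real_) {
  arclength <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  structure(list(points = points, arclength = arclength,
                 local_radius = local_radius,
                 bottleneck_radius = min(local_radius),
                 segments = segments, spacing = spacing,
                 search_bottleneck = search_bottleneck),
            class = "TunnelPath")
}

#' @export
print.TunnelPath <- function(x, ...) {
  cat(sprintf(
    "TunnelPath: %d points, arc length %.1f A, bottleneck %.2f A\n",
    nrow(x$points), max(x$arclength), x$bottleneck_radius))
  invisible(x)
}

#' Detect a membrane-spanning channel
#'
#' Finds, on the clearance grid, the seed-to-bulk path on each membrane
#' side that maximises the bottleneck clearance (widest path), with ties
#' broken by shorter arc length, and concatenates the two half-paths into a
#' single N-side to P-side channel through the seed. The raw voxel
#' centreline is smoothed by a centred moving average and local radii are
#' re-evaluated on the smoothed centreline against the obstacle spheres.
#'
#' The maximin bottleneck is computed exactly (binary search over voxel
#' clearance levels with flood-fill connectivity); `search_bottleneck`
#' records the smaller of the two sides' bottlenecks before smoothing.
#' While searching toward one membrane side, the opposite side's bulk slab
#' is treated as out of bounds, so the path cannot wrap around the protein
#' through the far solvent (the surrounding membrane, not represented as
#' obstacles, forbids that route physically).
#'
#' @param grid a [build_grid()] result.
#' @param spec the [search_spec()] used to build the grid.
#' @param smoothing_window centreline moving-average window in points
#'   (odd; 1 disables smoothing). Default 3.
#' @return A `TunnelPath`: points (N-side first), `arclength` (the channel
#'   coordinate R, 0 at the N-side terminus), `local_radius`,
#'   `bottleneck_radius` = min local radius, per-point `segments` labels and
#'   the per-side `search_bottleneck`.
#' @export
find_channel <- function(grid, spec, smoothing_window = 3L) {
  clear_vec <- as.vector(grid$clearance)
  dims <- grid$dims
  seed <- grid$seed_index
  halves <- list()
  bnecks <- c(n = NA_real_, p = NA_real_)
  for (side in c("n", "p")) {
    other <- if (side == "n") "p" else "n"
    ## the opposite slab is out of bounds for this side's search, so the
    ## path cannot wrap around the protein through the far solvent
    cv <- clear_vec
    cv[.bulk_voxels(grid, spec$bulk, other)] <- -Inf
    pass <- cv >= spec$probe_radius
    targets <- .bulk_voxels(grid, spec$bulk, side)
    targets <- targets[pass[targets]]
    b <- if (length(targets) > 0L)
      .maximin_bottleneck(cv, dims, seed, targets, spec$probe_radius)
    else NA_real_
    if (is.na(b)) {
      ## best achievable bottleneck ignoring the probe floor, for the message
      pos <- cv[cv > 0 & is.finite(cv)]
      best <- if (length(pos) > 0L)
        .maximin_bottleneck(cv, dims, seed,
                            .bulk_voxels(grid, spec$bulk, side),
                            probe = min(pos))
      else NA_real_
      stop(sprintf(
        "channel blocked toward %s side: best achievable bottleneck %.2f A < probe %.2f A",
        if (side == "n") "N" else "P",
        if (is.na(best)) 0 else best, spec$probe_radius))
    }
    bnecks[side] <- b
    halves[[side]] <- .shortest_voxel_path(cv, dims, grid$spacing,
                                           seed, targets, b)
  }
  ## N-side half reversed so the path reads N -> seed -> P
  idx_n <- rev(halves$n)
  idx_p <- halves$p
  idx <- c(idx_n, idx_p[-1])
  seg <- c(rep("n_side", length(idx_n) - 1L), "seed",
           rep("p_side", length(idx_p) - 1L))
  pts <- .vox_xyz(idx, grid)
  pts <- .moving_average(pts, smoothing_window)
  lr <- .clearance_at(pts, grid$obstacles, cap = grid$max_clearance)
  .make_tunnel_path(pts, lr, seg, grid$spacing,
                    search_bottleneck = min(bnecks))
}

#' Extend a channel path to bulk solvent
#'
#' Appends, at each terminus not yet inside a bulk slab, the minimal-length
#' passable voxel extension to that side's bulk region — an automated
#' equivalent of manually curating tunnels out to the solvent. Extension
#' points are labelled `"n_extension"` / `"p_extension"` in `segments`. If a
#' terminus is sealed (no passable extension within `max_extension`), the
#' path is returned unextended with `attr(, "unextended")` naming the side,
#' with a warning.
#'
#' @param path a `TunnelPath`.
#' @param grid the [build_grid()] result.
#' @param spec the [search_spec()].
#' @param max_extension cap on the straight-line distance from terminus to
#'   bulk, Angstrom.
#' @return A `TunnelPath` (idempotent when both termini already reach bulk).
#' @export
extend_to_bulk <- function(path, grid, spec, max_extension = 15) {
  clear_vec <- as.vector(grid$clearance)
  dims <- grid$dims
  pts <- path$points
  lr <- path$local_radius
  seg <- path$segments
  unext <- character(0)
  for (side in c("n", "p")) {
    bulk <- .bulk_voxels(grid, spec$bulk, side)
    bulk <- bulk[clear_vec[bulk] >= spec$probe_radius]
    term_xyz <- if (side == "n") pts[1, ] else pts[nrow(pts), ]
    ## already in bulk?
    ax <- match(spec$bulk[[side]]$axis, c("x", "y", "z"))
    lim <- grid$extent[spec$bulk[[side]]$side, spec$bulk[[side]]$axis]
    inside <- if (spec$bulk[[side]]$side == "min")
      term_xyz[ax] < lim - spec$bulk$offset else
        term_xyz[ax] > lim + spec$bulk$offset
    if (inside) next
    tv <- .nearest_passable_voxel(grid, term_xyz, spec$probe_radius,
                                  max_dist = 2 * grid$spacing + 1e-9)
    ext <- NULL
    if (!is.na(tv) && length(bulk) > 0L) {
      bxyz <- .vox_xyz(bulk, grid)
      d <- sqrt((bxyz[, 1] - term_xyz[1])^2 + (bxyz[, 2] - term_xyz[2])^2 +
                  (bxyz[, 3] - term_xyz[3])^2)
      near <- bulk[d <= max_extension]
      if (length(near) > 0L) {
        ext <- tryCatch(
          .shortest_voxel_path(clear_vec, dims, grid$spacing, tv, near,
                               spec$probe_radius),
          error = function(e) NULL)
      }
    }
    if (length(ext) == 1L) next  # terminus already sits at the bulk edge
    if (is.null(ext) || length(ext) == 0L) {
      unext <- c(unext, side)
      next
    }
    exyz <- .vox_xyz(ext, grid)
    ## the cap limits the appended arc length, so a "detour" extension that
    ## wraps around the obstacle set does not count as reaching bulk
    ext_len <- sum(sqrt(rowSums(diff(rbind(term_xyz, exyz))^2)))
    if (ext_len > max_extension) {
      unext <- c(unext, side)
      next
    }
    exyz <- exyz[-1, , drop = FALSE]
    elab <- rep(paste0(side, "_extension"), nrow(exyz))
    if (side == "n") {
      pts <- rbind(exyz[rev(seq_len(nrow(exyz))), , drop = FALSE], pts)
      seg <- c(elab, seg)
    } else {
      pts <- rbind(pts, exyz)
      seg <- c(seg, elab)
    }
  }
  lr <- .clearance_at(pts, grid$obstacles, cap = grid$max_clearance)
  out <- .make_tunnel_path(pts, lr, seg, path$spacing,
                           search_bottleneck = path$search_bottleneck)
  if (length(unext) > 0L) {
    warning("no passable extension to bulk on side(s): ",
            paste(unext, collapse = ", "), "; path returned unextended")
    attr(out, "unextended") <- unext
  }
  out
}

#' Channel lining and radius profile
#'
#' For each centreline point, lists the residues with any heavy atom within
#' `contact_cutoff` of the point and classifies them as polar, nonpolar or
#' titratable ([residue_classes()]). Also reports the channel radius
#' profile: `radius` against the full obstacle set and `radius_lining`
#' with titratable residues removed from the obstacle set, so protonatable
#' side chains do not mask the geometric lumen they line.
#'
#' @param path a `TunnelPath`.
#' @param structure the `StructureModel`.
#' @param contact_cutoff contact distance, Angstrom. Default 4.
#' @return data.frame with one row per centreline point: `R`, `radius`,
#'   `radius_lining`, counts `n_polar`, `n_nonpolar`, `n_titratable` and a
#'   `residues` string ("RESNAME resid" contacts, `;`-separated).
#' @export
lining_profile <- function(path, structure, contact_cutoff = 4) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  a <- structure$atoms
  ## zero-radius marker pseudo-atoms are neither obstacles nor contacts
  prot <- a[a$is_heavy & !a$is_solvent & a$vdw_radius > 0, , drop = FALSE]
  am <- as.matrix(prot[, c("x", "y", "z")])
  cls_tab <- .residue_class
  obst_all <- data.frame(x = prot$x, y = prot$y, z = prot$z,
                         vdw_radius = prot$vdw_radius)
  titr <- !is.na(cls_tab[prot$resname]) & cls_tab[prot$resname] == "titratable"
  obst_nt <- obst_all[!titr, , drop = FALSE]
  n <- nrow(path$points)
  out <- data.frame(R = path$arclength,
                    radius = .clearance_at(path$points, obst_all),
                    radius_lining = .clearance_at(path$points, obst_nt),
                    n_polar = 0L, n_nonpolar = 0L, n_titratable = 0L,
                    residues = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- sqrt((am[, 1] - path$points[i, 1])^2 +
                (am[, 2] - path$points[i, 2])^2 +
                (am[, 3] - path$points[i, 3])^2)
    hit <- prot[d <= contact_cutoff, c("resname", "resid", "chain")]
    if (nrow(hit) == 0L) next
    res <- unique(hit)
    cls <- cls_tab[res$resname]
    out$n_polar[i] <- sum(cls == "polar", na.rm = TRUE)
    out$n_nonpolar[i] <- sum(cls == "nonpolar", na.rm = TRUE)
    out$n_titratable[i] <- sum(cls == "titratable", na.rm = TRUE)
    out$residues[i] <- paste(sprintf("%s %d", res$resname, res$resid),
                             collapse = ";")
  }
  out
}
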