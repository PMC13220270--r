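## Clearance grid -----------------------------------------------------------

#' Bulk-solvent definition for the channel search
#'
#' Bulk regions are slabs beyond the obstacle extent on a coordinate axis
#' (membrane normal = z by default): the N-side slab lies beyond one face,
#' the P-side slab beyond the other. Each side may use its own axis, which
#' accommodates bent test cavities that exit through different box faces.
#'
#' @param n_axis,p_axis axis of the N-/P-side exit: `"x"`, `"y"` or `"z"`.
#' @param n_side,p_side which face of the obstacle extent the slab lies
#'   beyond: `"min"` or `"max"`.
#' @param offset slab offset from the obstacle extent, Angstrom; positive
#'   values push the slab further into the margin.
#' @return list of class `bulk_definition`.
#' @export
bulk_slabs <- function(n_axis = "z", n_side = "min",
                       p_axis = "z", p_side = "max", offset = 0) {
  stopifnot(n_axis %in% c("x", "y", "z"), p_axis %in% c("x", "y", "z"),
            n_side %in% c("min", "max"), p_side %in% c("min", "max"))
  structure(list(n = list(axis = n_axis, side = n_side),
                 p = list(axis = p_axis, side = p_side),
                 offset = offset),
            class = "bulk_definition")
}

#' Channel-search specification
#'
#' @param start residue selector resolving to exactly one residue (see
#'   [resolve_residues()]); the search seeds at this residue (in antiporter
#'   modules, the central lysine, e.g. `"LYS+329"`).
#' @param probe_radius probe sphere radius, Angstrom. Default 0.9.
#' @param excluded_residues selectors for residues removed from the obstacle
#'   set (protonatable residues and bulky gating residues along the channel,
#'   so the search is not blocked by side chains that move during transport).
#' @param bulk a [bulk_slabs()] definition of the two solvent exits.
#' @return list of class `SearchSpec`.
#' @export
search_spec <- function(start, probe_radius = 0.9,
                        excluded_residues = character(),
                        bulk = bulk_slabs()) {
  if (!is.numeric(probe_radius) || probe_radius <= 0)
    stop("probe_radius must be > 0")
  structure(list(start = start, probe_radius = probe_radius,
                 excluded_residues = excluded_residues, bulk = bulk),
            class = "SearchSpec")
}

#' Build a clearance grid from a sphere-approximated structure
#'
#' Heavy atoms are approximated as spheres by their van der Waals radii;
#' solvent atoms and residues excluded in the search spec do not act as
#' obstacles. Each voxel's clearance is the distance from the voxel centre
#' to the nearest obstacle vdW surface (the radius of the largest probe
#' centred there), capped at `max_clearance`; voxels inside an obstacle
#' sphere carry negative clearance and are excluded.
#'
#' @param structure a `StructureModel`.
#' @param spec a [search_spec()]; its `start` is resolved to a seed position
#'   and its `excluded_residues` are dropped from the obstacle set.
#' @param spacing voxel edge, Angstrom. Default 0.8 (must resolve the 0.9 A
#'   probe).
#' @param margin grid margin beyond the obstacle bounding box, Angstrom,
#'   providing room for the bulk slabs.
#' @param max_clearance clearance cap, Angstrom; larger clearances are
#'   reported as the cap.
#' @return Object of class `CavityGrid`: clearance array, geometry, the
#'   obstacle atom table, the resolved seed position and the obstacle
#'   extents used by the bulk definition.
#' @export
build_grid <- function(structure, spec, spacing = 0.8, margin = 4,
                       max_clearance = 6) {
  if (spacing <= 0) stop("spacing must be > 0")
  a <- structure$atoms
  excl <- if (length(spec$excluded_residues) > 0L)
    resolve_residues(structure, spec$excluded_residues) else
      rep(FALSE, nrow(a))
  obst <- a[a$is_heavy & !a$is_solvent & !excl & a$vdw_radius > 0, ,
            drop = FALSE]
  if (nrow(obst) == 0L) {
    ## empty obstacle set: clearance everywhere at the cap
    lo <- c(-margin, -margin, -margin)
    hi <- c(margin, margin, margin)
  } else {
    lo <- c(min(obst$x - obst$vdw_radius), min(obst$y - obst$vdw_radius),
            min(obst$z - obst$vdw_radius)) - margin
    hi <- c(max(obst$x + obst$vdw_radius), max(obst$y + obst$vdw_radius),
            max(obst$z + obst$vdw_radius)) + margin
  }
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  ax <- lapply(1:3, function(k) lo[k] + spacing * (seq_len(dims[k]) - 1L))
  clearance <- array(max_clearance, dim = dims)
  ## per-atom local update: only voxels within vdw + cap can see this atom
  if (nrow(obst) > 0L) {
    om <- as.matrix(obst[, c("x", "y", "z")])
    orad <- obst$vdw_radius
    for (i in seq_len(nrow(obst))) {
      reach <- orad[i] + max_clearance
      rng <- lapply(1:3, function(k) {
        which(ax[[k]] >= om[i, k] - reach & ax[[k]] <= om[i, k] + reach)
      })
      if (any(vapply(rng, length, integer(1)) == 0L)) next
      dx2 <- (ax[[1]][rng[[1]]] - om[i, 1])^2
      dy2 <- (ax[[2]][rng[[2]]] - om[i, 2])^2
      dz2 <- (ax[[3]][rng[[3]]] - om[i, 3])^2
      d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - orad[i]
      sub <- clearance[rng[[1]], rng[[2]], rng[[3]]]
      clearance[rng[[1]], rng[[2]], rng[[3]]] <- pmin(sub, d)
    }
  }
  ## resolve seed
  sel <- resolve_residues(structure, spec$start)
  resk <- unique(paste(a$chain[sel], a$resid[sel]))
  if (length(resk) == 0L) stop("start selector matched no residue")
  if (length(resk) > 1L)
    stop("start selector must resolve to exactly one residue, got ",
         length(resk))
  seed_xyz <- colMeans(as.matrix(a[sel & a$is_heavy, c("x", "y", "z"),
                                   drop = FALSE]))
  extent <- if (nrow(obst) > 0L)
    rbind(min = c(min(obst$x), min(obst$y), min(obst$z)),
          max = c(max(obst$x), max(obst$y), max(obst$z)))
  else rbind(min = lo, max = hi)
  colnames(extent) <- c("x", "y", "z")
  grid <- structure(list(
    spacing = spacing, origin = lo, dims = dims, axes = ax,
    clearance = clearance, max_clearance = max_clearance,
    obstacles = obst[, c("x", "y", "z", "vdw_radius", "resname", "resid",
                         "chain")],
    seed_xyz = seed_xyz, extent = extent), class = "CavityGrid")
  ## seed voxel: nearest voxel with clearance >= probe within 6 A
  sv <- .nearest_passable_voxel(grid, seed_xyz, spec$probe_radius,
                                max_dist = 6)
  if (is.na(sv))
    stop("seed buried: no voxel with clearance >= probe radius within 6 A ",
         "of the start residue")
  grid$seed_index <- sv
  grid
}

#' @export
print.CavityGrid <- function(x, ...) {
  cat(sprintf("CavityGrid: %d x %d x %d voxels, spacing %.2f A, %d obstacle atoms\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, nrow(x$obstacles)))
  invisible(x)
}

## voxel index helpers: linear index <-> (i, j, k), 1-based internally
.vox_ijk <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

.vox_idx <- function(ijk, dims) {
  (ijk[, 1] - 1L) + dims[1] * ((ijk[, 2] - 1L) + dims[2] * (ijk[, 3] - 1L)) + 1L
}

.vox_xyz <- function(idx, grid) {
  ijk <- .vox_ijk(idx, grid$dims)
  cbind(grid$axes[[1]][ijk[, 1]], grid$axes[[2]][ijk[, 2]],
        grid$axes[[3]][ijk[, 3]])
}

## 26-connected neighbourhood offsets (all nonzero combinations)
.offsets26 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
})

.nearest_passable_voxel <- function(grid, xyz, probe, max_dist = 6) {
  pass <- which(grid$clearance >= probe)
  if (length(pass) == 0L) return(NA_integer_)
  pv <- .vox_xyz(pass, grid)
  d2 <- (pv[, 1] - xyz[1])^2 + (pv[, 2] - xyz[2])^2 + (pv[, 3] - xyz[3])^2
  b <- which.min(d2)
  if (sqrt(d2[b]) > max_dist) return(NA_integer_)
  pass[b]
}

## Voxels belonging to one bulk slab ('n' or 'p') under a bulk definition.
.bulk_voxels <- function(grid, bulk, which_side) {
  side <- bulk[[which_side]]
  k <- match(side$axis, c("x", "y", "z"))
  axvals <- grid$axes[[k]]
  lim <- grid$extent[side$side, side$axis]
  keep <- if (side$side == "min") axvals < lim - bulk$offset else
    axvals > lim + bulk$offset
  if (!any(keep)) return(integer(0))
  sel <- which(keep)
  ## all voxels whose k-th index is in sel
  dims <- grid$dims
  idx_all <- seq_len(prod(dims))
  ijk <- .vox_ijk(idx_all, dims)
  idx_all[ijk[, k] %in% sel]
}
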