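## Independent oracles and fixture builders shared across tests.

## Maximin (widest-path) bottleneck by Kruskal-style incremental insertion
## with union-find: activate voxels in decreasing clearance order; the
## bottleneck is the clearance of the voxel whose insertion first connects
## the seed to any target. Deliberately a different algorithm from the
## package's binary-search flood fill.
oracle_maximin <- function(clearance, dims, from, targets, probe) {
  clear_vec <- as.vector(clearance)
  n <- length(clear_vec)
  eligible <- which(clear_vec >= probe)
  if (!(from %in% eligible)) return(NA_real_)
  targets <- intersect(targets, eligible)
  if (length(targets) == 0L) return(NA_real_)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  active <- logical(n)
  target_mask <- logical(n)
  target_mask[targets] <- TRUE
  ord <- eligible[order(clear_vec[eligible], decreasing = TRUE)]
  ## process in groups of equal clearance
  vals <- clear_vec[ord]
  i <- 1L
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) && vals[j + 1L] == vals[i]) j <- j + 1L
    for (v in ord[i:j]) {
      active[v] <- TRUE
      ijk <- protonpath:::.vox_ijk(v, dims)
      for (o in seq_len(nrow(offs))) {
        ni <- ijk[1] + offs[o, 1]
        nj <- ijk[2] + offs[o, 2]
        nk <- ijk[3] + offs[o, 3]
        if (ni < 1 || ni > dims[1] || nj < 1 || nj > dims[2] ||
            nk < 1 || nk > dims[3]) next
        w <- protonpath:::.vox_idx(cbind(ni, nj, nk), dims)
        if (active[w]) {
          rv <- find(v)
          rw <- find(w)
          if (rv != rw) parent[rv] <- rw
        }
      }
    }
    ## connected yet? (seed to any target, both must be active)
    if (active[from]) {
      rf <- find(from)
      act_t <- targets[active[targets]]
      if (length(act_t) > 0L &&
          any(vapply(act_t, function(tv) find(tv) == rf, logical(1))))
        return(vals[i])
    }
    i <- j + 1L
  }
  NA_real_
}

## Per-side oracle bottleneck for a grid + spec, mirroring what
## find_channel reports as search_bottleneck.
oracle_search_bottleneck <- function(grid, spec) {
  b <- c(n = NA_real_, p = NA_real_)
  for (side in c("n", "p")) {
    other <- if (side == "n") "p" else "n"
    cv <- as.vector(grid$clearance)
    ## same out-of-bounds rule as find_channel: no wrap through the far slab
    cv[protonpath:::.bulk_voxels(grid, spec$bulk, other)] <- -Inf
    tv <- protonpath:::.bulk_voxels(grid, spec$bulk, side)
    tv <- tv[cv[tv] >= spec$probe_radius]
    b[side] <- oracle_maximin(cv, grid$dims, grid$seed_index,
                              tv, spec$probe_radius)
  }
  min(b)
}

## Random small cavity: a box of random obstacle spheres with a zero-radius
## seed marker at the centre. Returns NULL when the seed is buried or no
## channel exists, so callers can draw further seeds.
random_cavity <- function(seed, n_atoms = 14, box = 12, probe = 0.4) {
  set.seed(seed)
  pos <- matrix(runif(3 * n_atoms, 0, box), ncol = 3)
  rad <- runif(n_atoms, 1.2, 2.2)
  atoms <- data.frame(
    serial = seq_len(n_atoms), name = "C", resname = "GLY",
    resid = seq_len(n_atoms), chain = "A",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vdw_radius = rad, charge = 0, is_heavy = TRUE, is_solvent = FALSE)
  atoms <- rbind(atoms, data.frame(
    serial = n_atoms + 1L, name = "S", resname = "SED", resid = 999L,
    chain = "X", x = box / 2, y = box / 2, z = box / 2,
    vdw_radius = 0, charge = 0, is_heavy = TRUE, is_solvent = FALSE))
  struct <- structure_model(atoms)
  spec <- search_spec(start = "X:999", probe_radius = probe)
  grid <- tryCatch(
    build_grid(struct, spec, spacing = 1, margin = 2, max_clearance = 5),
    error = function(e) NULL)
  if (is.null(grid)) return(NULL)
  if (any(grid$dims > 20L)) return(NULL)
  path <- tryCatch(find_channel(grid, spec), error = function(e) NULL)
  if (is.null(path)) return(NULL)
  list(grid = grid, spec = spec, path = path)
}

## Simple independent Kabsch RMSD for superposition checks.
oracle_kabsch_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  rot <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  sqrt(mean(rowSums((ac %*% t(rot) - bc)^2)))
}

## A tiny 3-atom PDB + charge side table written to tempfiles.
write_toy_pdb <- function(dir = tempdir()) {
  atoms <- data.frame(
    serial = 1:4, name = c("N", "CA", "O", "O"),
    resname = c("ALA", "ALA", "ALA", "HOH"),
    resid = c(1L, 1L, 1L, 2L), chain = c("A", "A", "A", "A"),
    x = c(0, 1.5, 2.5, 8), y = c(0, 0.2, 1.1, 8), z = c(0, 0, 0.5, 8),
    vdw_radius = c(1.55, 1.70, 1.52, 1.52),
    charge = c(-0.47, 0.07, -0.51, 0),
    is_heavy = TRUE, is_solvent = c(FALSE, FALSE, FALSE, TRUE))
  struct <- structure_model(atoms)
  pdb <- file.path(dir, "toy.pdb")
  tab <- file.path(dir, "toy_charges.csv")
  write_structure(struct, pdb, charge_table = tab)
  list(structure = struct, pdb = pdb, charge_table = tab)
}
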