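fx <- make_channel_structure(length = 20, lumen_radius = 3)

test_that("occupancy counts frames with a water at the coordinate", {
  wt <- make_water_trajectory(fx, 1, n_frames = 10, seed = 1)
  occ <- water_occupancy(wt$trajectory, wt$structure, fx$path, step = 5)
  expect_true(all(occ$occupancy == 1))
  dry <- make_water_trajectory(fx, 0, n_frames = 10, seed = 1)
  occ0 <- water_occupancy(dry$trajectory, dry$structure, fx$path, step = 5)
  expect_true(all(occ0$occupancy == 0))
})

test_that("occupancy is an exact frame ratio", {
  ## water present at the second grid point in exactly 3 of 10 frames
  wt <- make_water_trajectory(fx, 0, n_frames = 10, seed = 1)
  rs <- resample_path(fx$path, 5)
  widx <- which(wt$structure$atoms$is_solvent)
  frames <- wt$trajectory$frames
  for (f in 1:3) frames[[f]][widx[2], ] <- rs$points[2, ]
  traj <- trajectory(frames, 0.1, 1L)
  occ <- water_occupancy(traj, wt$structure, fx$path, step = 5)
  expect_equal(occ$occupancy[2], 0.3)
  expect_true(all(occ$occupancy[-2] == 0))
})

test_that("occupancy needs frames and waters", {
  expect_error(water_occupancy(trajectory(list(coords(fx$structure)), 1),
                               fx$structure, fx$path),
               "no waters")
})

test_that("occupancy is invariant to frame order, duplication and rigid motion", {
  wt <- make_water_trajectory(fx, c(0.4, 0.7, 0.2, 0.9, 0.5),
                              n_frames = 60, seed = 11)
  occ <- water_occupancy(wt$trajectory, wt$structure, fx$path, step = 5)
  ## reorder frames
  sh <- trajectory(rev(wt$trajectory$frames), 0.1, 1L)
  expect_equal(water_occupancy(sh, wt$structure, fx$path, step = 5)$occupancy,
               occ$occupancy)
  ## duplicating every frame changes nothing
  dbl <- trajectory(c(wt$trajectory$frames, wt$trajectory$frames), 0.1, 1L)
  expect_equal(water_occupancy(dbl, wt$structure, fx$path,
                               step = 5)$occupancy, occ$occupancy)
  ## joint rigid motion of waters, protein and path
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -3, 2)
  move <- function(m) sweep(m %*% t(rot), 2, shift, `+`)
  mtraj <- trajectory(lapply(wt$trajectory$frames, move), 0.1, 1L)
  mpath <- protonpath:::.make_tunnel_path(move(fx$path$points),
                                          fx$path$local_radius,
                                          fx$path$segments, NA_real_)
  expect_equal(water_occupancy(mtraj, wt$structure, mpath,
                               step = 5)$occupancy, occ$occupancy)
})

test_that("replica aggregation takes means and population SDs", {
  mk <- function(v) channel_profile(coordinate = 1:2, occupancy = v,
                                    n_frames = 10L, replicas = 1L)
  agg <- aggregate_replicas(list(mk(c(0.2, 0.5)), mk(c(0.4, 0.5))))
  expect_equal(agg$occupancy, c(0.3, 0.5))
  expect_equal(agg$occupancy_sd, c(0.1, 0))  # population convention
  ## single replica, no normalization: identity
  one <- aggregate_replicas(list(mk(c(0.2, 0.5))))
  expect_equal(one$occupancy, c(0.2, 0.5))
  ## normalization rescales the peak to 1
  nrm <- aggregate_replicas(list(mk(c(0.25, 0.5))), normalize = TRUE)
  expect_equal(nrm$occupancy, c(0.5, 1))
  ## mismatched grids are refused
  bad <- channel_profile(coordinate = c(1, 3), occupancy = c(0, 0))
  expect_error(aggregate_replicas(list(mk(c(0.1, 0.1)), bad)), "grid")
})

test_that("superposition removes rigid motion and reports RMSD", {
  toy <- write_toy_pdb()
  ## extra atoms so the fit selection has >= 3 heavy atoms
  ref <- coords(toy$structure)
  ## identity frame
  tr <- trajectory(list(ref), 1)
  sup <- superpose(tr, toy$structure, c("A:1", "HOH+2"))
  expect_equal(attr(sup, "rmsd"), 0, tolerance = 1e-10)
  expect_equal(sup$frames[[1]], ref, ignore_attr = TRUE)
  ## 90-degree rotation is removed exactly
  rot90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tr2 <- trajectory(list(ref %*% t(rot90)), 1)
  sup2 <- superpose(tr2, toy$structure, c("A:1", "HOH+2"))
  expect_equal(attr(sup2, "rmsd"), 0, tolerance = 1e-10)
  expect_equal(sup2$frames[[1]], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(superpose(tr, toy$structure, "HOH+2"), "at least 3")
})

test_that("a single displaced atom leaves RMSD 1/sqrt(n) over all atoms", {
  ## fit on the unmoved atoms; displacement shows up only in the moved one
  set.seed(4)
  n <- 12L
  pos <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", resname = "GLY", resid = seq_len(n),
    chain = "A", x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vdw_radius = 1.7, charge = 0, is_heavy = TRUE, is_solvent = FALSE)
  s <- structure_model(atoms)
  moved <- pos
  moved[n, ] <- moved[n, ] + c(1, 0, 0)
  tr <- trajectory(list(moved), 1)
  sel <- sprintf("A:%d", seq_len(n - 1L))
  sup <- superpose(tr, s, sel)
  all_rmsd <- sqrt(mean(rowSums((sup$frames[[1]] - pos)^2)))
  expect_equal(all_rmsd, 1 / sqrt(n), tolerance = 1e-10)
  ## matches the independent Kabsch oracle fitted on all atoms (<= 1/sqrt(n))
  expect_lte(oracle_kabsch_rmsd(moved, pos), all_rmsd + 1e-12)
})
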