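cyl <- make_channel_structure(length = 30, lumen_radius = 3)
cyl_spec <- search_spec(cyl$seed_selector, probe_radius = 0.9,
                        bulk = cyl$bulk)
cyl_grid <- build_grid(cyl$structure, cyl_spec)
cyl_path <- find_channel(cyl_grid, cyl_spec)

test_that("a straight cylinder is found along its axis", {
  ## bottleneck within one grid spacing of the analytic lumen radius
  expect_lt(abs(cyl_path$bottleneck_radius - 3), cyl_grid$spacing)
  ## centreline stays near the axis (x = y = 0) inside the tube
  inside <- cyl_path$points[, 3] > 2 & cyl_path$points[, 3] < 28
  expect_lt(max(abs(cyl_path$points[inside, 1:2])), 2 * cyl_grid$spacing)
  ## channel coordinate runs N (low z) to P (high z), starting at 0
  expect_equal(cyl_path$arclength[1], 0)
  expect_true(all(diff(cyl_path$arclength) > 0))
  expect_lt(cyl_path$points[1, 3], cyl_path$points[nrow(cyl_path$points), 3])
})

test_that("a sub-probe constriction blocks the channel", {
  blocked <- make_channel_structure(length = 30, lumen_radius = 3,
                                    blockers = data.frame(R = 22,
                                                          radius = 0.5))
  expect_equal(min(blocked$path$local_radius), 0.5)  # ground truth
  spec <- search_spec(blocked$seed_selector, probe_radius = 0.9,
                      bulk = blocked$bulk)
  g <- build_grid(blocked$structure, spec)
  expect_error(find_channel(g, spec), "channel blocked toward P")
})

test_that("an L-shaped cavity is traversed arm to arm", {
  lb <- make_channel_structure(length = 30, lumen_radius = 2.5,
                               geometry = "l_bend")
  spec <- search_spec(lb$seed_selector, probe_radius = 0.9, bulk = lb$bulk)
  g <- build_grid(lb$structure, spec)
  p <- find_channel(g, spec)
  ## arc length ~ sum of the two arms plus the exit margins; the found
  ## path may cut the inner corner, so bound it by the ground-truth arc
  ## plus the margin overhead and below by the Euclidean end distance
  ends <- p$points[c(1, nrow(p$points)), ]
  euclid <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  expect_gte(max(p$arclength) + 1e-9, euclid)
  expect_lt(max(p$arclength), max(lb$path$arclength) + 12)
  expect_gt(max(p$arclength), euclid + 2)  # genuinely bent, not straight
})

test_that("search bottleneck equals the union-find maximin oracle", {
  found <- 0L
  seed <- 0L
  while (found < 6L && seed < 60L) {
    seed <- seed + 1L
    rc <- random_cavity(seed)
    if (is.null(rc)) next
    found <- found + 1L
    expect_equal(rc$path$search_bottleneck,
                 oracle_search_bottleneck(rc$grid, rc$spec),
                 tolerance = 1e-12)
  }
  expect_gte(found, 6L)
})

test_that("bottleneck responds monotonically to the obstacle set", {
  ## enlarging every obstacle radius never increases the bottleneck
  grown <- cyl$structure
  grown$atoms$vdw_radius[grown$atoms$vdw_radius > 0] <-
    grown$atoms$vdw_radius[grown$atoms$vdw_radius > 0] + 0.4
  g2 <- build_grid(grown, cyl_spec)
  p2 <- find_channel(g2, cyl_spec)
  expect_lte(p2$search_bottleneck, cyl_path$search_bottleneck + 1e-12)
  ## excluding a lining residue from the obstacle set never decreases it
  res_mid <- cyl$structure$atoms$resid[
    which.min(abs(cyl$structure$atoms$z - 15))]
  spec_ex <- search_spec(cyl$seed_selector, probe_radius = 0.9,
                         excluded_residues = sprintf("W:%d", res_mid),
                         bulk = cyl$bulk)
  g3 <- build_grid(cyl$structure, spec_ex)
  p3 <- find_channel(g3, spec_ex)
  expect_gte(p3$search_bottleneck, cyl_path$search_bottleneck - 1e-12)
})

test_that("halving the grid spacing moves the bottleneck by < coarse spacing", {
  small <- make_channel_structure(length = 16, lumen_radius = 2.5)
  spec <- search_spec(small$seed_selector, probe_radius = 0.9,
                      bulk = small$bulk)
  b <- vapply(c(0.8, 0.4), function(sp) {
    g <- build_grid(small$structure, spec, spacing = sp)
    find_channel(g, spec)$search_bottleneck
  }, numeric(1))
  expect_lt(abs(b[1] - b[2]), 0.8)
})

test_that("arc length is at least the Euclidean seed-to-exit distance", {
  seed_i <- which(cyl_path$segments == "seed")
  for (end_i in c(1L, nrow(cyl_path$points))) {
    euclid <- sqrt(sum((cyl_path$points[end_i, ] -
                          cyl_path$points[seed_i, ])^2))
    expect_gte(abs(cyl_path$arclength[end_i] - cyl_path$arclength[seed_i]),
               euclid - 1e-9)
  }
})

test_that("extend_to_bulk completes a truncated path and is idempotent", {
  ## truncate the found path well inside the tube
  keep <- cyl_path$points[, 3] < 24
  trunc <- protonpath:::.make_tunnel_path(cyl_path$points[keep, ],
                                          cyl_path$local_radius[keep],
                                          cyl_path$segments[keep],
                                          cyl_path$spacing)
  ext <- extend_to_bulk(trunc, cyl_grid, cyl_spec)
  expect_gt(max(ext$points[, 3]), cyl_grid$extent["max", "z"])
  expect_true(any(ext$segments == "p_extension"))
  ## a path already reaching bulk is returned unchanged
  again <- extend_to_bulk(ext, cyl_grid, cyl_spec)
  expect_equal(again$points, ext$points)
  expect_null(attr(again, "unextended"))
})

test_that("a sealed terminus is flagged, not silently extended", {
  blocked <- make_channel_structure(length = 30, lumen_radius = 3,
                                    blockers = data.frame(R = 26,
                                                          radius = 0))
  spec <- search_spec(blocked$seed_selector, probe_radius = 0.9,
                      bulk = blocked$bulk)
  g <- build_grid(blocked$structure, spec)
  ## hand the extender a stub ending under the seal
  keep <- blocked$path$points[, 3] < 24
  stub <- protonpath:::.make_tunnel_path(
    blocked$path$points[keep, ], blocked$path$local_radius[keep],
    rep("truth", sum(keep)), 0.8)
  expect_warning(ext <- extend_to_bulk(stub, g, spec, max_extension = 8),
                 "unextended")
  expect_true("p" %in% attr(ext, "unextended"))
})

test_that("lining classification and radius profile match the fixture", {
  prof <- lining_profile(cyl_path, cyl$structure, contact_cutoff = 6)
  inside <- cyl_path$points[, 3] > 3 & cyl_path$points[, 3] < 27
  ## all-LEU lining: nonpolar contacts only
  expect_true(all(prof$n_nonpolar[inside] > 0))
  expect_true(all(prof$n_polar[inside] == 0))
  expect_true(all(prof$n_titratable[inside] == 0))
  expect_match(prof$residues[which(inside)[1]], "LEU")
  ## radius ~ lumen radius along the tube
  expect_lt(max(abs(prof$radius[inside] - 3)), 0.8)

  ## titratable lining is removed from the obstacle set for radius_lining
  tit <- make_channel_structure(length = 20, lumen_radius = 2.5,
                                lining = c("titratable", "nonpolar"))
  tp <- lining_profile(tit$path, tit$structure, contact_cutoff = 6)
  mid <- tp$R > 4 & tp$R < 16
  expect_true(any(tp$n_titratable[mid] > 0))
  expect_true(all(tp$radius_lining[mid] >= tp$radius[mid] - 1e-9))
  expect_gt(max(tp$radius_lining[mid] - tp$radius[mid]), 0.2)
})
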