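## Synthetic fixtures with known ground truth -------------------------------
##
## Every generator is deterministic given its seed and records its
## generating parameters (the ground truth) in metadata/attributes, so
## downstream tests never re-derive the truth by hand.

.class_resname <- c(polar = "SER", nonpolar = "LEU", titratable = "LYS")

## dense centreline samples for the three fixture geometries; z is the
## overall membrane normal except for the second arm of the L-bend.
.fixture_centerline <- function(length, geometry, ds = 0.25) {
  if (geometry == "straight") {
    z <- seq(0, length, by = ds)
    cbind(x = 0, y = 0, z = z)
  } else if (geometry == "l_bend") {
    half <- length / 2
    s <- seq(0, length, by = ds)
    x <- ifelse(s <= half, 0, s - half)
    z <- ifelse(s <= half, s, half)
    cbind(x = x, y = 0, z = z)
  } else if (geometry == "s_curve") {
    z <- seq(0, length, length.out = ceiling(length / ds) + 1L)
    amp <- length / 8
    cbind(x = amp * sin(2 * pi * z / length), y = 0, z = z)
  } else stop("unknown geometry: ", geometry)
}

## distance from points (n x 3) to a polyline (m x 3), via nearest sample
.dist_to_polyline <- function(pts, line) {
  n <- nrow(pts)
  out <- numeric(n)
  ## chunked to bound memory
  chunk <- max(1L, floor(2e6 / nrow(line)))
  for (i0 in seq(1, n, by = chunk)) {
    ii <- i0:min(n, i0 + chunk - 1L)
    d2 <- outer(pts[ii, 1], line[, 1], "-")^2 +
      outer(pts[ii, 2], line[, 2], "-")^2 +
      outer(pts[ii, 3], line[, 3], "-")^2
    out[ii] <- sqrt(apply(d2, 1, min))
  }
  out
}

## orthonormal frame perpendicular to tangent t
.perp_frame <- function(t) {
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- c(t[2] * ref[3] - t[3] * ref[2],
          t[3] * ref[1] - t[1] * ref[3],
          t[1] * ref[2] - t[2] * ref[1])
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(t[2] * n1[3] - t[3] * n1[2],
          t[3] * n1[1] - t[1] * n1[3],
          t[1] * n1[2] - t[2] * n1[1])
  list(n1 = n1, n2 = n2)
}

#' Generate a channel-bearing pseudo-structure
#'
#' Builds a solid block of uncharged pseudo-atoms (vdW radius 1.7 Angstrom,
#' on a 2 Angstrom lattice) with a tube of the requested lumen radius bored
#' along a straight, L-bent or S-curved centreline, plus rings of wall
#' atoms placed at exactly `lumen_radius + 1.7` from the centreline so the
#' analytic clearance on the axis equals `lumen_radius`. Optional blockers
#' narrow the lumen to a stated radius at a stated channel coordinate. Wall
#' atoms are grouped into pseudo-residues of ~3 Angstrom along the channel,
#' named after the requested lining classes (SER = polar, LEU = nonpolar,
#' LYS = titratable). A zero-radius seed pseudo-atom (chain `"X"`, resid
#' 9999) marks the channel midpoint for the search.
#'
#' @param length channel length, Angstrom. Default 40.
#' @param lumen_radius lumen (clearance) radius, Angstrom; must exceed
#'   0.3 (narrower lumens fall below the wall-atom packing artifacts).
#' @param geometry `"straight"`, `"l_bend"` or `"s_curve"`.
#' @param lining vector of classes (`"polar"`, `"nonpolar"`,
#'   `"titratable"`) recycled along the channel.
#' @param blockers optional data.frame with columns `R` (channel
#'   coordinate, Angstrom) and `radius` (narrowed lumen, Angstrom >= 0).
#' @param wall_pad solid wall thickness around the bore, Angstrom.
#' @return list: `structure` (a [structure_model()]), `path` (ground-truth
#'   `TunnelPath` along the analytic centreline), `seed_selector`
#'   (`"X:9999"`), `bulk` (a [bulk_slabs()] matching the exit faces) and
#'   `lumen_radius`.
#' @export
make_channel_structure <- function(length = 40, lumen_radius = 3,
                                   geometry = c("straight", "l_bend",
                                                "s_curve"),
                                   lining = "nonpolar", blockers = NULL,
                                   wall_pad = 4) {
  geometry <- match.arg(geometry)
  if (lumen_radius <= 0.3)
    stop("lumen narrower than wall-atom packing artifacts (need > 0.3 A)")
  r_wall <- 1.7
  lattice_a <- 2.0
  bore <- lumen_radius + r_wall
  line <- .fixture_centerline(length, geometry)
  s <- c(0, cumsum(sqrt(rowSums(diff(line)^2))))
  ## lattice block around the centreline
  lo <- apply(line, 2, min) - (bore + wall_pad)
  hi <- apply(line, 2, max) + (bore + wall_pad)
  gx <- seq(lo[1], hi[1], by = lattice_a)
  gy <- seq(lo[2], hi[2], by = lattice_a)
  gz <- seq(lo[3], hi[3], by = lattice_a)
  lat <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  ## open the two exit faces: drop lattice atoms beyond the end planes
  t_start <- line[2, ] - line[1, ]
  t_start <- t_start / sqrt(sum(t_start^2))
  nl <- nrow(line)
  t_end <- line[nl, ] - line[nl - 1, ]
  t_end <- t_end / sqrt(sum(t_end^2))
  keep <- as.vector((lat - matrix(line[1, ], nrow(lat), 3,
                                  byrow = TRUE)) %*% t_start) >= 0 &
    as.vector((lat - matrix(line[nl, ], nrow(lat), 3,
                            byrow = TRUE)) %*% t_end) <= 0
  lat <- lat[keep, , drop = FALSE]
  d <- .dist_to_polyline(lat, line)
  lat <- lat[d >= bore + 0.05, , drop = FALSE]
  ## rings pinning the lumen radius, every 1 A of arc length
  ring_idx <- vapply(seq(0, max(s), by = 1),
                     function(si) which.min(abs(s - si)), integer(1))
  ring_pts <- NULL
  ring_s <- NULL
  add_ring <- function(center, tangent, radius) {
    fr <- .perp_frame(tangent)
    nang <- max(8L, ceiling(2 * pi * radius / 1.0))
    ang <- 2 * pi * (seq_len(nang) - 1L) / nang
    (outer(cos(ang), fr$n1) + outer(sin(ang), fr$n2)) * radius +
      matrix(center, nang, 3, byrow = TRUE)
  }
  for (ri in ring_idx) {
    i0 <- max(1L, ri - 1L)
    i1 <- min(nl, ri + 1L)
    tg <- line[i1, ] - line[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    rp <- add_ring(line[ri, ], tg, bore)
    ring_pts <- rbind(ring_pts, rp)
    ring_s <- c(ring_s, rep(s[ri], nrow(rp)))
  }
  ## drop ring atoms that protrude into the lumen elsewhere along the
  ## centreline (inner corners of bent geometries)
  if (!is.null(ring_pts)) {
    ok <- .dist_to_polyline(ring_pts, line) >= bore - 1e-6
    ring_pts <- ring_pts[ok, , drop = FALSE]
    ring_s <- ring_s[ok]
  }
  ## ground-truth radius profile
  truth_r <- rep(lumen_radius, nl)
  ## blockers: a disc of atoms narrowing the lumen at coordinate R
  if (!is.null(blockers)) {
    for (bi in seq_len(nrow(blockers))) {
      Rb <- blockers$R[bi]
      rb <- blockers$radius[bi]
      if (rb < 0) stop("blocker radius must be >= 0")
      ci <- which.min(abs(s - Rb))
      i0 <- max(1L, ci - 1L)
      i1 <- min(nl, ci + 1L)
      tg <- line[i1, ] - line[i0, ]
      tg <- tg / sqrt(sum(tg^2))
      for (rr in seq(rb + r_wall, bore + lattice_a, by = 1.2)) {
        rp <- add_ring(line[ci, ], tg, rr)
        ring_pts <- rbind(ring_pts, rp)
        ring_s <- c(ring_s, rep(s[ci], nrow(rp)))
      }
      truth_r[abs(s - s[ci]) < 1e-9] <- rb
    }
  }
  wall <- rbind(lat, ring_pts)
  ## arc-length coordinate of each wall atom, for residue binning
  wall_s <- c(s[.dist2_to_line_idx(lat, line)[, 1]], ring_s)
  bin <- pmin(floor(wall_s / 3) + 1L, ceiling(max(s) / 3))
  classes <- rep(lining, length.out = max(bin))
  resn <- .class_resname[classes]
  n <- nrow(wall)
  atoms <- data.frame(
    serial = seq_len(n), name = "C", resname = resn[bin],
    resid = bin, chain = "W",
    x = wall[, 1], y = wall[, 2], z = wall[, 3],
    vdw_radius = r_wall, charge = 0,
    is_heavy = TRUE, is_solvent = FALSE, stringsAsFactors = FALSE)
  seed_xyz <- line[which.min(abs(s - max(s) / 2)), ]
  atoms <- rbind(atoms, data.frame(
    serial = n + 1L, name = "S", resname = "SED", resid = 9999L,
    chain = "X", x = seed_xyz[1], y = seed_xyz[2], z = seed_xyz[3],
    vdw_radius = 0, charge = 0, is_heavy = TRUE, is_solvent = FALSE,
    stringsAsFactors = FALSE))
  struct <- structure_model(atoms)
  bulk <- if (geometry == "l_bend")
    bulk_slabs(n_axis = "z", n_side = "min", p_axis = "x", p_side = "max")
  else bulk_slabs()
  path <- .make_tunnel_path(line, truth_r,
                            segments = rep("truth", nl), spacing = NA_real_)
  list(structure = struct, path = path, seed_selector = "X:9999",
       bulk = bulk, lumen_radius = lumen_radius)
}

## index of nearest centreline sample for each point (chunked)
.dist2_to_line_idx <- function(pts, line) {
  n <- nrow(pts)
  out <- integer(n)
  chunk <- max(1L, floor(2e6 / nrow(line)))
  for (i0 in seq(1, n, by = chunk)) {
    ii <- i0:min(n, i0 + chunk - 1L)
    d2 <- outer(pts[ii, 1], line[, 1], "-")^2 +
      outer(pts[ii, 2], line[, 2], "-")^2 +
      outer(pts[ii, 3], line[, 3], "-")^2
    out[ii] <- max.col(-d2, "first")
  }
  matrix(out, ncol = 1)
}

#' Generate a water trajectory with known occupancy
#'
#' Adds one water slot (an oxygen pseudo-atom, resname `HOH`) per channel
#' grid point to the structure and, independently per frame and per point,
#' places the water at its grid point with the target probability (parked
#' far outside the channel otherwise). Placement is i.i.d. across frames,
#' so realized occupancy converges to the targets at the binomial rate.
#'
#' The slot grid step must exceed the capture radius used downstream;
#' otherwise a water placed for one coordinate also falls inside the
#' capture sphere of its neighbours and the measured occupancy becomes the
#' union probability rather than the per-point target. The default step of
#' 5 Angstrom keeps slots independent for the standard 2 Angstrom capture
#' radius; pass the same `step` to [water_occupancy()] when checking
#' recovery.
#'
#' @param fixture a [make_channel_structure()] result (or any list with
#'   `structure` and `path`).
#' @param occupancy_profile target occupancy fractions in \[0, 1\], one per
#'   channel grid point (length must match the `step` grid), or a scalar.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param step channel grid step, Angstrom (must match the step used in
#'   [water_occupancy()] and exceed its capture radius). Default 5.
#' @return list: `structure` (augmented with waters), `trajectory`, and
#'   `targets` (the per-point target occupancies, also stored in
#'   `attr(trajectory, "targets")`).
#' @export
make_water_trajectory <- function(fixture, occupancy_profile, n_frames,
                                  seed = 1L, step = 5) {
  rs <- resample_path(fixture$path, step)
  m <- nrow(rs$points)
  targets <- rep(occupancy_profile, length.out = m)
  if (any(targets < 0 | targets > 1))
    stop("target occupancies must lie in [0, 1]")
  a <- fixture$structure$atoms
  n0 <- nrow(a)
  waters <- data.frame(
    serial = n0 + seq_len(m), name = "O", resname = "HOH",
    resid = 5000L + seq_len(m), chain = "S",
    x = 0, y = 0, z = 0, vdw_radius = 1.52, charge = 0,
    is_heavy = TRUE, is_solvent = TRUE, stringsAsFactors = FALSE)
  struct <- structure_model(rbind(a, waters))
  park <- cbind(900 + 10 * seq_len(m), 900, 900)
  base <- coords(fixture$structure)
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    present <- stats::runif(m) < targets
    w <- park
    w[present, ] <- rs$points[present, , drop = FALSE]
    frames[[f]] <- rbind(base, w)
  }
  traj <- trajectory(frames, frame_interval = 0.1, replica_id = 1L)
  attr(traj, "targets") <- targets
  list(structure = struct, trajectory = traj, targets = targets)
}

#' Generate a point-charge system
#'
#' Pseudo-atoms with stated partial charges and zero vdW radius (so they
#' never act as channel obstacles), for electric-field tests with
#' closed-form expectations.
#'
#' @param positions n x 3 matrix, Angstrom.
#' @param charges length-n charges, elementary charge units.
#' @param box optional periodic cell lengths.
#' @return A [structure_model()].
#' @export
make_charge_system <- function(positions, charges, box = NULL) {
  positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  if (length(charges) != n) stop("one charge per position required")
  atoms <- data.frame(
    serial = seq_len(n), name = "Q", resname = "CHG",
    resid = seq_len(n), chain = "Q",
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    vdw_radius = 0, charge = charges,
    is_heavy = TRUE, is_solvent = FALSE, stringsAsFactors = FALSE)
  structure_model(atoms, box = box)
}

#' Reference Coulomb field (independent oracle)
#'
#' Plain double-loop direct Coulomb sum over the charges of a structure,
#' deliberately independent of the vectorised [electric_field()] code
#' path, for cross-checking. Vacuum permittivity, V/Angstrom.
#'
#' @param structure a `StructureModel` (typically from
#'   [make_charge_system()]).
#' @param points m x 3 query points, Angstrom.
#' @param exclusion_radius omit sources closer than this, Angstrom.
#' @return m x 3 matrix of field vectors, V/Angstrom.
#' @export
reference_coulomb_field <- function(structure, points,
                                    exclusion_radius = 0) {
  points <- matrix(points, ncol = 3)
  a <- structure$atoms[!structure$atoms$is_solvent, , drop = FALSE]
  out <- matrix(0, nrow(points), 3)
  for (i in seq_len(nrow(points))) {
    E <- c(0, 0, 0)
    for (j in seq_len(nrow(a))) {
      dvec <- c(points[i, 1] - a$x[j], points[i, 2] - a$y[j],
                points[i, 3] - a$z[j])
      if (!is.null(structure$box))
        dvec <- dvec - structure$box * round(dvec / structure$box)
      r <- sqrt(sum(dvec^2))
      if (r <= exclusion_radius || r == 0) next
      E <- E + .const$ke_VA_e * a$charge[j] * dvec / r^3
    }
    out[i, ] <- E
  }
  out
}

#' Generate a synthetic pyranine (HPTS) trace
#'
#' Inside-liposome pH is constant at `initial_pH` until the ATP addition at
#' `event_time`, then approaches `initial_pH - delta_pH` exponentially with
#' rate `k`. Gaussian noise of `noise_sd` (pH units) is added, and the pH
#' series is inverted through the calibration to I460/I405 intensity pairs
#' (I405 held constant at 100). Generating parameters land in the trace
#' metadata.
#'
#' @param delta_pH generating pH drop.
#' @param k exponential rate constant, 1/s. Default 0.01.
#' @param initial_pH baseline pH. Default 8.
#' @param event_time ATP addition time, s. Default 60.
#' @param duration total length, s. Default 420 (7 min assay).
#' @param sample_interval s. Default 0.6 (instrument resolution).
#' @param noise_sd pH noise SD. Default 0.002.
#' @param calib a `PyranineCalibration`. Default: the fixed
#'   a = 1.931, b = 7.926 calibration.
#' @param seed RNG seed.
#' @return An [assay_trace()] with channels `I405`, `I460`.
#' @export
make_pyranine_trace <- function(delta_pH, k = 0.01, initial_pH = 8,
                                event_time = 60, duration = 420,
                                sample_interval = 0.6, noise_sd = 0.002,
                                calib = pyranine_calibration(1.931, 7.926),
                                seed = 1L) {
  t <- seq(0, duration, by = sample_interval)
  pH <- ifelse(t < event_time, initial_pH,
               (initial_pH - delta_pH) +
                 delta_pH * exp(-k * (t - event_time)))
  set.seed(seed)
  pH <- pH + stats::rnorm(length(t), sd = noise_sd)
  I405 <- rep(100, length(t))
  I460 <- I405 * 10^((pH - calib$b) / calib$a)
  assay_trace(t, list(I405 = I405, I460 = I460),
              sample_interval = sample_interval,
              metadata = list(true_delta_pH = delta_pH, true_k = k,
                              initial_pH = initial_pH,
                              event_time = event_time,
                              noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic oxonol VI stopped-flow trace
#'
#' Membrane potential rises linearly at `rate` for `linear_duration`
#' seconds after mixing, then saturates exponentially toward `plateau`
#' (slope-continuous), emulating ATP-synthase-driven potential buildup.
#' The potential is inverted through the calibration to A588/A625 pairs
#' (A625 held at 0.5). Noise is Gaussian in mV.
#'
#' @param rate initial rate, mV/s.
#' @param plateau saturating potential, mV. Default 150.
#' @param linear_duration length of the strictly linear phase, s.
#'   Default 2 (covers the 1 s initial-rate window).
#' @param duration s. Default 20 (monitoring time).
#' @param sample_interval s. Default 0.002 (stopped-flow resolution).
#' @param noise_sd mV. Default 1.
#' @param calib a `PsiCalibration`. Default slope 2000 mV/AU,
#'   intercept 0.
#' @param seed RNG seed.
#' @return An [assay_trace()] with channels `A588`, `A625`.
#' @export
make_oxonol_trace <- function(rate, plateau = 150, linear_duration = 2,
                              duration = 20, sample_interval = 0.002,
                              noise_sd = 1,
                              calib = psi_calibration(2000, 0),
                              seed = 1L) {
  t <- seq(0, duration, by = sample_interval)
  psi_lin_end <- rate * linear_duration
  psi <- rate * t
  if (rate > 0 && plateau > psi_lin_end) {
    k2 <- rate / (plateau - psi_lin_end)
    late <- t > linear_duration
    psi[late] <- plateau - (plateau - psi_lin_end) *
      exp(-k2 * (t[late] - linear_duration))
  } else if (rate > 0) {
    psi <- pmin(psi, plateau)
  }
  set.seed(seed)
  psi <- psi + stats::rnorm(length(t), sd = noise_sd)
  dA <- (psi - calib$intercept) / calib$slope
  A625 <- rep(0.5, length(t))
  assay_trace(t, list(A588 = A625 + dA, A625 = A625),
              sample_interval = sample_interval,
              metadata = list(true_rate = rate, plateau = plateau,
                              linear_duration = linear_duration,
                              noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic oxygraph trace
#'
#' Oxygen concentration declines linearly at `rate` from `o2_start` until
#' `break_time` (substrate or O2 exhausted), then stays flat, with Gaussian
#' noise — the piecewise shape the automatic linear-range detection must
#' handle.
#'
#' @param rate consumption rate, concentration units/s (positive).
#' @param o2_start starting concentration. Default 250.
#' @param break_time end of the linear phase, s. Default 120.
#' @param duration s. Default 180.
#' @param sample_interval s. Default 1.
#' @param noise_sd concentration units. Default 0.5.
#' @param seed RNG seed.
#' @return An [assay_trace()] with channel `O2`.
#' @export
make_o2_trace <- function(rate, o2_start = 250, break_time = 120,
                          duration = 180, sample_interval = 1,
                          noise_sd = 0.5, seed = 1L) {
  t <- seq(0, duration, by = sample_interval)
  o2 <- pmax(o2_start - rate * pmin(t, break_time), 0)
  set.seed(seed)
  o2 <- o2 + stats::rnorm(length(t), sd = noise_sd)
  assay_trace(t, list(O2 = o2), sample_interval = sample_interval,
              metadata = list(true_rate = rate, break_time = break_time,
                              noise_sd = noise_sd, seed = seed))
}
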