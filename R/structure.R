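## Structure and trajectory containers -------------------------------------

#' Construct a StructureModel
#'
#' A `StructureModel` holds an atom table (coordinates in Angstrom, van der
#' Waals radii, partial charges, residue labels) plus an optional periodic
#' box. It is the common input of the channel search, hydration and
#' electric-field stages.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `resid`, `chain`, `x`, `y`, `z`, `vdw_radius`, `charge`, `is_heavy`,
#'   `is_solvent`.
#' @param box optional numeric length-3 vector of periodic cell lengths
#'   (Angstrom); when present, distance computations downstream use the
#'   minimum-image convention.
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms, box = NULL) {
  required <- c("serial", "name", "resname", "resid", "chain",
                "x", "y", "z", "vdw_radius", "charge",
                "is_heavy", "is_solvent")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique")
  if (any(atoms$is_heavy & !(atoms$vdw_radius >= 0)))
    stop("heavy atoms must have non-negative vdW radii")
  ## one residue name per (chain, resid)
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  nm <- tapply(atoms$resname, key, function(v) length(unique(v)))
  if (any(nm > 1L))
    stop("residue identity conflict: a (chain, resid) pair maps to more ",
         "than one residue name")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive cell lengths (Angstrom)")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, box = box), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("StructureModel: %d atoms, %d residues%s\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              if (is.null(x$box)) "" else
                sprintf(", periodic box %.1f x %.1f x %.1f A",
                        x$box[1], x$box[2], x$box[3])))
  cat(sprintf("  heavy: %d, solvent: %d, charged (|q|>0): %d\n",
              sum(a$is_heavy), sum(a$is_solvent), sum(a$charge != 0)))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param structure a `StructureModel`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Construct a Trajectory
#'
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom), one per
#'   frame; all frames must have the same atom count.
#' @param frame_interval time between frames, ns; must be > 0.
#' @param replica_id integer replicate index (simulations are typically run
#'   in triplicate; this indexes the replicate).
#' @return Object of class `Trajectory`.
#' @export
trajectory <- function(frames, frame_interval = 1, replica_id = 1L) {
  if (length(frames) == 0L) stop("trajectory needs at least one frame")
  nat <- vapply(frames, nrow, integer(1))
  if (length(unique(nat)) != 1L)
    stop("all frames must have the same atom count")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(frames = frames, frame_interval = frame_interval,
                 replica_id = as.integer(replica_id)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %g ns, replica %d\n",
              length(x$frames), nrow(x$frames[[1]]), x$frame_interval,
              x$replica_id))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

## PDB input ----------------------------------------------------------------

.default_solvent_resnames <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "SPC")

.element_from_name <- function(name, resname, solvent) {
  ## strip digits/primes, take leading element symbol; two-letter symbols
  ## only for common ions to avoid CA (calcium) vs CA (C-alpha) confusion
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  ion_res <- resname %in% c("NA", "CL", "K", "MG", "ZN", "FE", "BR", "I")
  el[ion_res & two %in% names(.bondi_radii)] <- two[ion_res &
                                                    two %in% names(.bondi_radii)]
  el
}

#' Read a protein structure from a PDB file
#'
#' Parses PDB coordinates (via the bio3d reader) and resolves per-atom van
#' der Waals radii and partial charges. With a side table (CSV with columns
#' `resname`, `name`, `vdw_radius`, `charge`) every non-solvent atom must
#' resolve through the table, otherwise an error names the offending
#' residue/atom. Without a side table, radii come from the bundled Bondi
#' element set ([default_vdw_radii()]) and charges default to zero.
#'
#' @param path PDB file.
#' @param charge_table optional CSV path mapping (resname, atom name) to
#'   (vdw_radius, charge).
#' @param solvent_resnames residue names flagged as solvent.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, charge_table = NULL,
                           solvent_resnames = .default_solvent_resnames) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  is_solv <- a$resid %in% solvent_resnames
  el <- .element_from_name(a$elety, a$resid, is_solv)
  is_heavy <- el != "H"
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, resname = a$resid,
    resid = a$resno, chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    vdw_radius = NA_real_, charge = 0,
    is_heavy = is_heavy, is_solvent = is_solv,
    stringsAsFactors = FALSE)
  if (!is.null(charge_table)) {
    tab <- read.csv(charge_table, stringsAsFactors = FALSE)
    need <- c("resname", "name", "vdw_radius", "charge")
    if (!all(need %in% names(tab)))
      stop("charge table must have columns: ", paste(need, collapse = ", "))
    key <- paste(atoms$resname, atoms$name)
    idx <- match(key, paste(tab$resname, tab$name))
    unresolved <- which(is.na(idx) & !atoms$is_solvent)
    if (length(unresolved) > 0L) {
      u <- atoms[unresolved[1], ]
      stop(sprintf(
        "atom %s of residue %s %d (chain %s) not found in charge table",
        u$name, u$resname, u$resid, u$chain))
    }
    ok <- !is.na(idx)
    atoms$vdw_radius[ok] <- tab$vdw_radius[idx[ok]]
    atoms$charge[ok] <- tab$charge[idx[ok]]
    ## solvent atoms absent from the table get element radii, zero charge
    miss <- which(is.na(idx))
    atoms$vdw_radius[miss] <- unname(.bondi_radii[el[miss]])
  } else {
    r <- unname(.bondi_radii[el])
    if (anyNA(r)) {
      bad <- which(is.na(r))[1]
      stop(sprintf("no default vdW radius for atom %s (element '%s') of %s %d",
                   atoms$name[bad], el[bad], atoms$resname[bad],
                   atoms$resid[bad]))
    }
    atoms$vdw_radius <- r
  }
  structure_model(atoms)
}

#' Write a StructureModel to a PDB file
#'
#' Coordinates go to a standard PDB; radii and charges, which PDB does not
#' carry, can be written to a companion CSV side table readable back by
#' [read_structure()].
#'
#' @param structure a `StructureModel`.
#' @param path output PDB path.
#' @param charge_table optional CSV path for the (resname, name) ->
#'   (vdw_radius, charge) side table.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, charge_table = NULL) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain)
  if (!is.null(charge_table)) {
    tab <- unique(data.frame(resname = a$resname, name = a$name,
                             vdw_radius = a$vdw_radius, charge = a$charge,
                             stringsAsFactors = FALSE))
    write.csv(tab, charge_table, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL block becomes one frame. The atom count of every frame must
#' match `structure`. Binary trajectory dialects are out of scope of the
#' core reader; convert to multi-model PDB or construct a [trajectory()]
#' directly from coordinate matrices.
#'
#' @param path multi-model PDB file.
#' @param structure the `StructureModel` the frames belong to.
#' @param frame_interval ns between frames.
#' @param replica_id replicate index.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, structure, frame_interval = 1,
                            replica_id = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  if (nat != nrow(structure$atoms))
    stop(sprintf("trajectory has %d atoms per frame, structure has %d",
                 nat, nrow(structure$atoms)))
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  trajectory(frames, frame_interval = frame_interval,
             replica_id = replica_id)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `Trajectory`.
#' @param structure the matching `StructureModel` (atom labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, structure, path) {
  a <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$frames[[f]]
    lines <- sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      a$serial %% 100000L,
      ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
      a$resname, substr(a$chain, 1, 1), a$resid %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## Residue selectors --------------------------------------------------------

#' Resolve residue selector strings
#'
#' Selectors are either `"chain:resid"` (e.g. `"A:329"`) or
#' `"RESNAME+resid"` (e.g. `"LYS+329"`, any chain).
#'
#' @param structure a `StructureModel`.
#' @param selectors character vector of selectors.
#' @return logical vector over atoms: TRUE where the atom belongs to a
#'   selected residue.
#' @export
resolve_residues <- function(structure, selectors) {
  a <- structure$atoms
  hit <- rep(FALSE, nrow(a))
  for (s in selectors) {
    if (grepl(":", s, fixed = TRUE)) {
      parts <- strsplit(s, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("bad selector: ", s)
      m <- a$chain == parts[1] & a$resid == as.integer(parts[2])
    } else if (grepl("+", s, fixed = TRUE)) {
      parts <- strsplit(s, "+", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("bad selector: ", s)
      m <- a$resname == toupper(parts[1]) & a$resid == as.integer(parts[2])
    } else {
      stop("bad selector (expected 'chain:resid' or 'RESNAME+resid'): ", s)
    }
    hit <- hit | m
  }
  hit
}

## Minimum-image displacement helper shared by hydration/field stages.
## disp: n x 3 raw displacement; box NULL or length-3.
.min_image <- function(disp, box) {
  if (is.null(box)) return(disp)
  for (k in 1:3) disp[, k] <- disp[, k] - box[k] * round(disp[, k] / box[k])
  disp
}
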