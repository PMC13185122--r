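# Trajectory container and topology/trajectory readers and writers.
# PDB parsing/writing and DCD reading are delegated to bio3d; the DCD
# writer (CHARMM 32-bit CORD format) is implemented here since bio3d
# only reads the format.

#' Construct a trajectory
#'
#' @param atoms an atom table (see [atom_table()]).
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param box optional `n_frames x 3` matrix of box lengths (Angstrom).
#' @return object of class `dln_trajectory`: list with elements `atoms`,
#'   `coords`, `times`, `box`.
#' @export
trajectory <- function(atoms, coords, times = NULL, box = NULL) {
  validate_atoms(atoms)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(atoms))
    stop("coordinate count (", dim(coords)[1], ") != atom count (", nrow(atoms), ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("length(times) != number of frames")
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times),
                 box = box),
            class = "dln_trajectory")
}

#' @export
print.dln_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames, t = %.4g..%.4g ns\n",
              dim(x$coords)[1], dim(x$coords)[3],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `dln_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an `n x 3` coordinate matrix
#' @param traj a `dln_trajectory`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  traj$coords[, , i, drop = TRUE]
}

#' Read a PDB topology into an atom table
#'
#' Parses ATOM/HETATM records; duplicated or non-contiguous serial
#' numbers are re-indexed 0..N-1 with a warning. Radii come from the
#' element table ([vdw_radii_default()]) with the element taken from the
#' PDB element column when present, otherwise guessed from the atom name.
#'
#' @param path PDB file.
#' @param radii named numeric radius overrides.
#' @return an atom table.
#' @export
read_topology <- function(path, radii = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  ele <- a$elesy
  if (is.null(ele) || all(is.na(ele)) || all(trimws(ele) == ""))
    ele <- guess_element(a$elety)
  ele <- ifelse(is.na(ele) | trimws(ele) == "", guess_element(a$elety), trimws(ele))
  resid <- trimws(a$resid)
  # CHARMM-style residue names may run to 5 characters, spilling into the
  # PDB chain column (this package's writers never emit chain ids):
  # rejoin a chain letter abutting a 4-character residue name
  spill <- !is.na(a$chain) & nchar(resid) == 4
  resid[spill] <- paste0(resid[spill], trimws(a$chain[spill]))
  if (anyDuplicated(a$eleno))
    warning("duplicated atom serial numbers; re-indexing 0..N-1")
  seg <- a$segid
  if (is.null(seg)) seg <- "MAIN"
  seg[is.na(seg) | trimws(seg) == ""] <- "MAIN"
  atom_table(atom_name = trimws(a$elety), element = ele,
             residue_name = resid, residue_id = a$resno,
             segment = seg, radii = radii)
}

#' Read a trajectory (multi-model PDB or DCD)
#'
#' @param path multi-model PDB (`MODEL`/`ENDMDL`) or CHARMM-style DCD.
#'   Format chosen by file extension (".dcd" vs anything else = PDB).
#' @param atoms atom table the frames must match.
#' @param frame_interval frame spacing in ns. Required for DCD (the
#'   format stores no physical time usable here); for PDB, defaults to
#'   1 ns per model.
#' @param check_bonds if TRUE (default), warn when any within-molecule
#'   nearest-neighbor atom pair exceeds 5 Angstrom in the first frame,
#'   a sign of wrapped (periodic-image) coordinates, which this package
#'   does not unwrap.
#' @return a `dln_trajectory`.
#' @export
read_trajectory <- function(path, atoms, frame_interval = NULL,
                            check_bonds = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_dcd <- grepl("\\.dcd$", path, ignore.case = TRUE)
  if (is_dcd) {
    if (is.null(frame_interval))
      stop("frame_interval (ns) is required when reading DCD")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(frame_interval)) frame_interval <- 1
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("frame atom count (", ncol(xyz) / 3, ") != atom table size (",
         nrow(atoms), ")")
  nf <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3L, nrow(atoms), nf)), c(2, 1, 3))
  traj <- trajectory(atoms, coords, times = (seq_len(nf) - 1) * frame_interval)
  if (check_bonds) check_molecule_gaps(traj)
  traj
}

# Warn if any atom sits > 5 A from every other atom of its molecule
# (first frame): the usual symptom of coordinates wrapped across a
# periodic boundary, which the analyses do not handle.
check_molecule_gaps <- function(traj, limit = 5) {
  fr <- get_frame(traj, 1)
  mol <- molecule_index(traj$atoms)
  for (m in split(seq_along(mol), mol)) {
    if (length(m) < 2) next
    d <- as.matrix(dist(fr[m, , drop = FALSE]))
    diag(d) <- Inf
    if (any(apply(d, 1, min) > limit)) {
      warning("an atom lies more than ", limit, " A from the rest of its ",
              "molecule; coordinates may be wrapped across periodic boundaries")
      return(invisible(FALSE))
    }
  }
  invisible(TRUE)
}

#' Write a topology / trajectory as (multi-model) PDB
#'
#' Fixed-width ATOM records (CHARMM-style 4-character residue names in
#' columns 18-21, segment id in 73-76, element in 77-78), occupancy
#' 1.00, B-factor 0.00; one MODEL/ENDMDL block per frame when more than
#' one frame is present.
#'
#' @param traj a `dln_trajectory` (or single frame via [trajectory()]).
#' @param path output file.
#' @export
write_pdb <- function(traj, path) {
  nf <- n_frames(traj)
  a <- traj$atoms
  # short atom names start at column 14, per convention
  nm <- ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name)
  con <- file(path, "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-5s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
      (a$atom_id %% 99999L) + 1L, nm, substr(a$residue_name, 1, 5),
      a$residue_id %% 10000L,
      fr[, 1], fr[, 2], fr[, 3], 1, 0, a$segment,
      substr(a$element, 1, 2)), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as CHARMM-format DCD
#'
#' 32-bit CORD-header DCD as produced by CHARMM/NAMD, single precision.
#'
#' @param traj a `dln_trajectory`.
#' @param path output file.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  rec <- function(writer) {
    # Fortran unformatted record: length, payload, length
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf       # NSET
  icntrl[2] <- 1        # ISTART
  icntrl[3] <- 1        # NSAVC
  icntrl[20] <- 24      # CHARMM version flag
  rec(function(rc) {
    writeChar("CORD", rc, nchars = 4, eos = NULL)
    writeBin(as.integer(icntrl), rc, size = 4, endian = "little")
  })
  title <- sprintf("%-80s", "Written by dlntraj")
  rec(function(rc) {
    writeBin(1L, rc, size = 4, endian = "little")
    writeChar(title, rc, nchars = 80, eos = NULL)
  })
  rec(function(rc) writeBin(na, rc, size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    for (k in 1:3)
      rec(function(rc) writeBin(as.numeric(fr[, k]), rc, size = 4,
                                endian = "little"))
  }
  invisible(path)
}
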