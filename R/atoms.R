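# Atom tables and the element -> van der Waals radius default table.

#' Default van der Waals radii (Angstrom)
#'
#' Frozen element-to-radius table used to assign radii when reading a
#' topology. Values are the Bondi radii for the elements occurring in
#' lipid/PEG/DNA systems. Override individual entries via the
#' `radii` argument of [read_topology()] or [atom_table()].
#'
#' @return Named numeric vector, names are element symbols.
#' @export
vdw_radii_default <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, MG = 1.73,
    K = 2.75, ZN = 1.39)
}

#' Construct an atom table
#'
#' The atom table is the per-atom identity record shared by all analyses:
#' one row per atom with 0-based contiguous `atom_id`, atom name, element,
#' residue (species) name, residue id, segment id and van der Waals radius.
#'
#' @param atom_name character atom names (e.g. "C2", "P").
#' @param element character element symbols; if `NULL`, guessed from the
#'   first alphabetic character of the atom name.
#' @param residue_name character species keys (e.g. "DMPC").
#' @param residue_id integer residue numbers; together with `residue_name`
#'   and `segment` these identify a molecule instance.
#' @param segment character segment ids (recycled).
#' @param radii named numeric overrides/additions to [vdw_radii_default()].
#' @return data.frame of class `dln_atoms` with columns `atom_id`,
#'   `atom_name`, `element`, `residue_name`, `residue_id`, `segment`,
#'   `vdw_radius`.
#' @export
atom_table <- function(atom_name, element = NULL, residue_name, residue_id,
                       segment = "MAIN", radii = NULL) {
  n <- length(atom_name)
  stopifnot(length(residue_name) == n, length(residue_id) == n)
  if (is.null(element)) element <- guess_element(atom_name)
  element <- toupper(element)
  tab <- vdw_radii_default()
  if (!is.null(radii)) tab[toupper(names(radii))] <- radii
  r <- unname(tab[element])
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "),
         "; supply via `radii`")
  }
  at <- data.frame(atom_id = seq_len(n) - 1L,
                   atom_name = as.character(atom_name),
                   element = element,
                   residue_name = as.character(residue_name),
                   residue_id = as.integer(residue_id),
                   segment = rep_len(as.character(segment), n),
                   vdw_radius = r,
                   stringsAsFactors = FALSE)
  class(at) <- c("dln_atoms", "data.frame")
  at
}

guess_element <- function(atom_name) {
  e <- sub("^[0-9']*", "", toupper(atom_name))
  # two-letter elements common in these systems
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "NA"), two, one)
}

#' Unique molecule key for each atom
#'
#' @param atoms an atom table.
#' @return integer vector: atoms sharing a (segment, residue_name,
#'   residue_id) triple share a molecule index.
#' @export
molecule_index <- function(atoms) {
  key <- paste(atoms$segment, atoms$residue_name, atoms$residue_id, sep = "\r")
  match(key, unique(key))
}

validate_atoms <- function(atoms) {
  stopifnot(inherits(atoms, "data.frame"))
  n <- nrow(atoms)
  if (!identical(atoms$atom_id, seq_len(n) - 1L))
    stop("atom_ids must be contiguous from 0")
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0))
    stop("every atom needs a positive vdw_radius")
  invisible(atoms)
}

#' @export
print.dln_atoms <- function(x, ...) {
  cat(sprintf("Atom table: %d atoms, %d molecules, species: %s\n",
              nrow(x), max(molecule_index(x)),
              paste(unique(x$residue_name), collapse = ", ")))
  invisible(x)
}
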