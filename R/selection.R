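# Selection configuration: species -> reference atom, motif classes, roles.

#' Selection configuration
#'
#' Maps residue species to their role in the analysis (`lipid`,
#' `detergent`, `polymer`, `scaffold`), the per-lipid reference atom
#' (default "C2", the glycerol-backbone carbon used as the headgroup
#' proxy throughout), tail atom names, and named motif classes.
#' Head motif classes (`choline`, `phosphate`, `glycerol`, `ester`) and
#' occluder motif classes (`methylene`, `oxygen`, `linker`) are disjoint
#' atom-name sets within a species.
#'
#' @param species named list; each entry a list with elements
#'   `role` (one of lipid/detergent/polymer/scaffold),
#'   `reference_atom` (default "C2"), `tails` (character),
#'   `motifs` (named list of character atom-name vectors).
#' @return object of class `dln_selection`.
#' @export
selection_config <- function(species) {
  stopifnot(is.list(species), length(names(species)) == length(species))
  for (sp in names(species)) {
    e <- species[[sp]]
    if (is.null(e$role)) stop("species ", sp, " lacks a role")
    if (!e$role %in% c("lipid", "detergent", "polymer", "scaffold"))
      stop("unknown role for species ", sp, ": ", e$role)
    if (is.null(e$reference_atom)) species[[sp]]$reference_atom <- "C2"
    if (is.null(e$tails)) species[[sp]]$tails <- character()
    if (is.null(e$motifs)) species[[sp]]$motifs <- list()
    m <- species[[sp]]$motifs
    all_names <- unlist(m, use.names = FALSE)
    if (anyDuplicated(all_names))
      stop("motif classes of species ", sp, " are not disjoint")
  }
  structure(list(species = species), class = "dln_selection")
}

#' Default selection configuration for the synthetic nanodisc system
#'
#' Matches the atom naming of the synthetic-membrane generator:
#' lipids carry N (amine/choline), P (phosphate, absent in DMTAP),
#' O21 (ester oxygen), C2 (reference) and tail carbons C3A/C4A/C5A;
#' DTAB is a single-tail cationic detergent; PEG chains alternate
#' methylene carbons (CP) and ether oxygens (OP) with linker carbons (CL).
#'
#' @return a `dln_selection`.
#' @export
default_selection <- function() {
  lip <- function(phosphate, choline) {
    m <- list(glycerol = "C2", ester = "O21")
    if (phosphate) m$phosphate <- "P"
    if (choline) m$choline <- "N"
    list(role = "lipid", reference_atom = "C2",
         tails = c("C3A", "C4A", "C5A", "C6A", "C3B", "C4B", "C5B", "C6B"),
         motifs = m)
  }
  selection_config(list(
    DMPC = lip(TRUE, TRUE),
    DMTAP = lip(FALSE, TRUE),
    DMPE = lip(TRUE, FALSE),
    DTAB = list(role = "detergent", reference_atom = "C2",
                tails = c("C3A", "C4A"),
                motifs = list(choline = "N")),
    PEG = list(role = "polymer", reference_atom = "CP",
               tails = character(),
               motifs = list(methylene = "CP", oxygen = "OP", linker = "CL"))
  ))
}

sel_species <- function(sel, roles) {
  names(Filter(function(e) e$role %in% roles, sel$species))
}

#' Resolve atom index sets from a selection configuration
#'
#' @param atoms atom table.
#' @param sel a `dln_selection`.
#' @param what one of "reference" (per-lipid reference atoms), "tails",
#'   or a motif class name (e.g. "methylene").
#' @param roles restrict to species with these roles (default: lipid).
#' @param species restrict to these species (default: all with the role).
#' @return integer vector of 1-based row indices into `atoms`.
#' @export
select_atoms <- function(atoms, sel, what = "reference",
                         roles = c("lipid"), species = NULL) {
  sps <- if (is.null(species)) sel_species(sel, roles) else species
  idx <- integer()
  for (sp in sps) {
    e <- sel$species[[sp]]
    if (is.null(e)) stop("species ", sp, " not in selection config")
    nm <- switch(what,
                 reference = e$reference_atom,
                 tails = e$tails,
                 all = unique(atoms$atom_name[atoms$residue_name == sp]),
                 e$motifs[[what]])
    if (is.null(nm)) nm <- character()
    idx <- c(idx, which(atoms$residue_name == sp & atoms$atom_name %in% nm))
  }
  sort(idx)
}

#' All atoms of species with the given roles
#' @inheritParams select_atoms
#' @return integer vector of 1-based row indices.
#' @export
select_role_atoms <- function(atoms, sel, roles = "lipid") {
  sps <- sel_species(sel, roles)
  which(atoms$residue_name %in% sps)
}
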