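# Nanodisc design arithmetic: minicircle diameters from the base-pair
# count, PEG modification density per helical turn, and the lipid count
# needed to fill the ring.

#' Minicircle design parameters
#'
#' @param n_bp number of base pairs in the circle.
#' @param rise_per_bp helical rise (nm/bp, default 0.34, B-form DNA).
#' @param bp_per_turn base pairs per helical turn (default 10.5).
#' @param helix_width double-helix width (nm, default 2.0).
#' @param n_modifications number of PEG modifications on the circle.
#' @param area_per_lipid area per lipid (nm^2, default 0.684; this
#'   default is back-solved from the published 1:450 DNA:lipid
#'   stoichiometry, not an independently stated value).
#' @return list of class `dln_minicircle_design`.
#' @export
minicircle_design <- function(n_bp, rise_per_bp = 0.34, bp_per_turn = 10.5,
                              helix_width = 2.0, n_modifications = 0,
                              area_per_lipid = 0.684) {
  stopifnot(n_bp > 0, rise_per_bp > 0, bp_per_turn > 0, helix_width > 0,
            area_per_lipid > 0)
  structure(list(n_bp = n_bp, rise_per_bp = rise_per_bp,
                 bp_per_turn = bp_per_turn, helix_width = helix_width,
                 n_modifications = n_modifications,
                 area_per_lipid = area_per_lipid),
            class = "dln_minicircle_design")
}

#' Minicircle diameters
#'
#' Centerline diameter = contour length / pi = n_bp * rise / pi; outer
#' and inner diameters add/subtract the helix width. Full precision is
#' retained; values rounded to the nearest nm are reported alongside.
#'
#' @param design a [minicircle_design()].
#' @return list: `centerline`, `outer`, `inner` (nm) and
#'   `outer_nm`, `inner_nm` (nearest nm).
#' @export
minicircle_geometry <- function(design) {
  centerline <- design$n_bp * design$rise_per_bp / pi
  inner <- centerline - design$helix_width
  if (inner <= 0) stop("helix width >= centerline diameter: degenerate ring")
  outer <- centerline + design$helix_width
  list(centerline = centerline, outer = outer, inner = inner,
       outer_nm = round(outer), inner_nm = round(inner))
}

#' PEG modifications per helical turn
#'
#' @param n_modifications number of modifications on the circle.
#' @param n_bp base pairs in the circle.
#' @param bp_per_turn base pairs per helical turn (default 10.5).
#' @return modifications per turn.
#' @export
peg_density <- function(n_modifications, n_bp, bp_per_turn = 10.5) {
  stopifnot(n_bp > 0)
  n_modifications / (n_bp / bp_per_turn)
}

#' Lipids required to fill a minicircle
#'
#' Number of lipids filling the two leaflets of a bilayer disc spanning
#' the inner diameter: round(2 * pi * (d/2)^2 / APL), and the
#' corresponding DNA:lipid molar ratio.
#'
#' @param inner_diameter inner diameter (nm).
#' @param area_per_lipid area per lipid (nm^2).
#' @return list: `lipid_count`, `ratio` (string "1:count").
#' @export
lipid_fill <- function(inner_diameter, area_per_lipid = 0.684) {
  stopifnot(inner_diameter >= 0, area_per_lipid > 0)
  n <- round(2 * pi * (inner_diameter / 2)^2 / area_per_lipid)
  list(lipid_count = n, ratio = paste0("1:", n))
}

#' Characteristic spacing between lipids of one species
#'
#' Estimate of the typical nearest-neighbor distance of a species in one
#' leaflet: sqrt(leaflet area / per-leaflet species count). Provided as a
#' rough comparator for diffusion displacements; not a rigorously defined
#' observable.
#'
#' @param leaflet_area leaflet area (Angstrom^2).
#' @param n_species number of molecules of the species in the leaflet.
#' @return spacing (Angstrom).
#' @export
species_spacing <- function(leaflet_area, n_species) {
  stopifnot(leaflet_area > 0, n_species > 0)
  sqrt(leaflet_area / n_species)
}

#' Formatted design table
#'
#' @param design a [minicircle_design()].
#' @return data.frame of named design quantities with units.
#' @export
design_table <- function(design) {
  g <- minicircle_geometry(design)
  # the published stoichiometry computes the fill from the nm-rounded
  # inner diameter; the report layer does the same
  fill <- lipid_fill(g$inner_nm, design$area_per_lipid)
  data.frame(
    quantity = c("base pairs", "centerline diameter", "outer diameter",
                 "inner diameter", "PEG modifications",
                 "PEG per helical turn", "lipid fill count",
                 "DNA:lipid ratio"),
    value = c(design$n_bp, round(g$centerline, 2), g$outer_nm,
              g$inner_nm, design$n_modifications,
              round(peg_density(design$n_modifications, design$n_bp,
                                design$bp_per_turn), 3),
              fill$lipid_count, fill$ratio),
    units = c("bp", "nm", "nm", "nm", "", "1/turn", "lipids", ""),
    stringsAsFactors = FALSE)
}
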