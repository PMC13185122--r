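---
title: "Analysing DNA-corralled lipid nanodisc trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing DNA-corralled lipid nanodisc trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The system and the observables

A DNA-lipid nanodisc (DLN) is a discoidal lipid bilayer patch whose rim
is corralled by a covalently closed, PEG-functionalized double-stranded
DNA minicircle. The membrane mixes a zwitterionic lipid (DMPC) with a
cationic lipid (DMTAP) and a trace fluorescent-analog stand-in (DMPE);
a cationic detergent (DTAB) assists assembly. `dlntraj` implements the
trajectory-analysis protocol used to characterize such systems in
molecular-dynamics simulation:

* **surface occlusion** — how much of the lipid-tail solvent-accessible
  surface area (SASA) the PEG corona and detergent hide;
* **contacts** — motif-resolved atom-pair contact counts (PEG oxygens
  against cholines/phosphates, linkers against the glycerol region,
  methylenes against the tails);
* **leaflet and edge regionalization** — per-lipid leaflet labels, an
  in-plane distance from the bilayer edge derived from a volumetric
  surface, four-region composition fractions, and debounced flip
  counting;
* **bilayer geometry** — thickness from per-leaflet Gaussian fits to the
  C2 density profile, area per lipid, sphere-fit curvature, and the
  edge headgroup count;
* **lateral diffusion** — in-plane mean-square displacement (MSD) of
  the C2 atoms and diffusion coefficients;
* **the tilt collective variable** — the best-fit rotation of the C2
  atoms onto a reference decomposed into a spin about the bilayer
  normal and a tilt about an in-plane axis;
* **design arithmetic** — minicircle diameters from the base-pair
  count, PEG density per helical turn, and the lipid fill
  stoichiometry.

Throughout, the per-lipid reference point is the glycerol-backbone C2
atom, a conventional proxy for the headgroup position.

# Frame preprocessing

Every analysis assumes frames expressed in the bilayer's own axes.
`preprocess_align()` translates the center of mass of the lipid C2
atoms to the origin and rotates the principal axes of the C2 cloud onto
the Cartesian axes, mapping the smallest-extent axis to *z* (the
normal). Two conventions had to be fixed where the procedure is
under-determined:

* **Axis order.** Variance ordering (largest → *x*, smallest → *z*) is
  only meaningful while the patch is wider than it is thick. For the
  564-lipid, 79 Å patch this holds comfortably (in-plane variance
  ≈ R²/4 ≈ 1560 Ų against ≈ 310 Ų across the leaflets); synthetic
  patches below ≈ 40 Å radius would invert the ordering, so test
  fixtures stay above that size.
* **Axis signs.** Eigenvectors are sign-ambiguous. The first frame
  orients each axis by the sign of the third moment of the C2
  projections — a rotation-invariant functional of the point set, so a
  rigidly rotated copy of a trajectory aligns to the *identical*
  output — with a largest-component fallback for exactly symmetric
  clouds. The determinant is forced to +1 by flipping an in-plane axis,
  never the normal, so leaflet labels agree with an already-aligned
  input.
* **In-plane gauge.** For a nearly isotropic disc the two in-plane
  eigenvalues are almost degenerate, and per-frame eigenvectors swing
  randomly — re-deriving them every frame would inject spurious rigid
  rotation into every lateral observable (it inflated recovered
  diffusion coefficients several-fold before this was fixed). Only the
  normal is re-estimated per frame; the in-plane axes are carried
  forward from the previous frame, projected onto the current normal
  plane and re-orthonormalized. This also keeps leaflet labels stable
  across frames. A corollary: the tilt collective variable must be
  evaluated on the *unaligned* (lab-frame) trajectory — alignment, by
  construction, removes the tilt — and `run_dln_analysis()` does so.

Coordinates are treated as unwrapped; reading a trajectory warns if
bonded-neighbor distances exceed 5 Å, the usual symptom of wrapped
periodic images. No periodic-boundary reassembly is attempted (the
nanodisc is compact).

# The synthetic membrane generator

No trajectories are deposited with the study the protocol comes from,
so the package carries its own ground-truth generator. Its defaults are
the study's membrane: a 79 Å radius patch at 69.5 Ų per lipid —
282 lipids per leaflet, 564 total, `round(pi*79^2/69.5)` — of
90 % DMPC / 9 % DMTAP / 1 % DMPE, with the two C2 planes 35 Å apart
(a typical C2–C2 distance for a DMPC bilayer). Lipids are coarse
pseudo-atom stacks: head motifs (amine/choline N, phosphate P, ester
O21) above the C2, two laterally offset tail chains of four carbons
reaching the midplane below it. Two chains per lipid matter: with a
single chain the atom cloud is too sparse for the 6 Å volumetric
surface used by the edge analysis, and the bilayer core would show
spurious holes that no all-atom membrane has.

Dynamics are deliberately minimal — the analyses only consume
positions:

* in-plane Brownian steps per lipid (variance 2 D Δt per axis) with the
  published per-species coefficients as the reference setting
  (0.02 / 0.14 / 1.14 Ų/ns for DMPC / DMTAP / DMPE);
* a Metropolis-style boundary at the patch radius: steps that would
  leave the disc are rejected. A radial fold (ρ → 2R−ρ) was tried first
  and measurably pumped density inward at O(step/R), biasing area-per-
  lipid recovery; rejection preserves the uniform stationary density
  exactly;
* scripted, instantaneous leaflet flips (the flip-counting contract is
  about label changes, not pathways);
* optional spherical-cap curvature, applied as the sag
  z += c ρ² / (1 + √(1 − c²ρ²)), and a scheduled rigid tilt;
* rim-hugging PEG chains (alternating methylene/oxygen pseudo-atoms,
  linker-labelled first monomer) within 6 Å of the rim cylinder,
  spanning the inter-leaflet gap.

Everything is seeded; identical specs give bit-identical trajectories.
What the generator does **not** emulate: conformational flexibility,
protrusions, undulations, realistic flip pathways, detergent kinetics,
electrostatics, or the DNA ring itself. Passing tests therefore verify
the *analysis code* against known ground truth — they say nothing about
force fields or sampling of real membranes.

# Numerical choices

**SASA.** Shrake–Rupley with a 2.0 Å probe and a 960-point Fibonacci
sphere lattice per atom (sub-1 % error at desk cost; doubling the count
moves areas by < 0.5 %). The occluded fraction computes the tail area
twice — occluders treated as solvent, then as structure — and divides
the difference by the former. A point exactly on a neighboring inflated
sphere counts as buried (with 1e-10 relative slack), so a coincident
duplicate atom occludes completely. The van der Waals radii are a
frozen, documented Bondi table, overridable per element; the radii used
by the original analysis software are not published, so absolute areas
on real trajectories may differ by a few percent.

**Contacts.** Distance ≤ 4.0 Å (closed boundary, fixed for
determinism), exact counting with a cell list, validated against an
O(N²) oracle. Pair fractions normalize by whole-system group sizes
N_A·N_B. Motif classes are heavy-atom sets; hydrogens are excluded by
default.

**Edge regionalization.** The lipid surface is a Gaussian-smeared
density (kernel width = vdW radius) on a 6 Å voxel grid, thresholded at
isovalue 0.01 — the "resolution 6 / isovalue 0.01" setting of the
original volumetric tool, with 6 interpreted as the voxel edge in Å and
kept configurable. The mask is collapsed along *z* over a 2 nm slab
(the stated projection slab; a 1 nm variant appears elsewhere in the
source's figure captions, so the thickness is a parameter); a pixel is
outside if its inside-average falls below 0.5, and the edge distance is
the in-plane distance from the C2 atom to the nearest outside pixel
center, ties broken by pixel index order. The edge/interior threshold
defaults to 10 Å (the source does not print its bin boundary).

**Flips.** The midplane is recomputed each frame from the C2 center of
mass. A label change counts as a flip only if the new label persists
≥ 15 ns (the block-average window) or to the trajectory end; without a
debounce, thermal z-jitter would inflate counts. The source does not
state a debounce, and its large background counts suggest permissive
counting — the default here may undercount relative to that
presentation; the persistence is a parameter.

**Thickness.** 0.5 Å z-bins over the 4 nm core cylinder, one Gaussian
per side of z = 0 fitted by Levenberg–Marquardt, initialized from
empirical moments with the mean bounded inside the data range (narrow,
few-bin peaks can otherwise diverge); profiles with fewer than three
occupied bins fall back to the moment estimates. Thickness is
μ_upper − μ_lower.

**Curvature.** Per leaflet, the spherical cap is parameterized by its
sag, z(ρ) = z₀ + c ρ² / (1 + √(1 − c²ρ²)), with (z₀, c) free — this
realizes "shift along the normal and curvature as the independent
variables" while keeping the flat limit c → 0 numerically exact; |c| is
bounded by 0.999/ρ_max. The two leaflets' values are averaged. Sign
convention: positive c places the rim above the patch center after
alignment (the sag formula's native orientation; the generator and the
fit share it, so recovery is sign-consistent). The fit is restricted to
the 4 nm core by default, matching the core restriction of the other
bilayer properties, and configurable.

**Diffusion.** MSD over all time origins, strides 1–128 ns in powers of
two by default, membership in the 4 nm core evaluated at the origin
frame (configurable to both endpoints). D = slope/4 from an unweighted
ordinary least-squares regression over all strides (the source states a
plain linear regression; whether it dropped short strides is unknown,
so the stride subset is a parameter). The regression R² is reported so
ballistic or confined regimes are visible. Expected displacements
√(4 D t) are reported to 2 significant figures, the source's own
reporting style.

**Tilt.** Best-fit rotation by the quaternion (Horn) eigenvector
method; swing–twist factorization R = R_tilt · R_spin with the twist
about *z*. The factor order is a documented choice — both orders give
the same tilt magnitude, which is the observable. The 180° tilt
singularity takes the identity-twist branch; at tilt → 0 the azimuth is
reported as 0. The restraint energy is E = k/2 (cos θ − target)², with
the stiff published constant (10,000 energy units per unit cos²) as the
default.

**Design arithmetic.** Centerline diameter = n_bp · rise / π with
0.34 nm/bp and a 2 nm helix width; nearest-nm rounding happens only in
the report layer. The default area per lipid of 0.684 nm² in
`lipid_fill()` is *back-solved* from the published 1:450 DNA:lipid
stoichiometry (which itself uses the nm-rounded 14 nm lumen); it is not
an independently stated value and is flagged as such in the
documentation.

# Problem sizes

The bundled analysis scripts and the test suite run everything at desk
scale, chosen so each stage completes in seconds to a couple of
minutes: the full 564-lipid patch with 21×37-monomer rim chains over
40 frames (100 ns) for the structural stages; 200 single-species lipids
over 2000 frames (1000 ns) for diffusion-coefficient recovery at the
three published D values; 10⁴-atom frames for the exact contact-count
cross-check; and a ~500-atom rim-polymer patch for the SASA oracle
comparison. The headline observables of the source system (45 %
occlusion, tail-area totals, ~50 % cationic-lipid edge enrichment,
absolute flip tallies) depend on its microsecond all-atom trajectories,
which are not deposited; those quantities are exercised here as
property-based closures against generator ground truth instead.

# Known limitations

* Leaflet assignment is a flat-midplane bisection; strongly curved or
  vesiculating membranes would need a curved-midplane method, which is
  out of scope.
* The volumetric edge map inherits voxel quantization: edge distances
  carry O(voxel edge) uncertainty.
* No PBC unwrapping, no XTC/TRR readers, no per-atom SASA
  decomposition export.
* `msd()` requires uniform frame spacing.
* DCD files carry no usable absolute time; the frame interval is a
  required argument of the reader.
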