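# Report pipeline: runs the requested analyses in a fixed order and
# writes one TSV per analysis plus a JSON summary of interval means.

#' Run the full nanodisc trajectory analysis
#'
#' Executes the requested analyses in a fixed order (align -> leaflets ->
#' regions/flips -> geometry -> occlusion -> contacts -> diffusion ->
#' tilt), writes one tab-separated table per analysis into `outdir` plus
#' a `summary.json` with interval means, and returns everything
#' invisibly. Re-running with identical inputs reproduces byte-identical
#' outputs (nothing here is stochastic). Time-averaged summary
#' quantities skip the first quarter of the trajectory unless
#' `summary_start` gives an absolute time.
#'
#' @param traj a `dln_trajectory` (unaligned is fine; alignment runs
#'   first).
#' @param sel selection configuration (default [default_selection()]).
#' @param outdir output directory (created if missing); `NULL` to skip
#'   writing.
#' @param analyses subset of c("regions", "flips", "geometry",
#'   "occlusion", "contacts", "diffusion", "tilt").
#' @param species_of_interest species for regional composition (default
#'   "DMTAP", the cationic lipid).
#' @param summary_start absolute start time (ns) for interval means;
#'   `NULL` = first time + 25% of the span.
#' @param grid,geom,diffp parameter objects ([grid_params()],
#'   [geometry_params()], [diffusion_params()]).
#' @param edge_threshold edge/interior boundary for regions (Angstrom).
#' @param probe_radius,n_sphere_points SASA parameters.
#' @param cutoff contact cutoff (Angstrom).
#' @param block block-average window (ns) applied to written series;
#'   `NULL` for raw.
#' @param align run [preprocess_align()] first (default TRUE).
#' @return (invisibly) list of per-analysis results plus `summary`.
#' @export
run_dln_analysis <- function(traj, sel = default_selection(), outdir = NULL,
                             analyses = c("regions", "flips", "geometry",
                                          "occlusion", "contacts",
                                          "diffusion", "tilt"),
                             species_of_interest = "DMTAP",
                             summary_start = NULL,
                             grid = grid_params(), geom = geometry_params(),
                             diffp = diffusion_params(),
                             edge_threshold = 10, probe_radius = 2.0,
                             n_sphere_points = 960, cutoff = 4.0,
                             block = NULL, align = TRUE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(outdir))
      write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  step <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("analysis '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  # the tilt colvar is measured in the input (lab) frame against the
  # first frame: principal-axis alignment would remove the tilt signal
  traj_lab <- traj
  if (align) traj <- step("align", preprocess_align(traj, sel))
  res <- list()
  summary <- list(n_frames = n_frames(traj), n_atoms = n_atoms(traj),
                  time_span_ns = diff(range(traj$times)))

  if ("regions" %in% analyses) {
    res$regions <- step("regions",
      region_composition(traj, species_of_interest, sel,
                         edge_threshold = edge_threshold, params = grid))
    emit(res$regions, "regions")
    for (rg in unique(res$regions$region)) {
      s <- res$regions[res$regions$region == rg, ]
      ok <- is.finite(s$fraction)
      summary[[paste0("fraction_", species_of_interest, "_", rg)]] <-
        if (any(ok)) interval_mean(s$time[ok], s$fraction[ok], summary_start) else NA
    }
    summary[[paste0("fraction_", species_of_interest, "_global")]] <-
      attr(res$regions, "global_fraction")
  }
  if ("flips" %in% analyses) {
    res$flips <- step("flips", count_flips(traj, sel))
    emit(res$flips$events, "flips")
    for (k in seq_len(nrow(res$flips$counts))) {
      cc <- res$flips$counts[k, ]
      summary[[paste0("flips_", cc$species, "_lower_to_upper")]] <- cc$lower_to_upper
      summary[[paste0("flips_", cc$species, "_upper_to_lower")]] <- cc$upper_to_lower
    }
  }
  if ("geometry" %in% analyses) {
    res$geometry <- step("geometry", geometry_series(traj, sel, geom, block))
    emit(res$geometry, "geometry")
    for (q in c("thickness", "apl", "curvature", "edge_count"))
      summary[[paste0("mean_", q)]] <-
        interval_mean(res$geometry$time, res$geometry[[q]], summary_start)
  }
  if ("occlusion" %in% analyses) {
    res$occlusion <- step("occlusion",
      occlusion_series(traj, sel, probe_radius, n_sphere_points, block))
    emit(res$occlusion, "occlusion")
    summary$mean_occluded_fraction <-
      interval_mean(res$occlusion$time, res$occlusion$occluded_fraction,
                    summary_start)
  }
  if ("contacts" %in% analyses) {
    res$contacts <- step("contacts",
      suppressWarnings(motif_contact_report(traj, sel, cutoff = cutoff,
                                            start = summary_start)))
    emit(res$contacts$series, "contacts")
    emit(res$contacts$summary, "contacts_summary")
    for (k in seq_len(nrow(res$contacts$summary))) {
      s <- res$contacts$summary[k, ]
      summary[[paste0("contacts_", s$pair)]] <- s$mean_count
    }
  }
  if ("diffusion" %in% analyses) {
    sps <- intersect(sel_species(sel, c("lipid", "detergent")),
                     unique(traj$atoms$residue_name))
    res$diffusion <- list()
    dtab <- list()
    for (sp in sps) {
      tab <- step("diffusion", suppressWarnings(msd(traj, sp, sel, diffp)))
      if (nrow(tab) >= 2) {
        D <- diffusion_coefficient(tab)
        summary[[paste0("D_", sp)]] <- as.numeric(D)
        res$diffusion[[sp]] <- list(msd = tab, D = D)
        dtab[[sp]] <- data.frame(species = sp, tab)
      }
    }
    if (length(dtab)) emit(do.call(rbind, dtab), "diffusion")
  }
  if ("tilt" %in% analyses) {
    res$tilt <- step("tilt", tilt_series(traj_lab, sel))
    emit(res$tilt, "tilt")
    summary$mean_cos_tilt <-
      interval_mean(res$tilt$time, res$tilt$cos_tilt, summary_start)
  }
  res$summary <- summary
  if (!is.null(outdir))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
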