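#' Comparative tilt/interface report for a set of complexes
#'
#' Runs the full comparison workflow for a list of complexes against a
#' reference: receptor superposition, three-atom tilt, and (optionally)
#' buried interface area, one row per complex.  A failure in one complex is
#' reported in its row's `error` column instead of aborting the run.
#'
#' @param complexes Named list of `eph_complex` objects (names become row
#'   ids; unnamed entries use the structure id).
#' @param reference The reference `eph_complex` defining tilt 0.
#' @param spec A [tilt_spec()].
#' @param interface Also compute the buried interface area per complex.
#' @param n_points SASA lattice points (see [shrake_rupley_sasa()]).
#' @return A data frame: `id`, `tilt_deg` (signed, 1 decimal),
#'   `tilt_rounded` (whole degrees, report style), `raw_angle_deg`,
#'   `interface_area_A2`, `receptor_rmsd_A`, `pairs_used`, `error`.
#' @export
run_table3 <- function(complexes, reference, spec = tilt_spec(),
                       interface = TRUE, n_points = 960) {
  if (length(complexes) == 0) stop("no complexes given")
  ids <- names(complexes)
  if (is.null(ids)) ids <- rep("", length(complexes))
  rows <- lapply(seq_along(complexes), function(i) {
    cx <- complexes[[i]]
    id <- if (nzchar(ids[i])) ids[i] else cx$id
    row <- data.frame(id = id, tilt_deg = NA_real_, tilt_rounded = NA_integer_,
                      raw_angle_deg = NA_real_, interface_area_A2 = NA_real_,
                      receptor_rmsd_A = NA_real_, pairs_used = NA_integer_,
                      error = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      tl <- measure_tilt(cx, reference, spec)
      row$tilt_deg <- round(tl$tilt, 1)
      row$tilt_rounded <- tl$tilt_abs_rounded
      row$raw_angle_deg <- round(tl$raw_angle, 1)
      row$receptor_rmsd_A <- round(tl$receptor_rmsd, 3)
      row$pairs_used <- tl$pairs_used
      if (interface)
        row$interface_area_A2 <-
          round(buried_interface_area(cx$receptor, cx$ligand,
                                      n_points = n_points)$interface_area, 1)
      row
    }, error = function(e) {row$error <- conditionMessage(e); row})
    res
  })
  do.call(rbind, rows)
}

#' Write a report data frame as TSV and JSON
#'
#' @param report A data frame (e.g. from [run_table3()]).
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @export
write_report <- function(report, prefix) {
  utils::write.table(report, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, paste0(prefix, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}
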