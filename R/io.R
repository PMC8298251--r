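# Export: legacy ASCII VTK unstructured grids for solutions, CSV for lumen
# profiles, YAML round-trip for study configuration.

#' Export a solution to a legacy VTK unstructured-grid file
#'
#' Writes point displacements and per-cell stress/strain fields of a
#' structural solution, or the axial velocity field of a flow solution, as
#' ASCII legacy VTK readable by ParaView.
#'
#' @param x a `field_solution` or `flow_solution`.
#' @param path output file path (`.vtk`).
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(x, path, ...) UseMethod("write_vtk")

.vtk_header <- function(con, nodes, title) {
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes))), con)
  utils::write.table(cbind(nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
}

#' @export
write_vtk.field_solution <- function(x, path, ...) {
  mesh <- x$mesh
  con <- file(path, "w")
  on.exit(close(con))
  .vtk_header(con, mesh$nodes, "plaquemech structural solution")
  ne <- nrow(mesh$tri)
  writeLines(sprintf("CELLS %d %d", ne, 7 * ne), con)
  utils::write.table(cbind(6L, mesh$tri - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(22L, ne)), con)   # VTK_QUADRATIC_TRIANGLE
  writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
  writeLines("VECTORS displacement double", con)
  utils::write.table(cbind(x$u, 0), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  ef <- x$element_fields
  for (nm in colnames(ef)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(ef[, nm], digits = 10), con)
  }
  writeLines(c("SCALARS pws double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(.element_pws(x), digits = 10), con)
  invisible(path)
}

#' @export
write_vtk.flow_solution <- function(x, path, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  .vtk_header(con, x$nodes, "plaquemech axial flow (surrogate: fully-developed)")
  ne <- nrow(x$tri)
  writeLines(sprintf("CELLS %d %d", ne, 4 * ne), con)
  utils::write.table(cbind(3L, x$tri - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(5L, ne)), con)    # VTK_TRIANGLE
  writeLines(sprintf("POINT_DATA %d", nrow(x$nodes)), con)
  writeLines(c("SCALARS axial_velocity double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(x$velocity, digits = 10), con)
  invisible(path)
}

#' Write a lumen profile to CSV
#'
#' Columns: `point_index`, `arc_s`, `x`, `y`, `PWS_kPa`, `PWSn`,
#' `FSS_dyncm2` (plus any identification columns present).
#'
#' @param profile a `lumen_profile` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Recognized blocks: `cohort` (passed to [cohort_variability()] plus
#' `n_patients`, `base_seed`), `materials` (preset names or parameter
#' overrides per region), `solver` (`h`, `load_steps`, `pressure_phase`),
#' `preconditioning` (`shrink_tol`), `flow` (passed to [flow_config()]),
#' `comparison` (`pairs` as `"A:B"` strings).
#'
#' @param path YAML file.
#' @return List with `study` (a [study_config()]), `cohort_args`, `pairs`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  mats <- list(wall = material_params("vessel"),
               lipid = material_params("lipid"),
               calc = material_params("calcification"))
  for (nm in names(y$materials %||% list())) {
    m <- y$materials[[nm]]
    mats[[nm]] <- if (is.character(m)) material_params(m)
                  else do.call(material_params, c(list(preset = "custom"), m))
  }
  study <- study_config(
    materials = mats,
    h = y$solver$h %||% 0.3,
    n_points = y$solver$n_points %||% 100L,
    flow = do.call(flow_config, y$flow %||% list()),
    shrink_tol = y$preconditioning$shrink_tol %||% 0.005,
    pressure_phase = y$solver$pressure_phase %||% "max",
    load_steps = y$solver$load_steps %||% 6L)
  cohort_args <- y$cohort %||% list()
  pairs <- lapply(y$comparison$pairs %||%
                    list("M1:M2", "FSI:M1", "FSI:M5", "FSI:M7"),
                  function(s) strsplit(s, ":", fixed = TRUE)[[1]])
  list(study = study, cohort_args = cohort_args, pairs = pairs)
}
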