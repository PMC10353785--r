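#' Write a simulation snapshot
#'
#' Cells go to `cells_<tttttttt>.csv` (columns x, y, z, phase, V, V_F, V_NS,
#' V_CS, phase as its label) and the field to `field_<tttttttt>.csv`
#' (columns i, j, k, rho with 0-based voxel indices); the zero-padded index
#' is the time in whole minutes. With `vtk = TRUE`, legacy-ASCII VTK
#' companions are written (PolyData points with phase and volume scalars;
#' structured points for the field). Writing never mutates simulation state.
#'
#' @param pop a `CellPopulation`.
#' @param field a `Field` (or NULL to skip).
#' @param grid the `Grid`.
#' @param t simulation time (min).
#' @param dir output directory (created if needed).
#' @param vtk also write VTK legacy files.
#' @return invisible character vector of the files written.
#' @export
writeSnapshot <- function(pop, field, grid, t, dir, vtk = FALSE) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create snapshot directory: ", dir)
  tag <- sprintf("%08d", as.integer(round(t)))
  files <- character(0)
  cells_path <- file.path(dir, paste0("cells_", tag, ".csv"))
  dt <- data.table::data.table(
    x = pop$position[, 1], y = pop$position[, 2], z = pop$position[, 3],
    phase = phaseLabel(pop$phase),
    V = pop$V, V_F = pop$V_F, V_NS = pop$V_NS, V_CS = pop$V_CS)
  data.table::fwrite(dt, cells_path)
  files <- c(files, cells_path)
  if (!is.null(field)) {
    field_path <- file.path(dir, paste0("field_", tag, ".csv"))
    ijk <- expand.grid(i = 0:(grid$nx - 1), j = 0:(grid$ny - 1),
                       k = 0:(grid$nz - 1))
    data.table::fwrite(data.table::data.table(ijk, rho = as.vector(field$rho)),
                       field_path)
    files <- c(files, field_path)
  }
  if (vtk) {
    vp <- file.path(dir, paste0("cells_", tag, ".vtk"))
    writeVTKPoints(pop, vp)
    files <- c(files, vp)
    if (!is.null(field)) {
      vf <- file.path(dir, paste0("field_", tag, ".vtk"))
      writeVTKField(field, grid, vf)
      files <- c(files, vf)
    }
  }
  invisible(files)
}

#' Read a cell population from CSV
#'
#' Expects the snapshot schema (x, y, z, phase, V, V_F, V_NS, V_CS); phases
#' may be labels or 1-based codes. Rows violating the volume-closure
#' invariant or carrying an unknown phase raise an error naming the first
#' offending line.
#'
#' @param path CSV file.
#' @return a `CellPopulation`.
#' @export
readPopulation <- function(path) {
  dt <- data.table::fread(path)
  need <- c("x", "y", "z", "phase", "V", "V_F", "V_NS", "V_CS")
  if (!all(need %in% names(dt)))
    stop("population CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(dt) == 0) return(emptyPopulation())
  phase <- if (is.character(dt$phase)) {
    bad <- !(dt$phase %in% phaseLevels())
    if (any(bad))
      stop("unknown phase label at line ", which(bad)[1] + 1L, ": ",
           dt$phase[which(bad)[1]])
    phaseCode(dt$phase)
  } else {
    as.integer(dt$phase)
  }
  if (any(phase < 1L | phase > 6L))
    stop("phase code out of range at line ",
         which(phase < 1L | phase > 6L)[1] + 1L)
  comp <- dt$V_F + dt$V_NS + dt$V_CS
  rel <- abs(comp - dt$V) / pmax(dt$V, 1e-12)
  if (any(rel > 1e-6))
    stop("V != V_F + V_NS + V_CS at line ", which(rel > 1e-6)[1] + 1L)
  newCellPopulation(cbind(dt$x, dt$y, dt$z), phase = phase, V = dt$V,
                    V_F = dt$V_F, V_NS = dt$V_NS, V_CS = dt$V_CS)
}

#' Write / read a metrics series as CSV
#'
#' @param metrics the metrics data.frame of a `SimulationResult`.
#' @param path CSV file.
#' @return `writeMetrics` returns `path` invisibly; `readMetrics` a
#'   data.frame.
#' @export
writeMetrics <- function(metrics, path) {
  data.table::fwrite(metrics, path)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Legacy-ASCII VTK writers
#'
#' `writeVTKPoints` writes the cell centers as a POLYDATA point cloud with
#' phase-code and total-volume scalars; `writeVTKField` writes the
#' concentration as STRUCTURED_POINTS located at voxel centers. Minimal
#' legacy (version 2.0) files readable by standard VTK-based viewers.
#'
#' @param pop a `CellPopulation`.
#' @param field a `Field`.
#' @param grid the `Grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVTKPoints <- function(pop, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- pop$n
  writeLines(c("# vtk DataFile Version 2.0", "cell centers", "ASCII",
               "DATASET POLYDATA", paste("POINTS", n, "float")), con)
  if (n > 0)
    writeLines(apply(format(pop$position, trim = TRUE), 1, paste,
                     collapse = " "), con)
  writeLines(paste("VERTICES", n, 2 * n), con)
  if (n > 0) writeLines(paste(1, seq_len(n) - 1), con)
  writeLines(c(paste("POINT_DATA", n), "SCALARS phase int 1",
               "LOOKUP_TABLE default"), con)
  if (n > 0) writeLines(as.character(pop$phase), con)
  writeLines(c("SCALARS volume float 1", "LOOKUP_TABLE default"), con)
  if (n > 0) writeLines(format(pop$V, trim = TRUE), con)
  invisible(path)
}

#' @rdname writeVTKPoints
#' @export
writeVTKField <- function(field, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  orig <- grid$origin + grid$dx / 2
  writeLines(c("# vtk DataFile Version 2.0", "substance concentration",
               "ASCII", "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", grid$nx, grid$ny, grid$nz),
               paste("ORIGIN", orig[1], orig[2], orig[3]),
               paste("SPACING", grid$dx, grid$dx, grid$dx),
               paste("POINT_DATA", nVoxels(grid)),
               "SCALARS rho float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(field$rho), trim = TRUE), con)
  invisible(path)
}
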