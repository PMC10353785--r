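#' Structure-of-arrays cell population
#'
#' The population holds one vector (or n-by-3 matrix) per state variable, so
#' the compiled kernels can walk contiguous memory: positions and velocities
#' in micrometres (per minute), phase codes, time spent in the current phase
#' (minutes), the total and component volumes (cubic micrometres), the Morton
#' sort key, and the removal flag raised for dead cells that have shrunk below
#' the deletion threshold.
#'
#' @param position n-by-3 numeric matrix of cell centers (um).
#' @param phase integer phase codes (see [phaseLevels()]); recycled.
#' @param V,V_F,V_NS,V_CS total, fluid, nuclear-solid and cytoplasmic-solid
#'   volumes (um^3); recycled. `V` defaults to the component sum.
#' @param velocity,previous_velocity n-by-3 matrices (um/min); default zero.
#' @param phase_clock minutes already spent in the current phase; default 0.
#' @return an object of class `CellPopulation`.
#' @export
newCellPopulation <- function(position, phase, V_F, V_NS, V_CS, V = NULL,
                              velocity = NULL, previous_velocity = NULL,
                              phase_clock = 0) {
  position <- matrix(as.numeric(position), ncol = 3)
  n <- nrow(position)
  zero <- matrix(0, n, 3)
  if (is.null(velocity)) velocity <- zero
  if (is.null(previous_velocity)) previous_velocity <- zero
  V_F <- rep_len(as.numeric(V_F), n)
  V_NS <- rep_len(as.numeric(V_NS), n)
  V_CS <- rep_len(as.numeric(V_CS), n)
  if (is.null(V)) V <- V_F + V_NS + V_CS
  pop <- structure(list(
    n = n,
    position = position,
    velocity = velocity,
    previous_velocity = previous_velocity,
    phase = rep_len(as.integer(phase), n),
    phase_clock = rep_len(as.numeric(phase_clock), n),
    V = rep_len(as.numeric(V), n),
    V_F = V_F, V_NS = V_NS, V_CS = V_CS,
    sort_key = rep(NA_real_, n),
    removal_flag = rep(FALSE, n)
  ), class = "CellPopulation")
  validatePopulation(pop)
  pop
}

#' An empty population (0 cells)
#' @return a `CellPopulation` with `n = 0`.
#' @export
emptyPopulation <- function() {
  structure(list(
    n = 0L,
    position = matrix(numeric(0), 0, 3),
    velocity = matrix(numeric(0), 0, 3),
    previous_velocity = matrix(numeric(0), 0, 3),
    phase = integer(0), phase_clock = numeric(0),
    V = numeric(0), V_F = numeric(0), V_NS = numeric(0), V_CS = numeric(0),
    sort_key = numeric(0), removal_flag = logical(0)
  ), class = "CellPopulation")
}

#' @export
print.CellPopulation <- function(x, ...) {
  cat("<CellPopulation>", x$n, "cells\n")
  if (x$n > 0) {
    tab <- table(factor(phaseLabel(x$phase), levels = phaseLevels()))
    for (nm in names(tab)) if (tab[[nm]] > 0) cat(" ", nm, tab[[nm]], "\n")
    cat("  total volume", format(sum(x$V), digits = 6), "um^3\n")
  }
  invisible(x)
}

#' Number of cells
#' @param pop a `CellPopulation`.
#' @return integer count.
#' @export
nCells <- function(pop) pop$n

#' Cell radii from total volume
#'
#' R = (3V / 4 pi)^(1/3).
#'
#' @param V total volumes (um^3), or a `CellPopulation`.
#' @return radii in um.
#' @export
cellRadius <- function(V) {
  if (inherits(V, "CellPopulation")) V <- V$V
  (3 * V / (4 * pi))^(1 / 3)
}

#' Check the population invariants
#'
#' Volumes must be non-negative, the component sum must reproduce `V` to
#' within 1e-6 relative tolerance, and all fields must have matching length.
#'
#' @param pop a `CellPopulation`.
#' @return `pop`, invisibly; stops on violation.
#' @export
validatePopulation <- function(pop) {
  n <- pop$n
  vecs <- c("phase", "phase_clock", "V", "V_F", "V_NS", "V_CS",
            "sort_key", "removal_flag")
  for (f in vecs)
    if (length(pop[[f]]) != n) stop("field ", f, " has wrong length")
  for (f in c("position", "velocity", "previous_velocity"))
    if (nrow(pop[[f]]) != n) stop("field ", f, " has wrong row count")
  if (n == 0) return(invisible(pop))
  if (any(pop$phase < 1L | pop$phase > 6L)) stop("invalid phase code")
  if (any(pop$V < 0 | pop$V_F < 0 | pop$V_NS < 0 | pop$V_CS < 0))
    stop("negative cell volume")
  comp <- pop$V_F + pop$V_NS + pop$V_CS
  rel <- abs(comp - pop$V) / pmax(pop$V, 1e-12)
  if (any(rel > 1e-6))
    stop("V != V_F + V_NS + V_CS beyond 1e-6 relative tolerance (worst ",
         format(max(rel), digits = 3), ")")
  invisible(pop)
}

# Subset every per-cell field; keeps class. Used by sorting and birth/death.
subsetPopulation <- function(pop, idx) {
  out <- pop
  out$position <- pop$position[idx, , drop = FALSE]
  out$velocity <- pop$velocity[idx, , drop = FALSE]
  out$previous_velocity <- pop$previous_velocity[idx, , drop = FALSE]
  for (f in c("phase", "phase_clock", "V", "V_F", "V_NS", "V_CS",
              "sort_key", "removal_flag"))
    out[[f]] <- pop[[f]][idx]
  out$n <- nrow(out$position)
  out
}

# Append the cells of `b` after those of `a`.
bindPopulations <- function(a, b) {
  out <- a
  out$position <- rbind(a$position, b$position)
  out$velocity <- rbind(a$velocity, b$velocity)
  out$previous_velocity <- rbind(a$previous_velocity, b$previous_velocity)
  for (f in c("phase", "phase_clock", "V", "V_F", "V_NS", "V_CS",
              "sort_key", "removal_flag"))
    out[[f]] <- c(a[[f]], b[[f]])
  out$n <- a$n + b$n
  out
}
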