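#' Probability of a stochastic transition in a short interval
#'
#' A transition with rate `r` fires in a step of length `dt` with probability
#' `r * dt` (one uniform draw per test, the discretization of the underlying
#' exponential waiting time). Rates are per hour, steps in minutes; the unit
#' conversion happens here.
#'
#' @param rate transition rate (1/hour), non-negative.
#' @param dt time step (min), positive.
#' @return probability in a single step.
#' @export
transitionProbability <- function(rate, dt) {
  if (any(rate < 0)) stop("negative transition rate")
  stopifnot(all(dt > 0))
  p <- rate * dt / 60
  if (any(p > 1))
    warning("rate * dt exceeds 1; time step too long for this rate")
  p
}

#' Oxygen-dependent proliferation rate
#'
#' Quiescent cells activate for division at `r_pro_max` when the local oxygen
#' partial pressure is at least `Sa_pro`, at zero when it is at most
#' `Th_pro`, and on the linear ramp
#' `r_pro_max * (p_oxy - Th_pro) / (Sa_pro - Th_pro)` in between.
#'
#' @param p_oxy local oxygen partial pressure (mmHg).
#' @param params a [phaseParams()].
#' @return rate in 1/hour (vectorized over `p_oxy`).
#' @export
proliferationRate <- function(p_oxy, params) {
  ramp <- (p_oxy - params$Th_pro) / (params$Sa_pro - params$Th_pro)
  params$r_pro_max * pmin(pmax(ramp, 0), 1)
}

#' Oxygen-dependent necrosis rate
#'
#' Zero at or above `Th_nec`, maximal (`r_nec_max`) at or below `Sa_nec`,
#' linear ramp `r_nec_max * (Th_nec - p_oxy) / (Th_nec - Sa_nec)` in between:
#' necrotic death only happens in hypoxic regions.
#'
#' @inheritParams proliferationRate
#' @return rate in 1/hour (vectorized over `p_oxy`).
#' @export
necrosisRate <- function(p_oxy, params) {
  ramp <- (params$Th_nec - p_oxy) / (params$Th_nec - params$Sa_nec)
  params$r_nec_max * pmin(pmax(ramp, 0), 1)
}

#' One stochastic phase-transition step for the whole population
#'
#' Per cell, in fixed order: living cells test apoptosis (constant rate) and
#' then necrosis (oxygen-dependent); surviving premitotic cells whose clock
#' has reached `T_prem` are marked for division; postmitotic cells whose
#' clock has reached `T_postm` become quiescent; quiescent cells test
#' oxygen-dependent activation into the premitotic phase; early necrotic
#' cells whose volume has swollen past `rupture_ratio * V_std` rupture into
#' the late necrotic stage; dead cells below the removal volume are flagged;
#' finally every clock advances by `dt`. Order-independent across cells; RNG
#' draws are consumed in cell order.
#'
#' @param pop a `CellPopulation`.
#' @param p_oxy per-cell oxygen (mmHg), e.g. from [sampleConcentration()].
#' @param dt phase time step (min).
#' @param params a [phaseParams()].
#' @param vparams a [volumeParams()] (rupture and removal thresholds).
#' @return list: `population` (phases and clocks updated), `divisions`
#'   (integer indices of cells due to divide), `removals` (logical flags).
#' @export
updatePhases <- function(pop, p_oxy, dt, params, vparams) {
  if (pop$n == 0)
    return(list(population = pop, divisions = integer(0),
                removals = logical(0)))
  res <- update_phases_cpp(pop$phase, pop$phase_clock, pop$V,
                           rep_len(as.numeric(p_oxy), pop$n), dt,
                           params$T_prem * 60, params$T_postm * 60,
                           params$r_apop / 60,
                           params$r_pro_max / 60, params$Sa_pro,
                           params$Th_pro,
                           params$r_nec_max / 60, params$Sa_nec,
                           params$Th_nec,
                           standardVolume(vparams), vparams$rupture_ratio,
                           vparams$removal_fraction)
  pop$phase <- res$phase
  pop$phase_clock <- res$clock
  pop$removal_flag <- res$remove
  list(population = pop, divisions = which(res$divide),
       removals = res$remove)
}

#' One explicit component-volume relaxation step
#'
#' Each component relaxes toward its phase target,
#' `V_i <- V_i - dt * r * (V_i - V_i^p)`; the fluid target is `f_F * V` for
#' living phases, the current total volume during early necrosis (so the
#' cell swells while `f_F < 1`), and zero for apoptotic and late necrotic
#' cells. `V` is recomputed as the component sum; any component stepping
#' below zero is clamped (with a warning).
#'
#' @param pop a `CellPopulation`.
#' @param dt phase time step (min); `dt * max(r)` must stay below 1.
#' @param vparams a [volumeParams()].
#' @return the updated `CellPopulation`.
#' @export
updateVolumes <- function(pop, dt, vparams) {
  if (pop$n == 0) return(pop)
  res <- update_volumes_cpp(pop$phase, pop$V_F, pop$V_NS, pop$V_CS,
                            dt, vparams$f_F, vparams$fluid_mode,
                            vparams$r_F / 60,
                            vparams$V_NS_target, vparams$r_NS / 60,
                            vparams$V_CS_target, vparams$r_CS / 60)
  if (res$n_clamped > 0)
    warning(res$n_clamped, " component volume(s) clamped at zero")
  pop$V <- res$V
  pop$V_F <- res$V_F
  pop$V_NS <- res$V_NS
  pop$V_CS <- res$V_CS
  pop
}

#' Split dividing cells into daughter pairs
#'
#' Each daughter inherits half of every parent component volume and the
#' parent's velocities, enters the postmitotic phase with a reset clock, and
#' is displaced from the parent center by `(R - R / 2^(1/3))` along a
#' uniformly random unit vector (one daughter at `+`, the other at `-`, so
#' daughter positions sum to twice the parent center and total volume is
#' conserved exactly).
#'
#' @param pop a `CellPopulation`.
#' @param idx indices of the dividing (premitotic, mature) cells.
#' @return list of two population fragments, `first` and `second`, aligned
#'   with `idx`.
#' @export
divideCells <- function(pop, idx) {
  m <- length(idx)
  if (m == 0) return(list(first = emptyPopulation(),
                          second = emptyPopulation()))
  R <- cellRadius(pop$V[idx])
  disp <- R * (1 - 2^(-1 / 3))
  z <- stats::runif(m, -1, 1)
  phi <- stats::runif(m, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  theta <- cbind(s * cos(phi), s * sin(phi), z)
  half <- function(sign) {
    d <- subsetPopulation(pop, idx)
    d$position <- d$position + sign * disp * theta
    d$phase <- rep(POSTMITOTIC, m)
    d$phase_clock <- rep(0, m)
    d$V <- d$V / 2
    d$V_F <- d$V_F / 2
    d$V_NS <- d$V_NS / 2
    d$V_CS <- d$V_CS / 2
    d$removal_flag <- rep(FALSE, m)
    d
  }
  list(first = half(+1), second = half(-1))
}

#' Apply births and deaths and compact the cell array
#'
#' Dividing parents are replaced in place by their first daughter and the
#' second daughter is appended; removal-flagged cells are then deleted. No
#' stale records survive and every remaining cell keeps its state
#' field-by-field.
#'
#' @param pop a `CellPopulation` (with `removal_flag` set, e.g. by
#'   [updatePhases()]).
#' @param divisions integer indices of dividing cells.
#' @param daughters the pair of fragments from [divideCells()].
#' @param removals logical removal flags (length `nCells(pop)`); defaults to
#'   the population's own flags.
#' @return the compacted `CellPopulation`.
#' @export
applyBirthDeath <- function(pop, divisions, daughters,
                            removals = pop$removal_flag) {
  n0 <- pop$n
  if (length(divisions) > 0) {
    d1 <- daughters$first
    pop$position[divisions, ] <- d1$position
    pop$velocity[divisions, ] <- d1$velocity
    pop$previous_velocity[divisions, ] <- d1$previous_velocity
    for (f in c("phase", "phase_clock", "V", "V_F", "V_NS", "V_CS",
                "sort_key", "removal_flag"))
      pop[[f]][divisions] <- d1[[f]]
    pop <- bindPopulations(pop, daughters$second)
  }
  keep <- c(!removals, rep(TRUE, pop$n - n0))
  if (!all(keep)) pop <- subsetPopulation(pop, keep)
  pop
}
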