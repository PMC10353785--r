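#' Spheroid radius of a discrete cell population
#'
#' The population has no sharp edge, so the radius is estimated as a high
#' percentile (97.5 by default) of the cell-center distances from the
#' population centroid, plus the mean cell radius; this is robust to a few
#' straggler cells. A `max` method (largest center distance plus mean cell
#' radius) and other percentiles are available. Permutation- and
#' translation-invariant.
#'
#' @param pop a `CellPopulation` with at least one cell.
#' @param prob percentile used by the `"percentile"` method.
#' @param method `"percentile"` or `"max"`.
#' @return radius in um.
#' @export
spheroidRadius <- function(pop, prob = 0.975, method = c("percentile", "max")) {
  method <- match.arg(method)
  if (pop$n == 0) stop("spheroid radius of an empty population is undefined")
  .radiusEstimate(pop$position, cellRadius(pop), prob, method)
}

#' Necrotic core radius
#'
#' The same estimator as [spheroidRadius()] restricted to early and late
#' necrotic cells (about their own centroid); zero when no cell is necrotic.
#'
#' @inheritParams spheroidRadius
#' @return radius in um.
#' @export
necroticCoreRadius <- function(pop, prob = 0.975,
                               method = c("percentile", "max")) {
  method <- match.arg(method)
  sel <- isNecrotic(pop$phase)
  if (!any(sel)) return(0)
  .radiusEstimate(pop$position[sel, , drop = FALSE],
                  cellRadius(pop$V[sel]), prob, method)
}

.radiusEstimate <- function(pos, R, prob, method) {
  centroid <- colMeans(pos)
  d <- sqrt(rowSums(sweep(pos, 2, centroid)^2))
  core <- if (method == "max") max(d)
          else unname(stats::quantile(d, prob, names = FALSE))
  core + mean(R)
}

#' Axial front position of a duct-confined population
#'
#' The 99th percentile of the axial (x) coordinates of living cells,
#' measured from the closed end of the duct.
#'
#' @param pop a `CellPopulation`.
#' @param duct a [ductGeometry()].
#' @param prob percentile of the axial coordinate.
#' @return front position in um (0 if no living cell).
#' @export
dcisFront <- function(pop, duct, prob = 0.99) {
  x <- pop$position[isLiving(pop$phase), 1]
  if (length(x) == 0) return(0)
  unname(stats::quantile(x, prob, names = FALSE)) - duct$closed_end
}

#' Front positions and average advance rate from a metrics series
#'
#' The advance rate is the least-squares slope of front position against
#' time over the provided records, converted to um/day.
#'
#' @param time times in minutes.
#' @param front front positions in um (e.g. the `front` column of a
#'   [runSimulation()] metrics table).
#' @return list with `rate_um_per_day`, the fitted `intercept_um`, and the
#'   fit's `r_squared`.
#' @export
dcisAdvanceRate <- function(time, front) {
  keep <- is.finite(time) & is.finite(front)
  time <- time[keep]; front <- front[keep]
  if (length(time) < 2) stop("need at least two front records")
  fit <- stats::lm(front ~ time)
  list(rate_um_per_day = unname(stats::coef(fit)[2]) * 1440,
       intercept_um = unname(stats::coef(fit)[1]),
       r_squared = .rsq(fit, front))
}

#' @rdname dcisAdvanceRate
#' @param metrics the metrics data.frame of a `SimulationResult` from a duct
#'   scenario (columns `time` and `front`).
#' @export
dcisFrontAndRate <- function(metrics) {
  c(list(time = metrics$time, front = metrics$front),
    dcisAdvanceRate(metrics$time, metrics$front))
}

#' Linearity of radius growth
#'
#' Least-squares fit of radius against time; the R-squared quantifies how
#' linear the growth curve is (a constant viable rim makes it linear).
#'
#' @param time minutes.
#' @param radius um.
#' @return list with `slope_um_per_day`, `r_squared`.
#' @export
radiusGrowthFit <- function(time, radius) {
  keep <- is.finite(time) & is.finite(radius)
  fit <- stats::lm(radius[keep] ~ time[keep])
  list(slope_um_per_day = unname(stats::coef(fit)[2]) * 1440,
       r_squared = .rsq(fit, radius[keep]))
}

# R^2 without summary.lm (which warns on numerically perfect fits)
.rsq <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}
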