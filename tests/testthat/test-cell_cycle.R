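test_that("transition probability converts hourly rates over minute steps", {
  expect_equal(transitionProbability(0.0060, 6), 0.0006)
  expect_equal(transitionProbability(0, 123), 0)
  expect_equal(transitionProbability(0.1667, 6), 0.01667)
  expect_error(transitionProbability(-0.1, 6), "negative")
  expect_warning(transitionProbability(120, 60), "exceeds 1")
})

test_that("proliferation rate follows the oxygen ramp", {
  p <- phaseParams()
  expect_equal(proliferationRate(10, p), 0.1176)
  expect_equal(proliferationRate(50, p), 0.1176)
  expect_equal(proliferationRate(5, p), 0)
  expect_equal(proliferationRate(0, p), 0)
  expect_equal(proliferationRate(7.5, p), 0.0588)
})

test_that("necrosis rate follows the inverted oxygen ramp", {
  p <- phaseParams()
  expect_equal(necrosisRate(5, p), 0)
  expect_equal(necrosisRate(38, p), 0)
  expect_equal(necrosisRate(2.5, p), 0.1667)
  expect_equal(necrosisRate(0, p), 0.1667)
  expect_equal(necrosisRate(3.75, p), 0.08335)
})

test_that("volume relaxation converges to the closed-form solution as dt -> 0", {
  # dV/dt = -r (V - V^p): from 270 toward 135 at 0.33/h for one hour
  exact <- 135 + 135 * exp(-0.33)
  vp <- volumeParams()
  run <- function(dt_min) {
    pop <- randomPopulation(1, c(0, 0, 0), c(10, 10, 10))
    pop$phase <- POSTMITOTIC  # quiescent-column targets, NS target 135
    pop$V_NS <- 270
    pop$V <- pop$V_F + pop$V_NS + pop$V_CS
    for (i in seq_len(60 / dt_min)) pop <- updateVolumes(pop, dt_min, vp)
    pop$V_NS
  }
  err <- abs(c(run(6), run(3), run(1.5)) - exact)
  expect_lt(err[3], 0.005 * exact)
  # first-order convergence: halving dt about halves the error
  expect_gt(err[1] / err[2], 1.7)
  expect_lt(err[1] / err[2], 2.3)
  expect_gt(err[2] / err[3], 1.7)
  expect_lt(err[2] / err[3], 2.3)
})

test_that("components already at target are a fixed point", {
  vp <- volumeParams()
  pop <- randomPopulation(3, c(0, 0, 0), c(10, 10, 10))
  before <- pop[c("V", "V_F", "V_NS", "V_CS")]
  pop2 <- updateVolumes(pop, 6, vp)
  # quiescent seeds sit exactly at their targets (V_F = f_F * V)
  expect_equal(pop2$V_NS, before$V_NS, tolerance = 1e-12)
  expect_equal(pop2$V_CS, before$V_CS, tolerance = 1e-12)
  expect_equal(pop2$V_F, before$V_F, tolerance = 1e-9)
})

test_that("early necrotic cells swell and apoptotic cells shrink", {
  vp <- volumeParams()
  pop <- randomPopulation(2, c(0, 0, 0), c(10, 10, 10))
  pop$phase <- c(EARLY_NECROTIC, APOPTOTIC)
  V0 <- pop$V
  for (i in 1:50) pop <- updateVolumes(pop, 6, vp)
  expect_gt(pop$V[1], V0[1])   # oncotic fluid gain while f_F < 1
  expect_lt(pop$V[2], V0[2])   # all components decay toward zero
})

test_that("division halves all components and conserves volume exactly", {
  set.seed(7)
  pop <- randomPopulation(5, c(0, 0, 0), c(100, 100, 100))
  pop$phase[] <- PREMITOTIC
  total0 <- sum(pop$V)
  d <- divideCells(pop, c(2, 4))
  expect_equal(d$first$V, pop$V[c(2, 4)] / 2)
  expect_equal(d$first$V_NS, pop$V_NS[c(2, 4)] / 2)
  expect_equal(sum(d$first$V) + sum(d$second$V), pop$V[2] + pop$V[4])
  # daughters are symmetric about the parent center
  expect_equal(d$first$position + d$second$position,
               2 * pop$position[c(2, 4), ], ignore_attr = TRUE)
  expect_identical(d$first$phase, rep(POSTMITOTIC, 2))
  expect_identical(d$first$phase_clock, c(0, 0))
})

test_that("daughter displacement magnitude is R (1 - 2^(-1/3))", {
  set.seed(8)
  V <- 4 / 3 * pi * 8.412^3  # parent radius 8.412 um
  pop <- newCellPopulation(matrix(0, 1, 3), PREMITOTIC,
                           V_F = V * 0.75, V_NS = V * 0.1, V_CS = V * 0.15)
  d <- divideCells(pop, 1)
  disp <- sqrt(sum((d$first$position - pop$position)^2))
  expect_equal(disp, 8.412 * (1 - 2^(-1 / 3)), tolerance = 1e-12)
  expect_equal(disp, 1.735, tolerance = 1e-3)
})

test_that("birth/death bookkeeping matches a naive list rebuild", {
  set.seed(9)
  pop <- randomPopulation(20, c(0, 0, 0), c(200, 200, 200))
  pop$phase[c(3, 11)] <- PREMITOTIC
  removals <- rep(FALSE, 20)
  removals[c(5, 17, 18)] <- TRUE
  daughters <- divideCells(pop, c(3, 11))
  out <- applyBirthDeath(pop, c(3, 11), daughters, removals)
  expect_identical(out$n, 20L + 2L - 3L)
  # naive rebuild: survivors keep their state field-by-field
  survivors <- setdiff(seq_len(20), c(3, 11, 5, 17, 18))
  for (s in survivors) {
    row <- which(apply(out$position, 1, function(p)
      all(p == pop$position[s, ])))
    expect_length(row, 1)
    expect_identical(out$V[row], pop$V[s])
    expect_identical(out$phase[row], pop$phase[s])
    expect_identical(out$phase_clock[row], pop$phase_clock[s])
  }
  # no births, no deaths: identical population
  none <- applyBirthDeath(pop, integer(0), divideCells(pop, integer(0)),
                          rep(FALSE, 20))
  expect_identical(none, pop)
})

test_that("phase update applies transitions in the documented order", {
  p <- phaseParams()
  vp <- volumeParams()
  set.seed(10)
  # mature premitotic cell joins the division list
  pop <- randomPopulation(1, c(0, 0, 0), c(10, 10, 10))
  pop$phase <- PREMITOTIC
  pop$phase_clock <- 13 * 60
  up <- updatePhases(pop, 38, 6, p, vp)
  expect_identical(up$divisions, 1L)
  # postmitotic cell past T_postm becomes quiescent
  pop$phase <- POSTMITOTIC
  pop$phase_clock <- 2.5 * 60
  up <- updatePhases(pop, 38, 6, p, vp)
  expect_identical(up$population$phase, QUIESCENT)
  # all rates zero, clocks below thresholds: phase unchanged, clock advances
  p0 <- phaseParams(r_apop = 1e-300, r_pro_max = 1e-300)
  pop$phase <- QUIESCENT
  pop$phase_clock <- 0
  up <- updatePhases(pop, 38, 6, p0, vp)
  expect_identical(up$population$phase, QUIESCENT)
  expect_identical(up$population$phase_clock, 6)
  # swollen early necrotic cell ruptures into the late stage
  pop$phase <- EARLY_NECROTIC
  scale <- 2.1 * standardVolume(vp) / pop$V
  for (f in c("V", "V_F", "V_NS", "V_CS")) pop[[f]] <- pop[[f]] * scale
  up <- updatePhases(pop, 38, 6, p, vp)
  expect_identical(up$population$phase, LATE_NECROTIC)
  # shrunken dead cell is flagged for removal
  pop$phase <- APOPTOTIC
  scale <- 0.01 * standardVolume(vp) / pop$V
  for (f in c("V", "V_F", "V_NS", "V_CS")) pop[[f]] <- pop[[f]] * scale
  up <- updatePhases(pop, 38, 6, p, vp)
  expect_true(up$removals)
})

test_that("deterministic phase residence matches the configured durations", {
  p <- phaseParams(r_apop = 1e-300)
  vp <- volumeParams()
  set.seed(11)
  pop <- randomPopulation(1, c(0, 0, 0), c(10, 10, 10))
  pop$phase <- POSTMITOTIC
  pop$phase_clock <- 0
  dt <- 6
  t <- 0
  while (pop$phase == POSTMITOTIC && t < 5 * 60) {
    up <- updatePhases(pop, 38, dt, p, vp)
    pop <- up$population
    t <- t + dt
  }
  expect_lte(abs(t - 2.5 * 60), dt)
})

test_that("stochastic death fraction matches the exponential waiting time", {
  # 1e5 quiescent cells, apoptosis only at 0.0060/h, 10 h in 6-min steps
  p <- phaseParams(r_apop = 0.0060, r_pro_max = 1e-300)
  vp <- volumeParams()
  set.seed(12)
  pop <- randomPopulation(1e5, c(0, 0, 0), c(1000, 1000, 1000))
  for (s in 1:100) pop <- updatePhases(pop, 38, 6, p, vp)$population
  frac <- mean(pop$phase == APOPTOTIC)
  expected <- 1 - exp(-0.06)
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(frac - expected), 3 * se)
})
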