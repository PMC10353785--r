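test_that("Morton encoding interleaves bits as documented", {
  expect_identical(mortonEncode(0, 0, 0), 0)
  expect_identical(mortonEncode(1, 0, 0), 1)
  expect_identical(mortonEncode(0, 1, 0), 2)
  expect_identical(mortonEncode(0, 0, 1), 4)
  expect_identical(mortonEncode(3, 5, 1), mortonOracle(3L, 5L, 1L))
  expect_identical(mortonEncode(3, 5, 1), 143)
  set.seed(21)
  i <- sample(0:1023, 200, TRUE)
  j <- sample(0:1023, 200, TRUE)
  k <- sample(0:1023, 200, TRUE)
  expect_identical(mortonEncode(i, j, k),
                   mapply(mortonOracle, i, j, k))
  g <- newGrid(25, c(4, 4, 4))
  expect_error(mortonEncode(4, 0, 0, g), "out of domain")
  expect_error(mortonEncode(-1, 0, 0), "negative|out of domain")
})

test_that("voxel sorting is a permutation with correct contiguous ranges", {
  set.seed(22)
  g <- newGrid(25, c(10, 10, 10))
  pop <- randomPopulation(1000, c(0, 0, 0), rep(250, 3))
  sv <- sortByVoxel(pop, g)
  sp <- sv$population
  # permutation: every per-cell field is the same multiset
  expect_identical(sort(sp$position[, 1]), sort(pop$position[, 1]))
  expect_identical(sort(sp$V), sort(pop$V))
  expect_false(is.unsorted(sp$sort_key))
  # every voxel range contains exactly the cells brute-force assigned to it
  vox <- voxelIndex(sp, g)
  for (v in sample(0:(nVoxels(g) - 1), 50)) {
    rng <- (sv$grid$voxel_start[v + 1] + 1):sv$grid$voxel_end[v + 1]
    if (sv$grid$voxel_start[v + 1] == sv$grid$voxel_end[v + 1])
      rng <- integer(0)
    expect_identical(sort(which(vox$linear == v)), sort(rng))
  }
  # all cells in one voxel: a single range of length n
  one <- randomPopulation(17, c(1, 1, 1), rep(24, 3))
  sv1 <- sortByVoxel(one, g)
  expect_identical(sum(sv1$grid$voxel_end - sv1$grid$voxel_start), 17L)
  expect_identical(sv1$grid$voxel_end[1] - sv1$grid$voxel_start[1], 17L)
})

test_that("pairwise force has the documented supports and antisymmetry", {
  mp <- mechanicsParams()
  Ri <- 8; Rj <- 8
  RR <- Ri + Rj
  RA <- mp$adhesion_distance_factor * RR
  at <- function(d) pairwiseForce(c(0, 0, 0), c(d, 0, 0), Ri, Rj, mp)
  # at contact distance the repulsion vanishes, adhesion remains
  expect_equal(at(RR)[1], mp$C_cca * (1 - RR / RA)^2)
  # at the adhesive reach the total force vanishes
  expect_equal(at(RA), c(0, 0, 0))
  expect_equal(at(RA + 1), c(0, 0, 0))
  # half-overlap: repulsive magnitude C_ccr/4 plus the adhesive term
  f <- at(0.5 * RR)
  expect_equal(f[1],
               mp$C_cca * (1 - 0.5 * RR / RA)^2 - 10 * (1 - 0.5)^2)
  expect_equal(-10 * (1 - 0.5)^2, -2.5)
  # antisymmetry under i <-> j
  xi <- c(1, 2, 3); xj <- c(9, 7, 5)
  expect_equal(pairwiseForce(xi, xj, 7, 9, mp),
               -pairwiseForce(xj, xi, 9, 7, mp))
  expect_warning(f0 <- pairwiseForce(xi, xi, 7, 7, mp), "coincident")
  expect_equal(f0, c(-mp$C_ccr, 0, 0))
})

test_that("voxel-sorted forces equal the all-pairs oracle", {
  set.seed(23)
  g <- newGrid(25, c(4, 4, 4))
  mp <- mechanicsParams()
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    pop <- randomPopulation(n, c(0, 0, 0), rep(100, 3))
    sv <- sortByVoxel(pop, g)
    F <- aggregateForces(sv$population, sv$grid, mp)
    Fo <- allPairsForces(sv$population$position, cellRadius(sv$population),
                         mp)
    expect_lt(max(abs(F - Fo)), 1e-10)
    # Newton's third law: forces sum to zero with no motile force
    expect_lt(max(abs(colSums(F))), 1e-10)
  }
  # single cell feels only the motile force
  lone <- randomPopulation(1, c(40, 40, 40), c(60, 60, 60))
  sv <- sortByVoxel(lone, g)
  expect_equal(aggregateForces(sv$population, sv$grid, mp),
               matrix(0, 1, 3))
  mp2 <- mechanicsParams(F_mot = c(1, 2, 3))
  expect_equal(aggregateForces(sv$population, sv$grid, mp2),
               matrix(c(1, 2, 3), 1, 3))
})

test_that("overdamped velocities divide force by the drag coefficient", {
  F <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(cellVelocities(F, mechanicsParams()), F)
  expect_equal(cellVelocities(matrix(c(1, 0, 0), 1, 3),
                              mechanicsParams(eta = 2)),
               matrix(c(0.5, 0, 0), 1, 3))
  expect_equal(cellVelocities(matrix(0, 4, 3), mechanicsParams()),
               matrix(0, 4, 3))
})

test_that("Adams-Bashforth position update and its Euler bootstrap", {
  pop <- randomPopulation(1, c(0, 0, 0), c(10, 10, 10))
  x0 <- pop$position
  v <- matrix(c(2, 0, 0), 1, 3)
  # bootstrap reduces to Euler
  p1 <- updatePositions(pop, v, 0.1, bootstrap = TRUE)
  expect_equal(p1$position, x0 + 0.2 * matrix(c(1, 0, 0), 1, 3))
  expect_equal(p1$previous_velocity, v)
  # v_prev = 0, v_now = (2,0,0), dt = 0.1 -> displacement 0.3
  pop$previous_velocity <- matrix(0, 1, 3)
  p2 <- updatePositions(pop, v, 0.1)
  expect_equal(p2$position[1, 1] - x0[1, 1], 0.3)
  # equal velocities reduce to Euler; zero velocities are stationary
  pop$previous_velocity <- v
  p3 <- updatePositions(pop, v, 0.1)
  expect_equal(p3$position, x0 + 0.1 * v)
  pop$previous_velocity <- matrix(0, 1, 3)
  p4 <- updatePositions(pop, matrix(0, 1, 3), 0.1)
  expect_equal(p4$position, pop$position)
})

test_that("confinement projects cells into the box and the duct lumen", {
  g <- newGrid(25, c(20, 20, 20))
  duct <- ductGeometry(radius = 100, length = 450, closed_end = 50,
                       center_yz = c(250, 250))
  pop <- randomPopulation(3, c(100, 200, 200), c(110, 210, 210))
  R <- cellRadius(pop$V[1])
  # interior cell untouched
  pop$position[1, ] <- c(200, 250, 250)
  # radially outside the lumen by 5 um
  pop$position[2, ] <- c(200, 250 + 105, 250)
  # behind the closed end by 2 um
  pop$position[3, ] <- c(48, 250, 250)
  out <- applyConfinement(pop, g, duct)
  expect_equal(out$position[1, ], c(200, 250, 250))
  expect_equal(out$position[2, 2] - 250, 100 - R)
  expect_equal(out$position[3, 1], 50 + R)
  # box clamp without a duct
  pop$position[1, ] <- c(-50, 250, 600)
  out2 <- applyConfinement(pop, g, NULL)
  expect_gte(out2$position[1, 1], 0)
  expect_lte(out2$position[1, 3], 500)
})

test_that("two overlapping cells relax to the analytic equilibrium spacing", {
  set.seed(24)
  mp <- mechanicsParams()  # C_ccr 10, C_cca 0.4, factor 1.25
  R <- 8.41
  V <- 4 / 3 * pi * R^3
  d_star <- twoCellEquilibrium(R, mp)
  expect_equal(d_star, 16.02, tolerance = 1e-3)
  g <- newGrid(25, c(6, 6, 6))
  pos <- matrix(c(70, 75, 75, 80, 75, 75), 2, 3, byrow = TRUE)
  pop <- newCellPopulation(pos, QUIESCENT, V_F = 0.75 * V, V_NS = 0.1 * V,
                           V_CS = 0.15 * V)
  for (s in 1:4000) {
    sv <- sortByVoxel(pop, g)
    F <- aggregateForces(sv$population, sv$grid, mp)
    pop <- updatePositions(sv$population, cellVelocities(F, mp), 0.1,
                           bootstrap = s == 1)
  }
  d <- sqrt(sum((pop$position[1, ] - pop$position[2, ])^2))
  expect_lt(abs(d - d_star) / d_star, 0.01)
})
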