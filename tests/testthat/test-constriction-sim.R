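test_that("bead helices have exact spacing and the n-start phase offsets", {
  fils <- buildBeadHelix(HelixShape(20, 20), nStart = 2, nBeads = 12,
                         spacing = 5.6)
  expect_length(fils, 2)
  for (f in fils) {
    d <- sqrt(rowSums(diff(f@xyz)^2))
    expect_equal(d, rep(5.6, 11), tolerance = 1e-6)
  }
  # strands are phase-offset by 180 deg at matching z
  a0 <- atan2(fils[[1]]@xyz[, 2], fils[[1]]@xyz[, 1])
  a1 <- atan2(fils[[2]]@xyz[, 2], fils[[2]]@xyz[, 1])
  expect_equal(fils[[1]]@xyz[, 3], fils[[2]]@xyz[, 3])
  expect_equal(((a1 - a0) * 180 / pi) %% 360, rep(180, 12),
               tolerance = 1e-8)
  # pitch zero gives a planar ring arc
  ring <- buildBeadHelix(HelixShape(10, 0), nStart = 1, nBeads = 8,
                         spacing = 3)[[1]]
  expect_equal(ring@xyz[, 3], rep(0, 8))
  expect_equal(sqrt(rowSums(ring@xyz[, 1:2]^2)), rep(10, 8))
  expect_error(buildBeadHelix(HelixShape(20, 20), 1, 3), "nBeads")
  expect_error(buildBeadHelix(HelixShape(20, 20), 1, 8, spacing = -1),
               "spacing")
})

test_that("bead chains enforce the spacing invariant", {
  xyz <- buildBeadHelix(HelixShape(20, 20), 1, 6)[[1]]@xyz
  xyz[3, ] <- xyz[3, ] + c(3, 0, 0)       # > 20% bond distortion
  expect_error(BeadFilament(xyz, spacing = 5.6) |> validObject(), "20%")
  expect_error(new("BeadFilament", xyz = xyz[1:3, ], strand = 0L,
                   spacing = 5.6), "4 beads")
})

test_that("discrete curvature and twist recover analytic values", {
  # circle: Menger curvature is exact 1/R at any sane spacing
  ring <- buildBeadHelix(HelixShape(10, 0), 1, 12, spacing = 2)[[1]]
  ct <- discreteCurvatureTwist(ring)
  expect_equal(ct$kappa, rep(1 / 10, 10), tolerance = 0.01)
  expect_equal(abs(ct$tau), rep(0, 9), tolerance = 1e-10)
  # straight line: curvature 0, twist flagged undefined
  line <- cbind(seq(0, 10, length.out = 6) * 5.6, 0, 0)
  ctl <- discreteCurvatureTwist(line)
  expect_equal(ctl$kappa, rep(0, 4))
  expect_true(all(is.na(ctl$tau)))
  # helix at dimer spacing: within 5% of the continuous relations
  sh <- HelixShape(13.5, 20)
  fil <- buildBeadHelix(sh, 1, 20, spacing = 5.6)[[1]]
  ref <- shapeToCurvature(sh)
  cth <- discreteCurvatureTwist(fil)
  expect_equal(cth$kappa, rep(kappa(ref), 18), tolerance = 0.05)
  expect_equal(cth$tau, rep(tau(ref), 17), tolerance = 0.05)
  # left-handed helix gives negative twist density
  lh <- fil
  lh@xyz[, 2] <- -lh@xyz[, 2]
  expect_true(all(discreteCurvatureTwist(lh)$tau < 0))
})

test_that("system energy decomposes exactly into its terms", {
  fils <- buildBeadHelix(HelixShape(20, 20), 2, 10)
  tube <- MembraneTube(length = 20, n = 16, radius = 20)
  sys <- SimSystem(fils, tube)
  e <- systemEnergy(sys)
  expect_equal(e$total, e$filament + e$bond + e$membrane + e$coupling,
               tolerance = 1e-9)
  expect_gt(e$membrane, 0)
  expect_equal(e$coupling, 0, tolerance = 1e-12)  # beads start on the tube
  # a filament at its spontaneous shape has ~0 elastic energy
  sp <- curvatureToShape(CurvatureTwist(0.058, 0.041))
  free <- SimSystem(buildBeadHelix(sp, 1, 12))
  ef <- systemEnergy(free)
  # small residual from discretisation only
  expect_lt(ef$filament, 0.5)
  expect_lt(ef$bond, 1e-12)
})

test_that("two-start at doubled strand pitch carries less elastic energy", {
  # same radius, same rung spacing (10 nm), same total bead count
  one <- SimSystem(buildBeadHelix(HelixShape(20, 10), 1, 24))
  two <- SimSystem(buildBeadHelix(HelixShape(20, 20), 2, 12))
  expect_lt(systemEnergy(two)$filament, systemEnergy(one)$filament)
})

test_that("membrane-only relaxation finds the equilibrium tube", {
  sys <- SimSystem(tube = MembraneTube(length = 100, n = 32, radius = 30))
  traj <- relaxSystem(sys, maxSteps = 500, tol = 1e-10, chunk = 50)
  expect_true(all(diff(traj@energy) <= 0))
  rfin <- meanTubeRadius(finalState(traj)@tube)
  expect_equal(rfin, equilibriumRadius(), tolerance = 0.01)
})

test_that("a short free filament relaxes toward the spontaneous shape", {
  fil <- buildBeadHelix(HelixShape(15, 30), 1, 12)
  traj <- relaxSystem(SimSystem(fil), maxSteps = 1500, tol = 1e-8,
                      chunk = 150)
  expect_true(all(diff(traj@energy) <= 0))
  sh <- filamentShape(finalState(traj)@filaments[[1]])
  gm <- globalMinimum()
  expect_equal(helixRadius(sh), gm$radius, tolerance = 0.02 * gm$radius)
  expect_equal(helixPitch(sh), gm$pitch, tolerance = 0.02 * gm$pitch)
  # endpoint stationarity
  expect_lt(traj@finalGradInf, 0.05)
})

test_that("relaxation is deterministic for identical inputs", {
  run <- function() {
    fil <- buildBeadHelix(HelixShape(15, 25), 1, 8)
    relaxSystem(SimSystem(fil, seed = 7L), maxSteps = 300, tol = 1e-8,
                chunk = 100)
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1@energy, t2@energy)
  expect_identical(finalState(t1)@filaments[[1]]@xyz,
                   finalState(t2)@filaments[[1]]@xyz)
  expect_identical(t1@seed, 7L)
})

test_that("perturbed filaments carry more energy and relax back", {
  sp <- curvatureToShape(CurvatureTwist(0.058, 0.041))
  base <- buildBeadHelix(sp, 1, 10)
  pert <- makePerturbedFilament(sp, 1, 10, displacementSigma = 0.3,
                                seed = 5)
  e0 <- systemEnergy(SimSystem(base))$total
  e1 <- systemEnergy(SimSystem(pert))$total
  expect_gt(e1, e0)
  traj <- relaxSystem(SimSystem(pert), maxSteps = 1500, tol = 1e-8,
                      chunk = 150)
  sh <- filamentShape(finalState(traj)@filaments[[1]])
  gm <- globalMinimum()
  expect_equal(helixRadius(sh), gm$radius, tolerance = 0.02 * gm$radius)
  expect_equal(helixPitch(sh), gm$pitch, tolerance = 0.02 * gm$pitch)
})
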