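test_that("PDB round trip preserves atoms and coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  st <- writeTinyPdb(path, n = 10)
  back <- readStructure(path)
  expect_equal(nAtoms(back), 10)
  expect_equal(unique(back@atoms$chain), "A")
  expect_equal(coords(back), coords(st), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("superpose recovers exact transforms and enforces det +1", {
  path <- withr::local_tempfile(fileext = ".pdb")
  st <- writeTinyPdb(path, n = 20, seed = 9)
  # identity
  fit0 <- superpose(st, st)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(rotationAngle(fit0$transform), 0, tolerance = 1e-6)
  # 30 degrees about z
  Rz <- matrix(c(cos(pi / 6), sin(pi / 6), 0,
                 -sin(pi / 6), cos(pi / 6), 0, 0, 0, 1), 3, 3)
  rot <- applyTransform(st, RigidTransform(Rz, c(3, -2, 7)))
  fit <- superpose(st, rot)
  expect_equal(rotationAngle(fit$transform), 30, tolerance = 1e-6)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$transform@rotation), 1, tolerance = 1e-10)
  # near-planar adversarial fixture: mirrored copy must NOT be matched by
  # a reflection; the proper-rotation fit has nonzero residual
  set.seed(2)
  flat <- AtomicStructure(data.frame(
    chain = "A", resno = 1:12, insert = "", resid = "ALA", elety = "CA",
    elesy = "C", x = rnorm(12, sd = 10), y = rnorm(12, sd = 10),
    z = rnorm(12, sd = 0.05)))
  mirr <- flat
  mirr@atoms$z <- -mirr@atoms$z
  mirr@atoms$x <- mirr@atoms$x + 1    # break exact coincidence
  fitm <- superpose(flat, mirr)
  expect_equal(det(fitm$transform@rotation), 1, tolerance = 1e-10)
})

test_that("superpose matches the bio3d least-squares fit", {
  path <- withr::local_tempfile(fileext = ".pdb")
  st <- writeTinyPdb(path, n = 30, seed = 4)
  set.seed(21)
  tf <- randomRigidTransform()
  moved <- applyTransform(st, tf)
  moved@atoms$x <- moved@atoms$x + rnorm(30, sd = 0.3)  # imperfect match
  fit <- superpose(moved, st)
  # independent oracle: bio3d rmsd after its own fit
  oracle <- bio3d::rmsd(as.vector(t(coords(st))),
                        as.vector(t(coords(moved))), fit = TRUE)
  expect_equal(fit$rmsd, oracle, tolerance = 2e-3)  # bio3d rounds to 3 dp
})

test_that("no random rigid transform beats the Kabsch fit", {
  path <- withr::local_tempfile(fileext = ".pdb")
  st <- writeTinyPdb(path, n = 15, seed = 13)
  noisy <- st
  set.seed(31)
  noisy@atoms$x <- noisy@atoms$x + rnorm(15, sd = 1)
  noisy@atoms$y <- noisy@atoms$y + rnorm(15, sd = 1)
  fit <- superpose(noisy, st)
  X <- coords(noisy); Y <- coords(st)
  for (i in 1:200) {
    tf <- randomRigidTransform()
    rmsd <- sqrt(mean(rowSums((applyTransform(X, tf) - Y)^2)))
    expect_gte(rmsd, fit$rmsd - 1e-9)
  }
})

test_that("degenerate and underspecified selections are rejected", {
  line <- AtomicStructure(data.frame(
    chain = "A", resno = 1:6, insert = "", resid = "GLY", elety = "CA",
    elesy = "C", x = 1:6, y = 2 * (1:6), z = -(1:6)))
  expect_error(superpose(line, line), "collinear")
  a <- AtomicStructure(data.frame(
    chain = "A", resno = 1:2, insert = "", resid = "GLY", elety = "CA",
    elesy = "C", x = c(0, 1), y = c(0, 0), z = c(0, 1)))
  expect_error(superpose(a, a), "3 paired")
})

test_that("hinge angle recovers constructed rotations", {
  fx <- makeTwoDomainHinge(46, atomsPerDomain = 60, seed = 3)
  res <- hingeAngle(fx$s1, fx$s2, fx$domains$A, fx$domains$B)
  expect_equal(res$angle, 46, tolerance = 0.1)
  expect_equal(res$alignRMSD, 0, tolerance = 1e-8)
  # identical structures give zero
  res0 <- hingeAngle(fx$s1, fx$s1, fx$domains$A, fx$domains$B)
  expect_equal(res0$angle, 0, tolerance = 1e-5)
  # missing domain errors name the domain
  ghost <- DomainDefinition("ghost", c(5000, 5100))
  expect_error(hingeAngle(fx$s1, fx$s2, ghost, fx$domains$B), "ghost")
})

test_that("hinge angle is invariant under global rigid motions", {
  fx <- makeTwoDomainHinge(34, atomsPerDomain = 80, seed = 8)
  base <- hingeAngle(fx$s1, fx$s2, fx$domains$A, fx$domains$B)$angle
  set.seed(17)
  for (i in 1:5) {
    g1 <- randomRigidTransform()
    g2 <- randomRigidTransform()
    moved <- hingeAngle(applyTransform(fx$s1, g1),
                        applyTransform(fx$s2, g2),
                        fx$domains$A, fx$domains$B)$angle
    expect_equal(moved, base, tolerance = 1e-6)
  }
})

test_that("hinge recovery sweeps the full angular range", {
  for (ang in c(1, 15, 60, 120, 179)) {
    fx <- makeTwoDomainHinge(ang, atomsPerDomain = 50, seed = 2)
    res <- hingeAngle(fx$s1, fx$s2, fx$domains$A, fx$domains$B)
    expect_equal(res$angle, ang, tolerance = 1e-6)
  }
})

test_that("interface conservation compares contact maps across models", {
  # two chains forming an interface
  set.seed(6)
  mkPair <- function(shift) {
    A <- cbind(rnorm(30, sd = 4), rnorm(30, sd = 4), rnorm(30, sd = 4))
    B <- sweep(cbind(rnorm(30, sd = 4), rnorm(30, sd = 4),
                     rnorm(30, sd = 4)), 2, c(shift, 0, 0), "+")
    AtomicStructure(data.frame(
      chain = rep(c("A", "B"), each = 30), resno = rep(1:30, 2),
      insert = "", resid = "ALA", elety = "CA", elesy = "C",
      x = c(A[, 1], B[, 1]), y = c(A[, 2], B[, 2]),
      z = c(A[, 3], B[, 3])))
  }
  s <- mkPair(8)
  same <- interfaceConservation(s, s, c("A", "B"))
  expect_equal(same$jaccard, 1)
  expect_equal(same$interfaceRMSD, 0, tolerance = 1e-9)
  expect_gt(same$nContacts1, 0)
  # chain B pushed far away: no shared contacts
  far <- s
  keep <- far@atoms$chain == "B"
  far@atoms$x[keep] <- far@atoms$x[keep] + 500
  gone <- interfaceConservation(s, far, c("A", "B"))
  expect_equal(gone$jaccard, 0)
  # both interfaces empty: Jaccard undefined
  none <- interfaceConservation(far, far, c("A", "B"))
  expect_true(is.na(none$jaccard))
  # shuffled residue numbering is an error, not a silent mismatch
  shuf <- s
  shuf@atoms$resno[shuf@atoms$chain == "A"] <- c(2:30, 31)
  expect_error(interfaceConservation(s, shuf, c("A", "B")),
               "residue number|paired")
})

test_that("altloc filtering keeps the highest occupancy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00 10.00           C",
    "ATOM      4  CA  ALA A   3       7.600   1.000   0.000  1.00 10.00           C",
    "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00 10.00           O",
    "END")
  writeLines(lines, path)
  st <- readStructure(path)
  expect_equal(nAtoms(st), 3)                       # HETATM dropped
  expect_equal(st@atoms$x[st@atoms$resno == 1], 5)  # occupancy 0.60 wins
})

test_that("shipped dynamin domain definitions load and partition residues", {
  doms <- dynamin1Domains()
  expect_named(doms, c("Gdomain", "BSE", "Stalk", "PH"))
  expect_s4_class(doms$BSE, "DomainDefinition")
  expect_equal(nrow(doms$BSE@ranges), 3)
  # no overlap between G domain and BSE
  g <- unlist(apply(doms$Gdomain@ranges, 1, function(v) v[1]:v[2]))
  b <- unlist(apply(doms$BSE@ranges, 1, function(v) v[1]:v[2]))
  expect_length(intersect(g, b), 0)
  expect_error(DomainDefinition("bad", c(10, 20), c(15, 30)), "overlap")
})
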