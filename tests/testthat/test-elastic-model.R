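# Hand-evaluated oracle for the per-length elastic energy, kept separate
# from the package implementation.
oracleEnergyPerLength <- function(r, p, aK = 3000, aT = 2700,
                                  k0 = 0.058, t0 = 0.041) {
  h <- p / (2 * pi)
  k <- r / (h^2 + r^2)
  t <- h / (h^2 + r^2)
  aK * (k - k0)^2 + aT * (t - t0)^2
}

test_that("energy per length is the quadratic form, zero only at rest", {
  p <- FilamentElasticParams()
  expect_equal(energyPerLength(CurvatureTwist(0.058, 0.041), p), 0)
  expect_equal(energyPerLength(shapeToCurvature(HelixShape(13.5, 10)), p),
               oracleEnergyPerLength(13.5, 10))
  expect_equal(round(energyPerLength(
    shapeToCurvature(HelixShape(13.5, 10)), p), 3), 3.512)
  expect_equal(round(energyPerLength(
    shapeToCurvature(HelixShape(13.5, 20)), p), 3), 2.059)
  # strictly positive away from the spontaneous configuration
  set.seed(3)
  for (i in 1:20) {
    ct <- CurvatureTwist(runif(1, 0.001, 0.2), runif(1, -0.1, 0.1))
    e <- energyPerLength(ct, p)
    expect_gte(e, 0)
    if (abs(kappa(ct) - 0.058) > 1e-6 || abs(tau(ct) - 0.041) > 1e-6)
      expect_gt(e, 0)
  }
})

test_that("energy per dimer scales by the dimer length and adds g0", {
  expect_equal(energyPerDimer(HelixShape(13.5, 10)),
               oracleEnergyPerLength(13.5, 10) * 5.6)
  expect_equal(round(energyPerDimer(HelixShape(13.5, 10)), 2), 19.67)
  expect_equal(round(energyPerDimer(HelixShape(13.5, 20)), 2), 11.53)
  sp <- curvatureToShape(CurvatureTwist(0.058, 0.041))
  expect_equal(energyPerDimer(sp), 0, tolerance = 1e-12)
  pg <- FilamentElasticParams(g0 = 1.5)
  expect_equal(energyPerDimer(HelixShape(13.5, 10), pg),
               energyPerDimer(HelixShape(13.5, 10)) + 1.5 * 5.6)
})

test_that("landscape grid matches pointwise evaluation and holds the minimum", {
  ls <- energyLandscape(10, 20, 10, 60, nR = 2, nP = 2)
  expect_equal(dim(ls@energy), c(2, 2))
  for (i in 1:2) for (j in 1:2)
    expect_equal(ls@energy[i, j],
                 energyPerDimer(ls@radius[i], pitch = ls@pitch[j]))
  # grid through the closed-form minimum attains ~0 there
  ls2 <- energyLandscape(5, 25, 5, 80, nR = 201, nP = 301)
  expect_true(all(ls2@energy >= 0))
  i <- arrayInd(which.min(ls2@energy), dim(ls2@energy))
  gm <- globalMinimum()
  expect_equal(ls2@radius[i[1]], gm$radius, tolerance = 0.11)
  expect_equal(ls2@pitch[i[2]], gm$pitch, tolerance = 0.26)
  df <- as.data.frame(ls)
  expect_named(df, c("radius_nm", "pitch_nm", "energy_kjmol"))
  expect_equal(nrow(df), 4)
  expect_error(energyLandscape(5, 4, 5, 80), "rMin")
})

test_that("radius minimisation at fixed pitch agrees with a brute scan", {
  rs <- seq(5, 30, by = 0.01)
  scan <- rs[which.min(energyPerDimer(rs, pitch = 10))]
  m <- minEnergyOverRadius(10, rBounds = c(5, 30))
  expect_equal(m$radius, scan, tolerance = 0.011)
  # local minimality
  expect_lte(m$energy, energyPerDimer(m$radius + 0.1, pitch = 10))
  expect_lte(m$energy, energyPerDimer(m$radius - 0.1, pitch = 10))
  # the global minimum lies on the minimal-energy curve
  gm <- globalMinimum()
  m2 <- minEnergyOverRadius(gm$pitch, rBounds = c(5, 30))
  expect_equal(m2$radius, gm$radius, tolerance = 1e-4)
  expect_equal(m2$energy, 0, tolerance = 1e-8)
  expect_warning(minEnergyOverRadius(10, rBounds = c(20, 30)), "boundary")
})

test_that("minimal-energy curve is monotone on either side of the optimum", {
  gm <- globalMinimum()
  ps <- seq(5, 80, by = 2.5)
  es <- vapply(ps, function(p)
    minEnergyOverRadius(p, rBounds = c(1, 60))$energy, 0)
  below <- ps < gm$pitch
  expect_true(all(diff(es[below]) <= 1e-9))
  expect_true(all(diff(es[!below]) >= -1e-9))
})

test_that("global minimum closed form agrees with a dense grid search", {
  gm <- globalMinimum()
  expect_equal(round(gm$radius, 2), 11.5)
  expect_equal(round(gm$pitch, 1), 51.1)
  expect_equal(gm$energy, 0)
  # dense 0.05 nm grid oracle
  rs <- seq(5, 25, by = 0.05)
  ps <- seq(5, 80, by = 0.05)
  e <- outer(rs, ps, function(r, p) energyPerDimer(r, pitch = p))
  i <- arrayInd(which.min(e), dim(e))
  expect_equal(rs[i[1]], gm$radius, tolerance = 0.051)
  expect_equal(ps[i[2]], gm$pitch, tolerance = 0.051)
  # zero spontaneous twist degenerates to a planar ring
  ring <- globalMinimum(FilamentElasticParams(tau0 = 0))
  expect_equal(ring$pitch, 0)
  expect_equal(ring$radius, 1 / 0.058)
})

test_that("two-start beats one-start at the super-constricted radius", {
  ms <- multistartComparison(13.5, rungSpacing = 10, kStarts = c(1, 2))
  e1 <- ms$energies$energy_kjmol[ms$energies$k == 1]
  e2 <- ms$energies$energy_kjmol[ms$energies$k == 2]
  expect_equal(round(e1, 2), 19.67)
  expect_equal(round(e2, 2), 11.53)
  expect_gt(e1, e2)
  expect_equal(ms$deltaOneTwo, e1 - e2)
  expect_equal(round(ms$deltaOneTwo, 2), 8.14)
  expect_error(multistartComparison(13.5, kStarts = 0), "start")
})

test_that("the two-start advantage grows as the filament constricts", {
  rs <- seq(11, 18, by = 0.1)
  d <- vapply(rs, function(r) multistartComparison(r)$deltaOneTwo, 0)
  expect_true(all(diff(d) < 0))      # shrinking r => growing advantage
  # and two-start is never worse at fixed radius across [5, 25] nm
  rs2 <- seq(5, 25, by = 0.1)
  e1 <- energyPerDimer(rs2, pitch = 10)
  e2 <- energyPerDimer(rs2, pitch = 20)
  expect_true(all(e2 <= e1 + 1e-12))
})

test_that("constant g0 shifts the landscape without moving any argmin", {
  p0 <- FilamentElasticParams()
  pg <- FilamentElasticParams(g0 = 2)
  ls0 <- energyLandscape(8, 20, 5, 70, nR = 41, nP = 41, params = p0)
  lsg <- energyLandscape(8, 20, 5, 70, nR = 41, nP = 41, params = pg)
  expect_equal(lsg@energy, ls0@energy + 2 * 5.6, tolerance = 1e-10)
  expect_equal(which.min(lsg@energy), which.min(ls0@energy))
  gm0 <- globalMinimum(p0); gmg <- globalMinimum(pg)
  expect_equal(gmg$radius, gm0$radius)
  expect_equal(gmg$pitch, gm0$pitch)
  expect_equal(gmg$energy, 2 * 5.6)
})

test_that("lumen mapping is a clamped offset diameter", {
  lm <- lumenDiameter(13.5, offset = 11.5)
  expect_equal(lm$diameter, 4)
  expect_equal(lm$offset, 11.5)
  expect_equal(lumenDiameter(9, offset = 0)$diameter, 18)
  expect_error(lumenDiameter(10, offset = 11.5), "exceed")
})
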