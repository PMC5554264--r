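test_that("preset loader: published values and unit conversion", {
  p <- loadPreset("isolated_iso")
  pt <- p@params@perType
  # target area: 2.11e3 um^2 -> 337.6 subcells of 6.25 um^2
  expect_equal(pt$targetVolume[pt$type == "CM"], 2.11 * 160)
  # Lmax: 66.64 um -> 26.656 subcells
  expect_equal(pt$Lmax[pt$type == "CM"], 66.64 / 2.5)
  # G: printed mm over rho in mm == 400 x printed with rho in subcells
  expect_equal(pt$G[pt$type == "CM"], 47.48 * 400)
  expect_equal(p@params@temperature, 1.0)
  expect_equal(p@mcs, 900L)
  expect_equal(p@dims, c(400L, 400L))
  expect_equal(p@seedGrid, c(17L, 7L))
  # monolayer preset: 26 x 26 areas on 0.8 x 0.8 mm, 2000 MCS
  m <- loadPreset("monolayer_iso")
  expect_equal(m@seedGrid, c(26L, 26L))
  expect_equal(m@sampleDim, c(0.8, 0.8))
  expect_equal(m@mcs, 2000L)
  expect_equal(loadPreset("monolayer_fibres")@mcs, 3000L)
  # loader purity
  expect_identical(loadPreset("isolated_fibres"), loadPreset("isolated_fibres"))
})

test_that("preset J matrices are symmetric with zero medium-medium entry", {
  for (nm in presetNames()) {
    J <- loadPreset(nm)@params@J
    expect_equal(J, t(J))
    expect_equal(J[1, 1], 0)
  }
})

test_that("seed side follows sqrt(Vt/10); types split by largest remainder", {
  # Vt = 1000 subcells -> side 10
  par <- modelParams(lambda = c(1, 1), targetVolume = c(1000, 640),
                     G = c(1, 1), Pdetach = c(0, 0), Punleash = c(0, 0),
                     Lmax = c(50, 50), Nprotr = c(5, 5),
                     J = matrix(0, 3, 3))
  plan <- seedingPlan(c(60, 60), c(2, 2), fbFraction = 0.5)
  set.seed(1)
  st <- seedCells(plan, par)
  expect_equal(sort(unique(cellTable(st)$volume)),
               sort(unique(c(10 * 10, 8 * 8))))
  expect_equal(sum(cellTable(st)$type == "FB"), 2)
  expect_true(all(adhesionSites(st)[[1]] |> nrow() == 0))
  # exact split: fraction 0.5 on an even count
  plan2 <- seedingPlan(c(120, 120), c(4, 4), fbFraction = 0.5)
  set.seed(2)
  st2 <- seedCells(plan2, par)
  expect_equal(sum(cellTable(st2)$type == "FB"), 8)
  expect_equal(sum(cellTable(st2)$type == "CM"), 8)
})

test_that("seeds do not overlap and fit their areas", {
  par <- modelParams(lambda = c(1, 1), targetVolume = c(360, 360),
                     G = c(1, 1), Pdetach = c(0, 0), Punleash = c(0, 0),
                     Lmax = c(50, 50), Nprotr = c(5, 5),
                     J = matrix(0, 3, 3))
  plan <- seedingPlan(c(48, 48), c(6, 6), fbFraction = 0.3)
  set.seed(3)
  st <- seedCells(plan, par)
  expect_equal(nrow(cellTable(st)), 36)
  expect_true(all(cellTable(st)$volume == 36))  # side 6, no clipping
  expect_true(auditLattice(st))
  # a seed that cannot fit errors out
  planBad <- seedingPlan(c(10, 10), c(4, 4), fbFraction = 0)
  expect_error(suppressWarnings(seedCells(planBad, par)), "fit")
})

test_that("fibre fields: pitch, orientation, full coverage limit", {
  f <- generateFibreField(c(40, 40), 0, 4)
  expect_equal(sum(rowSums(f@occupied) > 0), 10)
  expect_true(all(f@orientation[f@occupied] == 0))
  f2 <- generateFibreField(c(40, 40), pi / 3, 1)
  expect_true(all(f2@occupied))
  expect_equal(unique(as.vector(f2@orientation)), pi / 3)
})

test_that("L-shaped mask geometry and junction placement", {
  m <- buildLShapeMask(c(100, 100), 50)
  expect_equal(mean(m), 0.75)
  j <- attr(m, "junction")
  expect_true(m[j[1], j[2]])
  # junction at the intersection of the arm middle lines
  expect_equal(j, c(75, 25))
  full <- buildLShapeMask(c(60, 60), 60)
  expect_true(all(full))
})

test_that("zero MCS returns the seeding unchanged; formation is seeded", {
  p <- loadPreset("isolated_iso")
  st <- growTissue(p, seed = 5, nMCS = 0, dims = c(80, 80))
  expect_equal(mcsCount(st), 0L)
  a <- growTissue(p, seed = 5, nMCS = 15, dims = c(80, 80))
  b <- growTissue(p, seed = 5, nMCS = 15, dims = c(80, 80))
  expect_identical(sigmaMatrix(a), sigmaMatrix(b))
  c <- growTissue(p, seed = 6, nMCS = 15, dims = c(80, 80))
  expect_false(identical(sigmaMatrix(a), sigmaMatrix(c)))
})

test_that("monolayer medium fraction shrinks during early formation", {
  p <- loadPreset("monolayer_iso")
  st <- growTissue(p, seed = 8, nMCS = 60, dims = c(120, 120),
                   recordEvery = 10)
  lg <- formationLog(st)
  expect_gt(nrow(lg), 2)
  # early spreading fills the dish monotonically in trend
  expect_lt(lg$mediumFraction[nrow(lg)], lg$mediumFraction[1])
})

test_that("masked growth keeps every cell inside the admissible domain", {
  p <- loadPreset("monolayer_iso")
  mask <- buildLShapeMask(c(120, 120), 60)
  st <- growTissue(p, seed = 9, nMCS = 30, dims = c(120, 120), mask = mask)
  expect_true(all(sigmaMatrix(st)[!mask] == 0))
  expect_gt(nrow(cellTable(st)), 20)
})
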