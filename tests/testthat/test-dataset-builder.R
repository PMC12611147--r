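# Frame rendering, pair construction, splitting, persistence.

test_that("rendering produces the binary mask and normalized field channels", {
  st <- rectState(L = 10L, r = 3:5, c = 4:7,
                  field = matrix(seq(0, 0.99, length.out = 100), 10, 10))
  fr <- renderFrame(st, normalization = 0.5, simId = "s1")
  expect_equal(sum(frameMask(fr)), 12)
  expect_true(all(frameMask(fr) %in% c(0, 1)))
  expect_equal(frameField(fr), chemField(st) / 0.5, tolerance = 1e-14)
  # all-medium state renders an empty mask
  fr0 <- renderFrame(latticeState(matrix(0L, 10, 10)), 1)
  expect_equal(sum(frameMask(fr0)), 0)
})

test_that("rendering commutes with cyclic shifts", {
  set.seed(6)
  st <- randomState(L = 10L)
  fr <- renderFrame(st, 2)
  stS <- latticeState(cyclicShift(cellLattice(st), 3, 4),
                      cyclicShift(chemField(st), 3, 4))
  frS <- renderFrame(stS, 2)
  expect_identical(frameMask(frS), cyclicShift(frameMask(fr), 3, 4))
  expect_identical(frameField(frS), cyclicShift(frameField(fr), 3, 4))
})

test_that("pair construction reproduces the protocol combinatorics", {
  # the standard window: unit cadence 200..20000, horizon 100
  expect_equal(nrow(buildPairs(200:20000, horizon = 100)), 19700L)
  # a window exactly one horizon long yields nothing under the half-open rule
  expect_equal(nrow(buildPairs(0:100, horizon = 100)), 0L)
  # enumeration check on a small window
  pr <- buildPairs(0:300, horizon = 100)
  expect_equal(nrow(pr), 200L)
  expect_equal(pr[1, ], c(input = 1L, target = 101L))
  expect_equal(pr[200, ], c(input = 200L, target = 300L))
  # every pair spans exactly one horizon (no leakage)
  mcs <- 0:300
  expect_true(all(mcs[pr[, 2]] - mcs[pr[, 1]] == 100))
  # works on coarser cadences when the horizon is representable
  expect_equal(nrow(buildPairs(seq(200, 2000, by = 100), horizon = 100)), 17L)
})

test_that("the split is seeded, disjoint and exhaustive", {
  sp <- splitPairs(10, seed = 1)
  expect_equal(length(sp$train), 8L)
  expect_equal(length(sp$test), 2L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(splitPairs(10, seed = 1), sp)
  expect_false(identical(splitPairs(10, seed = 2), sp))
  expect_error(splitPairs(0), "empty")
  expect_error(splitPairs(10, fraction = 1.2), "fraction")
})

test_that("datasets assemble, persist and round-trip exactly", {
  p <- cpmParams(latticeSize = 16L, nCellsInitial = 2L, seedBlockSide = 3L)
  r1 <- simulateVasculogenesis(p, seed = 1, mcsStartSave = 10, mcsEnd = 40,
                               saveEvery = 10)
  r2 <- simulateVasculogenesis(p, seed = 2, mcsStartSave = 10, mcsEnd = 40,
                               saveEvery = 10)
  ds1 <- makeDataset(r1, horizon = 10)
  ds2 <- makeDataset(list(r1, r2), horizon = 10)
  # pair counts are additive across simulations and never cross runs
  expect_equal(nrow(ds2@pairs), 2 * nrow(ds1@pairs))
  sims <- vapply(ds2@frames, function(f) f@simId, character(1))
  expect_true(all(sims[ds2@pairs[, 1]] == sims[ds2@pairs[, 2]]))
  # the default normalization is the saturation scale r/k
  expect_equal(ds2@normalization, p@secretionRate / p@decayRate)

  path <- tempfile(fileext = ".rds")
  writeDataset(ds2, path)
  back <- readDataset(path)
  expect_equal(back, ds2)
  # wrong container rejected
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = 99L), bad)
  expect_error(readDataset(bad), "format")
})

test_that("the by-simulation split keeps whole runs together", {
  p <- cpmParams(latticeSize = 16L, nCellsInitial = 2L, seedBlockSide = 3L)
  runs <- lapply(1:4, function(s)
    simulateVasculogenesis(p, seed = s, mcsStartSave = 10, mcsEnd = 40,
                           saveEvery = 10))
  ds <- makeDataset(runs, horizon = 10, splitBy = "simulation", seed = 3)
  sims <- vapply(ds@frames, function(f) f@simId, character(1))
  trainSims <- unique(sims[ds@pairs[ds@trainIdx, 1]])
  testSims <- unique(sims[ds@pairs[ds@testIdx, 1]])
  expect_length(intersect(trainSims, testSims), 0)
})
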