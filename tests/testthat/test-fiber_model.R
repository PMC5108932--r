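test_that("gap-junction interface currents follow Ohm's law and conserve charge", {
  expect_equal(gapCurrents(c(-80, -80, -80), 10), c(0, 0))
  expect_equal(gapCurrents(c(-70, -80), 10), 100)     # 10 mV x 10 uS
  set.seed(3)
  V <- runif(30, -90, 40)
  igj <- gapCurrents(V, 7.5)
  # net coupling current over the whole fiber is zero (sealed ends)
  percell <- c(-igj[1], igj[-length(igj)] - igj[-1], igj[length(igj)])
  expect_equal(sum(percell), 0, tolerance = 1e-10)
  expect_error(gapCurrents(-80, 10), "2 cells")
  expect_error(gapCurrents(c(NA, -80), 10), "finite")
})

test_that("fiber right-hand side reduces to independent cells when uncoupled", {
  y <- stateVector(defaultRest)
  cfg0 <- fiberConfig(nCells = 3, gGj = 0)
  d <- fiberDerivatives(broadcastState(y, 3), config = cfg0)
  dcell <- cellDerivatives(y, params = defaultParams)
  expect_equal(d, rep(unname(dcell), 3), tolerance = 1e-14)

  # identical states, nonzero coupling: still the isolated derivative
  cfg <- fiberConfig(nCells = 2, gGj = 10)
  d2 <- fiberDerivatives(broadcastState(y, 2), config = cfg)
  expect_equal(d2, rep(unname(dcell), 2), tolerance = 1e-14)
})

test_that("a depolarized cell sheds exactly its coupling current", {
  y <- stateVector(defaultRest)
  cfg <- fiberConfig(nCells = 3, gGj = 10)
  state <- broadcastState(y, 3)
  state[23] <- state[23] + 10           # depolarize the middle cell 10 mV
  d <- fiberDerivatives(state, config = cfg)
  yMid <- y; yMid["V"] <- yMid[["V"]] + 10
  dIso <- cellDerivatives(yMid, params = defaultParams)
  Cm <- paramVector(defaultParams)[["Cm"]]
  # two interfaces x 100 nA leave the middle cell
  expect_equal(d[23], dIso[["V"]] - 200 / Cm, tolerance = 1e-10)
  expect_error(fiberDerivatives(state[1:10], config = cfg), "66")
  expect_error(fiberDerivatives(state, config = cfg, stim = c(0, 0)),
               "number of cells")
})

test_that("uniform resting fiber is translation invariant and at rest", {
  cfg <- fiberConfig(nCells = 10)
  state <- fiberRestingState(cfg)
  expect_length(state, 220)
  d <- fiberDerivatives(state, config = cfg)
  expect_lt(max(abs(d)), 1e-6)
  # all interior cells have identical derivatives
  dm <- matrix(d, nrow = 22)
  for (i in 3:8) expect_equal(dm[, i], dm[, 2], tolerance = 1e-14)
})

test_that("stimulating both sealed ends produces a mirror-symmetric response", {
  cfg <- fiberConfig(nCells = 20, gGj = 10)
  prot <- stimulusProtocol(amplitude = -40, nPulses = 1,
                           targetCells = c(1, 2, 19, 20))
  tr <- runSimulation(NULL, prot, cfg, tSpan = c(0, 25), coarseStep = 0.5)
  vm <- traceVm(tr)
  expect_lt(max(abs(vm - vm[, 20:1])), 1e-4)
})

test_that("the assembled study fiber carries 22 states per cell", {
  cfg <- fiberConfig()            # 100 cells, the study geometry
  expect_equal(nCells(cfg), 100L)
  state <- fiberRestingState(cfg)
  expect_length(state, 2200)
  expect_equal(length(state) / nCells(cfg), 22)
  expect_error(fiberConfig(nCells = 1), "at least 2")
})
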