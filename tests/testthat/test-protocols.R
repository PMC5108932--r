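test_that("AP detection separates full APs from subthreshold responses", {
  prot <- stimulusProtocol(amplitude = -25, nPulses = 1)
  tr <- runSimulation(NULL, prot, defaultParams, tSpan = c(0, 100))
  expect_true(detectAP(tr, 1))
  quiet <- stimulusProtocol(amplitude = 0, nPulses = 0)
  tr0 <- runSimulation(NULL, quiet, defaultParams, tSpan = c(0, 100))
  expect_false(detectAP(tr0, 1))
  sub <- stimulusProtocol(amplitude = -15, nPulses = 1)
  trs <- runSimulation(NULL, sub, defaultParams, tSpan = c(0, 100))
  expect_false(detectAP(trs, 1))
  expect_error(detectAP(tr, 1, window = c(500, 600)), "empty")
})

test_that("bracketing threshold search equals a literal incremental scan", {
  for (gk1 in c(0.4, 0.5, 0.8)) {
    p <- cellParameters(gK1 = gk1)
    fast <- findCellThreshold(p, startGuess = -10)
    # literal 0.5 nA incremental search with the same pacing criterion
    rest <- restingState(p)
    succ <- function(amp) {
      prot <- stimulusProtocol(amplitude = amp, nPulses = 2)
      fiberAP:::.pacingSuccess(p, prot, detectCell = 1L, windowLen = 50,
                               initial = rest)
    }
    k <- 1L
    while (!succ(-k * 0.5)) k <- k + 1L
    expect_equal(fast@threshold, -k * 0.5)
    expect_true(fast@excitable)
    expect_lt(fast@nSimulations, k)  # and it gets there in fewer runs
  }
})

test_that("threshold search result does not depend on the warm start", {
  a <- findCellThreshold(defaultParams, startGuess = -5)
  b <- findCellThreshold(defaultParams, startGuess = -80)
  d <- findCellThreshold(defaultParams)
  expect_equal(a@threshold, b@threshold)
  expect_equal(a@threshold, d@threshold)
})

test_that("single-cell threshold magnitude is monotone in each conductance", {
  tNa <- vapply(c(0.5, 1, 2), function(g)
    findCellThreshold(cellParameters(gNa = g),
                      startGuess = -19)@threshold, numeric(1))
  expect_true(all(diff(abs(tNa)) < 0))   # raising G_Na lowers |threshold|
  tK1 <- vapply(c(0.5, 1, 2), function(g)
    findCellThreshold(cellParameters(gK1 = g),
                      startGuess = -19)@threshold, numeric(1))
  expect_true(all(diff(abs(tK1)) > 0))   # raising G_K1 raises |threshold|
})

test_that("APD measurement recovers the width of a rectangular pulse", {
  for (w in c(80, 150, 300)) {
    tr <- rectangularTrace(width = w, dt = 0.1)
    expect_equal(measureAPD(tr, 1, level = 0.9), w, tolerance = 0.01)
    # the level does not matter for a rectangle
    expect_equal(measureAPD(tr, 1, level = 0.5), w, tolerance = 0.01)
  }
  quietTrace <- rectangularTrace(width = 0.05, peak = -40)
  expect_error(measureAPD(quietTrace), "no action potential")
})

test_that("space-constant fit on the passive fixture matches the closed form", {
  for (gm in c(0.2, 0.5)) {
    spec <- passiveFiberSpec(gm = gm, gGj = 10, nCells = 100)
    fit <- measureSpaceConstant(passiveFiberFixture(spec))
    lam <- analyticSpaceConstant(gm, 10)
    expect_lt(abs(fit@lambda / lam - 1), 0.02)
    expect_gt(fit@lambda, 0)
    expect_true(is.finite(fit@residualNorm))
    # stimulated cells and the sealed far end are excluded from the fit
    expect_false(any(fit@cells %in% c(1:4, 96:100)))
  }
})

test_that("passive fiber steady state matches a dense linear ladder solve", {
  n <- 40; gm <- 0.4; ggj <- 5; I <- 2
  spec <- passiveFiberSpec(gm = gm, gGj = ggj, nCells = n)
  cfg <- passiveFiberFixture(spec)
  # sustained current into cell 1; steady profile from a long pulse
  prot <- stimulusProtocol(amplitude = -I, duration = 400, nPulses = 1,
                           onset = 1, targetCells = 1L)
  tr <- runSimulation(NULL, prot, cfg, tSpan = c(0, 401), coarseStep = 5)
  vEnd <- traceVm(tr)[nrow(tr@vm), ]
  # dense oracle: (G_m + L) v = I e1 for the resistive ladder
  L <- matrix(0, n, n)
  diag(L) <- gm + c(ggj, rep(2 * ggj, n - 2), ggj)
  L[cbind(1:(n - 1), 2:n)] <- -ggj
  L[cbind(2:n, 1:(n - 1))] <- -ggj
  vOracle <- solve(L, c(I, rep(0, n - 1)))
  expect_equal(unname(vEnd - spec@eRest), vOracle, tolerance = 1e-3)
})

test_that("space-clamped passive response has time constant Cm/gm", {
  n <- 5; gm <- 0.5; Cm <- 0.095
  spec <- passiveFiberSpec(gm = gm, Cm = Cm, gGj = 50, nCells = n)
  cfg <- passiveFiberFixture(spec)
  # identical current into every cell: no gradients, pure RC relaxation
  tau <- Cm / gm
  prot <- stimulusProtocol(amplitude = -1, duration = 10 * tau,
                           nPulses = 1, onset = 0, targetCells = 1:n)
  tr <- runSimulation(NULL, prot, cfg, tSpan = c(0, 10 * tau),
                      coarseStep = tau / 50, atol = 1e-10, rtol = 1e-10)
  t <- traceTime(tr); v <- traceVm(tr, 3) - spec@eRest
  vInf <- 1 / gm
  expect_equal(v[length(v)], vInf, tolerance = 1e-3)
  iTau <- which.min(abs(t - tau))
  expect_equal(v[iTau], vInf * (1 - exp(-1)), tolerance = 0.01)
})

test_that("conduction velocity requires activation at the measuring cells", {
  cfg <- fiberConfig(nCells = 20)
  prot_ok <- TRUE
  expect_error(
    measureCV(fiberConfig(nCells = 20), threshold = -1, cells = c(5, 15)),
    "no activation")
})

test_that("APD90 shortens dramatically as G_K1 grows", {
  apdAt <- function(p, amp, tmax) {
    prot <- stimulusProtocol(amplitude = amp, nPulses = 1)
    tr <- runSimulation(NULL, prot, p, tSpan = c(0, tmax),
                        coarseStep = 0.5)
    measureAPD(tr, 1, level = 0.9)
  }
  apdDefault <- apdAt(defaultParams, -30, 1200)
  expect_gt(apdDefault, 120)         # guinea-pig scale plateau at 1 Hz rest
  expect_lt(apdDefault, 320)
  apdHigh <- apdAt(cellParameters(gK1 = 5), -150, 600)
  expect_lt(apdHigh, 20)             # milliseconds at G_K1 = 5 uS
  # the qualitative contrast is insensitive to the repolarization level
  prot <- stimulusProtocol(amplitude = -30, nPulses = 1)
  tr <- runSimulation(NULL, prot, defaultParams, tSpan = c(0, 1200),
                      coarseStep = 0.5)
  expect_lt(measureAPD(tr, 1, level = 0.5), apdDefault)
  expect_gt(measureAPD(tr, 1, level = 0.5), 100)
})
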