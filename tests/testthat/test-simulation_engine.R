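test_that("an unstimulated run stays at rest", {
  quiet <- stimulusProtocol(amplitude = 0, nPulses = 0)
  tr <- runSimulation(NULL, quiet, defaultParams, tSpan = c(0, 1000))
  expect_lt(max(abs(traceVm(tr, 1) - restV)), 0.5)
})

test_that("pulse edges appear bit-exactly in the output grid", {
  prot <- stimulusProtocol(amplitude = -25, nPulses = 2, period = 40,
                           onset = 5, duration = 0.2)
  tr <- runSimulation(NULL, prot, defaultParams, tSpan = c(0, 90))
  t <- traceTime(tr)
  for (edge in c(5, 5.2, 45, 45.2)) expect_true(any(t == edge))
  expect_true(all(diff(t) > 0))
  expect_true(all(is.finite(tr@vm)))
})

test_that("identical inputs produce identical traces", {
  prot <- stimulusProtocol(amplitude = -30, nPulses = 1)
  cfg <- fiberConfig(nCells = 10)
  tr1 <- runSimulation(NULL, prot, cfg, tSpan = c(0, 30))
  tr2 <- runSimulation(NULL, prot, cfg, tSpan = c(0, 30))
  expect_identical(tr1@vm, tr2@vm)
  expect_identical(traceTime(tr1), traceTime(tr2))
})

test_that("halving the solver tolerances leaves the AP essentially unchanged", {
  prot <- stimulusProtocol(amplitude = -90, nPulses = 1, targetCells = 1:4)
  cfg <- fiberConfig(nCells = 20)
  run <- function(tol) {
    tr <- runSimulation(NULL, prot, cfg, tSpan = c(0, 40), atol = tol,
                        rtol = tol, fineSpan = 35, postStep = 0.02)
    v <- traceVm(tr, 10)
    c(peak = max(v), tPeak = traceTime(tr)[which.max(v)])
  }
  a <- run(1e-6); b <- run(5e-7)
  expect_lt(abs(a[["peak"]] - b[["peak"]]), 0.5)
  expect_lt(abs(a[["tPeak"]] - b[["tPeak"]]), 0.1)
})

test_that("suprathreshold and subthreshold fiber responses separate cleanly", {
  cfg <- fiberConfig()   # 100 cells, gGj = 10
  supra <- stimulusProtocol(amplitude = -90, nPulses = 1, targetCells = 1:4)
  tr <- runSimulation(NULL, supra, cfg, tSpan = c(0, 120), coarseStep = 0.5)
  v5 <- traceVm(tr, 5)
  expect_gt(max(v5), 0)         # full AP at cell 5
  sub <- stimulusProtocol(amplitude = -45, nPulses = 1, targetCells = 1:4)
  tr2 <- runSimulation(NULL, sub, cfg, tSpan = c(0, 120), coarseStep = 0.5)
  v5s <- traceVm(tr2, 5)
  expect_lt(max(v5s), 0)        # subthreshold: depolarizes then decays
  expect_gt(max(v5s), restV + 5)
  expect_lt(abs(v5s[length(v5s)] - restV), 5)
})

test_that("trace accessors and exports are consistent", {
  prot <- stimulusProtocol(amplitude = -30, nPulses = 1)
  cfg <- fiberConfig(nCells = 5)
  tr <- runSimulation(NULL, prot, cfg, tSpan = c(0, 20), saveStates = TRUE)
  expect_equal(dim(traceVm(tr)), c(length(traceTime(tr)), 5))
  expect_equal(ncol(tr@states), 110)
  # states and vm agree on the voltage columns
  expect_equal(unname(tr@states[, 1 + (0:4) * 22]), unname(traceVm(tr)))
  df <- traceAsDataFrame(tr)
  expect_equal(nrow(df), 5 * length(traceTime(tr)))
  expect_equal(df$Vm[df$cell == 3], unname(traceVm(tr, 3)))
  expect_length(finalState(tr), 110)
})
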