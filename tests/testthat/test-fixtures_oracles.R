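test_that("discrete-cable space constant has the right limits and monotonicity", {
  # continuum limit: lambda -> sqrt(gGj / gm)
  expect_lt(abs(analyticSpaceConstant(1e-3, 1) / sqrt(1 / 1e-3) - 1), 0.01)
  # exact unit decay: gm/gGj = e + 1/e - 2 makes r = e, lambda = 1
  x <- exp(1) + exp(-1) - 2
  expect_equal(analyticSpaceConstant(x, 1), 1, tolerance = 1e-12)
  # strictly decreasing in gm, increasing in gGj
  lam <- analyticSpaceConstant(seq(0.1, 2, by = 0.1), 10)
  expect_true(all(diff(lam) < 0))
  lam2 <- analyticSpaceConstant(0.5, seq(1, 20, by = 1))
  expect_true(all(diff(lam2) > 0))
  expect_error(analyticSpaceConstant(-1, 10), "positive")
  expect_error(analyticSpaceConstant(0.5, 0), "positive")
})

test_that("simulation, dense linear solve and closed form agree on the ladder", {
  combos <- list(c(0.2, 5), c(0.5, 10), c(1, 10), c(0.5, 2), c(2, 20))
  for (cb in combos) {
    gm <- cb[1]; ggj <- cb[2]; n <- 60
    spec <- passiveFiberSpec(gm = gm, gGj = ggj, nCells = n)
    fit <- measureSpaceConstant(passiveFiberFixture(spec))
    lamClosed <- analyticSpaceConstant(gm, ggj)
    # fitted decay vs closed form
    expect_lt(abs(fit@lambda / lamClosed - 1), 0.02)
    # dense linear-algebra oracle for the same steady state
    L <- matrix(0, n, n)
    diag(L) <- gm + c(ggj, rep(2 * ggj, n - 2), ggj)
    L[cbind(1:(n - 1), 2:n)] <- -ggj
    L[cbind(2:n, 1:(n - 1))] <- -ggj
    stim <- c(rep(1, 4), rep(0, n - 4))   # unit current into cells 1-4
    v <- solve(L, stim)
    iMid <- 20:40
    lamDense <- -1 / coef(lm(log(v[iMid]) ~ iMid))[[2]]
    expect_lt(abs(lamDense / lamClosed - 1), 0.02)
  }
})

test_that("study grids cover the published parameter ranges", {
  grids <- buildPaperGrids()
  expect_named(grids, c("independentGNa", "independentGK1", "reciprocal12",
                        "reciprocal11", "reciprocal21"))
  gna <- grids$independentGNa@grid
  expect_true(all(gna >= 0.2 & gna <= 5))
  expect_equal(range(gna), c(0.2, 5))
  gk1 <- grids$independentGK1@grid
  expect_true(all(gk1 >= 0.3 & gk1 <= 5))
  # 0.1 uS resolution across the excitability boundary
  expect_true(all(seq(1, 1.5, by = 0.1) %in% gk1))
  # eight coupling conductances spanning 0.1-20 uS including the default 10
  ggj <- grids$reciprocal11@gGj
  expect_length(ggj, 8)
  expect_true(all(ggj >= 0.1 & ggj <= 20))
  expect_true(10 %in% ggj)
  expect_equal(range(ggj), c(0.1, 20))
  # all three reciprocal stoichiometries are present
  ratios <- lapply(grids[c("reciprocal12", "reciprocal11", "reciprocal21")],
                   function(s) s@ratio)
  expect_equal(ratios$reciprocal12, c(1, 2))
  expect_equal(ratios$reciprocal11, c(1, 1))
  expect_equal(ratios$reciprocal21, c(2, 1))
})

test_that("the passive fixture runs through the production simulation path", {
  spec <- passiveFiberSpec(gm = 0.5, eRest = -88, gGj = 10, nCells = 30)
  cfg <- passiveFiberFixture(spec)
  prot <- stimulusProtocol(amplitude = -2, duration = 50, nPulses = 1,
                           targetCells = 1:4)
  tr <- runSimulation(NULL, prot, cfg, tSpan = c(0, 60), saveStates = TRUE)
  # non-voltage states stay frozen at their placeholder values
  nonV <- setdiff(seq_len(22 * 30), 1 + (0:29) * 22)
  expect_equal(tr@states[nrow(tr@states), nonV], tr@states[1, nonV])
  # voltages relax back toward eRest after the pulse ends
  expect_lt(max(abs(traceVm(tr)[1, ] - spec@eRest)), 1e-8)
  expect_gt(max(traceVm(tr, 1)), spec@eRest + 1)
})
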