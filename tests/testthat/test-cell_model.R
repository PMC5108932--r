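test_that("inward-rectifier current matches its closed form and sign conventions", {
  p <- defaultParams
  v <- paramVector(p)
  Ki <- fiberAP:::.initialStateGuess()[["Ki"]]
  EK <- thermalVoltage(v[["T"]]) * log(v[["Ko"]] / Ki)

  # zero driving force at the potassium Nernst potential
  expect_equal(computeIK1(EK, p, Ki = Ki), 0)

  # 10 mV above E_K the rectification denominator is exactly 2
  expect_equal(computeIK1(EK + 10, p, Ki = Ki),
               v[["gK1"]] * v[["Ko"]] / (v[["Ko"]] + v[["kmK1"]]) * 5,
               tolerance = 1e-12)

  # independent scalar evaluation of the full formula at an arbitrary point
  Vm <- -62.3
  rtf <- 8314.472 * v[["T"]] / 96485.3415
  expected <- v[["gK1"]] * (v[["Ko"]] / (v[["Ko"]] + v[["kmK1"]])) *
    (Vm - EK) / (1 + exp((Vm - EK - 10) * v[["rectK1"]] / rtf))
  expect_equal(computeIK1(Vm, p, Ki = Ki), expected, tolerance = 1e-12)

  # outward-positive above E_K
  expect_gt(computeIK1(EK + 5, p, Ki = Ki), 0)
  expect_lt(computeIK1(EK - 5, p, Ki = Ki), 0)
  expect_error(computeIK1(NaN, p), "finite")
})

test_that("inward rectification gives I_K1 an interior maximum in Vm", {
  vgrid <- seq(-95, 20, by = 1)
  i <- computeIK1(vgrid, defaultParams)
  imax <- which.max(i)
  expect_gt(imax, 1)
  expect_lt(imax, length(vgrid))
  # monotone rise just above E_K, decline at depolarized potentials
  expect_true(all(diff(i[1:(imax - 1)]) > 0))
  expect_lt(i[length(i)], i[imax] / 2)
})

test_that("fast sodium current follows G_Na m^3 h (V - E_rev)", {
  p <- defaultParams
  Erev <- sodiumReversal(p)
  expect_equal(computeINa(-40, 0, 0.7, p), 0)
  expect_equal(computeINa(Erev, 0.5, 0.5, p), 0)
  expect_equal(computeINa(Erev - 50, 1, 1, p), -0.5 * 50)
  expect_error(computeINa(-40, 1.2, 0.5, p), "\\[0, 1\\]")
  expect_error(computeINa(Inf, 0.5, 0.5, p), "finite")
})

test_that("both study currents are linear in their conductances", {
  p1 <- defaultParams
  p2 <- cellParameters(gK1 = 2 * gK1(p1), gNa = 2 * gNa(p1))
  vgrid <- seq(-90, 30, by = 5)
  expect_equal(computeIK1(vgrid, p2), 2 * computeIK1(vgrid, p1),
               tolerance = 1e-14)
  expect_equal(computeINa(vgrid, 0.3, 0.6, p2),
               2 * computeINa(vgrid, 0.3, 0.6, p1), tolerance = 1e-14)
})

test_that("the current set sums exactly to the reported total", {
  set.seed(11)
  for (k in 1:8) {
    y <- randomCellState()
    cur <- computeCurrents(y, defaultParams)
    expect_equal(cur[["Iion"]], sum(cur[setdiff(names(cur), "Iion")]),
                 tolerance = 1e-12)
  }
})

test_that("compiled and reference right-hand sides agree to machine precision", {
  set.seed(42)
  for (k in 1:12) {
    p <- randomParams()
    y <- randomCellState()
    iext <- runif(1, -50, 10)
    dC <- cellDerivatives(y, params = p, iExt = iext)
    dR <- fiberAP:::.cellRhsR(y, p, iExt = iext)
    scale <- pmax(abs(dR), 1e-6)
    expect_lt(max(abs(dC - dR) / scale), 1e-10)
  }
})

test_that("membrane equation is linear in the external current", {
  y <- stateVector(defaultRest)
  d0 <- cellDerivatives(y, params = defaultParams, iExt = 0)
  d1 <- cellDerivatives(y, params = defaultParams, iExt = -100)
  Cm <- paramVector(defaultParams)[["Cm"]]
  expect_equal(d1[["V"]] - d0[["V"]], 100 / Cm, tolerance = 1e-12)
  expect_equal(d1[-1], d0[-1])  # only the voltage equation sees I_ext
  expect_error(cellDerivatives(y[1:10]), "22")
})

test_that("gates relax to their voltage-dependent steady state", {
  for (V in c(-80, -40, 0)) {
    y <- stateVector(defaultRest)
    y["V"] <- V
    for (g in c("m", "h", "s", "xr1", "xs"))
      y[g] <- gateSteadyState(g, V, defaultParams)
    dy <- cellDerivatives(y, params = defaultParams)
    for (g in c("m", "h", "s", "xr1", "xs"))
      expect_lt(abs(dy[[g]]), 1e-12)
  }
})

test_that("the quiescent rest point has the reported physiology", {
  y <- stateVector(defaultRest)
  # fixed point of the full 22-state system
  expect_lt(max(abs(cellDerivatives(y, params = defaultParams))), 1e-6)
  # resting potential around -90 mV (the study reports -85 to -90)
  expect_gt(y[["V"]], -95)
  expect_lt(y[["V"]], -85)
  # near the potassium Nernst potential the rectifier carries almost
  # nothing compared to its peak
  iK1rest <- computeIK1(y[["V"]], defaultParams, Ki = y[["Ki"]])
  peak <- max(computeIK1(seq(-95, 0, 1), defaultParams, Ki = y[["Ki"]]))
  expect_lt(abs(iK1rest), 0.2 * peak)
  # re-integrating 1000 ms without stimulus stays put
  quiet <- stimulusProtocol(amplitude = 0, nPulses = 0)
  tr <- runSimulation(defaultRest, quiet, defaultParams, tSpan = c(0, 1000))
  expect_lt(max(abs(traceVm(tr, 1) - y[["V"]])), 0.1)
})

test_that("cell state validity guards gates and concentrations", {
  y <- stateVector(defaultRest)
  expect_s4_class(cellState(y), "CellState")
  bad <- y; bad["m"] <- 1.5
  expect_error(cellState(bad), "gating")
  bad <- y; bad["Nai"] <- -1
  expect_error(cellState(bad), "positive")
  expect_error(cellState(unname(y)), "named")
})

test_that("constants serialize and read back exactly", {
  path <- tempfile(fileext = ".json")
  writeCellConstants(cellParameters(gK1 = 1.25), path)
  p <- readCellConstants(path)
  expect_equal(paramVector(p)[["gK1"]], 1.25)
  expect_equal(paramVector(p), paramVector(cellParameters(gK1 = 1.25)))
  # the shipped constants file is the package default
  shipped <- system.file("extdata", "cell_constants.json",
                         package = "fiberAP")
  expect_equal(paramVector(readCellConstants(shipped)),
               defaultCellConstants())
})
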