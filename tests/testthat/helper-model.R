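# shared fixtures, computed once per test run

defaultParams <- cellParameters()
defaultRest <- restingState(defaultParams)
restV <- stateVector(defaultRest)[["V"]]

# a small fiber for engine-level tests (cheap), and the study fiber
smallFiber <- fiberConfig(nCells = 20)

# draw a physiologically plausible random cell state (for property tests)
randomCellState <- function() {
  y <- stateVector(defaultRest)
  y["V"] <- runif(1, -95, 40)
  for (g in c("m", "h", "d", "f", "f2", "f2ds", "s", "r", "xr1", "xr2",
              "xs")) y[g] <- runif(1)
  af <- runif(1, 0, 0.5); y["ActFrac"] <- af
  y["ProdFrac"] <- runif(1, 0, 1 - af)
  y["Nai"] <- runif(1, 4, 12); y["Ki"] <- runif(1, 120, 150)
  y["Cai"] <- 10^runif(1, -5.5, -3.2)
  y["Cads"] <- 10^runif(1, -5.5, -2.5)
  y["Caup"] <- runif(1, 0.1, 1); y["Carel"] <- runif(1, 0.1, 1)
  y["CaCalmod"] <- runif(1, 0, 0.019)
  y["CaTrop"] <- runif(1, 0, 0.049)
  y
}

# random parameter perturbation exercising the R/C layout contract
randomParams <- function() {
  cellParameters(gK1 = runif(1, 0.3, 3), gNa = runif(1, 0.2, 3),
                 gKs = runif(1, 0.001, 0.03), gpNa = runif(1, 0, 0.006),
                 Kmf2ds = runif(1, 5e-4, 2e-3), kNaCa = runif(1, 2e-4, 1e-3))
}

# rectangular pseudo-AP trace for APD plumbing tests
rectangularTrace <- function(onset = 10, width = 150, rest = -85,
                             peak = 20, dt = 0.1, tEnd = 400) {
  t <- seq(0, tEnd, by = dt)
  v <- rep(rest, length(t))
  v[t > onset & t <= onset + width] <- peak
  prot <- stimulusProtocol(amplitude = -1, nPulses = 1, onset = onset)
  new("SimulationTrace", time = t, vm = matrix(v, ncol = 1),
      states = NULL, protocol = prot, config = defaultParams,
      finalState = numeric(22))
}

# lazily computed expensive shared quantities
accCache <- new.env()
defaultFiberThreshold <- function() {
  if (is.null(accCache$thr))
    accCache$thr <- findFiberThreshold(fiberConfig(),
                                       startGuess = -40)@threshold
  accCache$thr
}
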