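# Independent oracles and fixture builders used across the suite.

# Finite-volume steady-state solver on a grid aligned with the zone
# interfaces: second-order central differences with the reaction rate
# averaged over each control volume (exact for piecewise-quadratic
# solutions when interfaces fall on nodes). Independent of the package's
# closed-form solver.
fdSolveSteadyState <- function(scenario, solute, h = 1) {
  L <- scenario@length
  stopifnot(abs(L / h - round(L / h)) < 1e-9,
            all(abs(scenario@boundaries / h -
                    round(scenario@boundaries / h)) < 1e-9))
  z <- seq(0, L, by = h)
  n <- length(z)
  edges <- c(0, scenario@boundaries, L)
  K <- length(edges) - 1L
  spec <- scenario@solutes[[solute]]
  d0 <- d0InfiniteDilution(spec, scenario@temperature, scenario@salinity,
                           scenario@pressure)
  Ds <- sedimentDiffusivity(d0, scenario@porosity)
  R <- scenario@rates[[solute]]
  if (is.null(R)) R <- rep(0, K)

  # rate per control volume: zone rate at interior nodes, mean of the two
  # adjacent zone rates at interface nodes
  rateAt <- function(zi) {
    onEdge <- which(abs(edges - zi) < 1e-9)
    if (length(onEdge) && onEdge > 1L && onEdge <= K)
      return((R[onEdge - 1L] + R[onEdge]) / 2)
    k <- findInterval(zi, edges, all.inside = TRUE)
    R[k]
  }

  hM <- h / 100
  A <- matrix(0, n, n); rhs <- numeric(n)
  A[1, 1] <- 1; rhs[1] <- scenario@bcTop[[solute]]
  A[n, n] <- 1; rhs[n] <- scenario@bcBottom[[solute]]
  for (i in 2:(n - 1L)) {
    A[i, i - 1L] <- 1; A[i, i] <- -2; A[i, i + 1L] <- 1
    rhs[i] <- -rateAt(z[i]) / Ds * hM^2
  }
  list(depth = z, conc = solve(A, rhs))
}

# Random 3-zone single-solute scenario with a non-negative solution
# (rejection sampling over seeds derived from `seed`).
randomThreeZoneScenario <- function(seed) {
  for (attempt in 0:49) {
    s <- seed + 100003L * attempt
    par <- withr::with_seed(s, list(
      b = sort(sample(seq(10, 110, by = 5), 2)),
      rates = stats::runif(3, -3, 3),
      bc = stats::runif(2, 2, 20)
    ))
    sc <- syntheticScenario(120, 2, boundaries = par$b,
                            rates = list(nitrate = par$rates),
                            bcTop = c(nitrate = par$bc[1]),
                            bcBottom = c(nitrate = par$bc[2]),
                            seed = s)
    tr <- try(solveSteadyState(sc), silent = TRUE)
    if (!inherits(tr, "try-error")) return(list(scenario = sc, truth = tr))
  }
  stop("no valid random scenario found for seed ", seed)
}

# Three-zone nitrite scenario with detectable nitrite throughout, used to
# check consumption-zone recovery against prescribed boundaries.
nitriteThreeZoneScenario <- function(spacing = 2, noiseSd = 0, seed = 1L) {
  syntheticScenario(240, spacing, boundaries = c(40, 90, 120, 190),
                    rates = list(nitrite = c(0, -0.168, 0.84, -0.168, 0)),
                    bcTop = c(nitrite = 0.5), bcBottom = c(nitrite = 0.5),
                    noiseSd = noiseSd, seed = seed)
}

# Analytic detection-limit crossing of a scenario truth (shallowest root of
# C(z) = dl below the last depth where C > dl), by bisection on the closed
# form. `from` brackets the crossing from above.
truthCrossing <- function(truth, solute, dl, lower, upper) {
  f <- function(z) truthConcentration(truth, solute, z) - dl
  stats::uniroot(f, lower = lower, upper = upper, tol = 1e-10)$root
}

# Profile builders for hand-made cases.
makeProfile <- function(depth, ..., censored = NULL, porosity = 0.7,
                        solutes = defaultSolutes()) {
  conc <- cbind(...)
  depthProfile(depth, conc, censored = censored, porosity = porosity,
               solutes = solutes)
}
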