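test_that("infinite-dilution diffusivities match the published linear fits", {
  sol <- defaultSolutes()
  toM2yr <- 1e-10 * 31557600
  # frozen from the published fit coefficients (1e-6 cm2/s):
  # nitrate (9.50, 0.388), nitrite (10.3, 0.331), at 0, 10, 25 C
  cases <- list(
    list(sol$nitrate, 0, 9.50), list(sol$nitrate, 10, 13.38),
    list(sol$nitrate, 25, 19.20),
    list(sol$nitrite, 0, 10.30), list(sol$nitrite, 10, 13.61),
    list(sol$nitrite, 25, 18.575))
  for (cs in cases) {
    got <- d0InfiniteDilution(cs[[1]], cs[[2]], salinity = 0,
                              pressure = 1.013253)
    expect_equal(got, cs[[3]] * toM2yr, tolerance = 0.01,
                 info = sprintf("%s at %g C", cs[[1]]@name, cs[[2]]))
  }
  # independent tracer-table values at 25 C (Li & Gregory), 1e-6 cm2/s
  expect_equal(d0InfiniteDilution(sol$nitrate, 25, 0, 1.013253),
               19.0 * toM2yr, tolerance = 0.05)
  expect_equal(d0InfiniteDilution(sol$nitrite, 25, 0, 1.013253),
               19.1 * toM2yr, tolerance = 0.05)
})

test_that("diffusivity behaves with temperature, salinity and degenerate coefficients", {
  sol <- defaultSolutes()
  for (s in sol)
    expect_lt(d0InfiniteDilution(s, 10), d0InfiniteDilution(s, 20))
  # m1 = 0 -> temperature-independent, equal to converted m0
  flat <- soluteSpec("flat", m0 = 10, m1 = 0)
  expect_equal(d0InfiniteDilution(flat, 5, 0, 1.013253),
               d0InfiniteDilution(flat, 25, 0, 1.013253))
  expect_equal(d0InfiniteDilution(flat, 5, 0, 1.013253),
               10 * 1e-10 * 31557600)
  # seawater is more viscous than pure water -> smaller D0
  expect_lt(d0InfiniteDilution(sol$nitrate, 2, 35, 100),
            d0InfiniteDilution(sol$nitrate, 2, 0, 1.013253))
  expect_warning(d0InfiniteDilution(sol$nitrate, 35), "extrapolating")
})

test_that("tortuosity correction obeys its limits and is monotone in porosity", {
  expect_equal(sedimentDiffusivity(0.03, 1), 0.03)
  expect_equal(sedimentDiffusivity(0.03, 0.6), 0.03 / (1 - log(0.36)))
  phis <- seq(0.05, 1, by = 0.01)
  for (model in c("log", "power")) {
    ds <- sedimentDiffusivity(0.03, phis, model = model)
    expect_true(all(diff(ds) > 0), info = model)
    expect_true(all(ds <= 0.03 + 1e-15), info = model)
  }
  expect_equal(sedimentDiffusivity(0.03, 1, model = "power"), 0.03)
  expect_error(sedimentDiffusivity(0.03, 0), "porosity")
})

test_that("three-point gradient equals an independent least-squares solution", {
  # exact line: 1 uM/cm = 100 mmol m-4
  p <- makeProfile(c(0, 1, 2), nitrate = c(0, 1, 2))
  expect_equal(localGradient(p, "nitrate", 1:3)$gradient, 100)
  # flat profile
  pf <- makeProfile(c(0, 5, 10), nitrate = c(7, 7, 7))
  expect_equal(localGradient(pf, "nitrate", 1:3)$gradient, 0)
  # noisy triplets against the normal equations, to 1e-10 relative
  for (seed in 1:20) {
    vals <- withr::with_seed(seed, list(
      z = sort(stats::runif(3, 0, 200)),
      c = stats::runif(3, 0, 30)))
    p <- makeProfile(vals$z, nitrate = vals$c)
    got <- localGradient(p, "nitrate", 1:3)$gradient
    X <- cbind(1, vals$z / 100)
    beta <- solve(t(X) %*% X, t(X) %*% vals$c)
    expect_equal(got, beta[2, 1], tolerance = 1e-10)
  }
  expect_error(localGradient(p, "nitrate", 1:2), "3 consecutive")
  expect_error(localGradient(p, "nitrate", c(1, 3, 4)), "3 consecutive")
})

test_that("Fick's law flux carries magnitude, sign convention and linearity", {
  expect_equal(boundaryFlux(0, 0.8, 0.01)$J, 0)
  fl <- boundaryFlux(100, 0.8, 0.01)
  expect_equal(fl$magnitude, 0.8)
  expect_equal(fl$direction, "upward")   # conc increasing downward
  expect_equal(boundaryFlux(-100, 0.8, 0.01)$direction, "downward")
  expect_equal(boundaryFlux(200, 0.8, 0.01)$magnitude, 2 * fl$magnitude)
  expect_error(boundaryFlux(1, 0, 0.01), "porosity")
  expect_error(boundaryFlux(1, 0.8, -1), "Ds")
})

test_that("net reaction rate matches the analytic curvature oracle", {
  # C(z) = a z^2 (z in m) -> R = -2 a phi Ds everywhere inside
  a <- 40
  zCm <- seq(0, 100, by = 5)
  p <- makeProfile(zCm, nitrate = a * (zCm / 100)^2, porosity = 0.8)
  R <- netReactionRate(p, "nitrate", Ds = 0.02)
  expect_true(all(is.na(R[c(1, length(R))])))
  expect_equal(unname(R[2:(length(R) - 1)]),
               rep(-2 * a * 0.8 * 0.02, length(R) - 2), tolerance = 1e-9)
  # linear profile -> zero rate at interior points
  pl <- makeProfile(zCm, nitrate = 20 - 0.1 * zCm)
  Rl <- netReactionRate(pl, "nitrate", Ds = 0.02)
  expect_equal(unname(Rl[2:(length(Rl) - 1)]), rep(0, length(Rl) - 2),
               tolerance = 1e-12)
  # sign pattern reproduces prescribed production/consumption zones
  out <- generateProfile(nitriteThreeZoneScenario())
  Rz <- netReactionRate(out$profile, "nitrite")
  z <- depths(out$profile)
  expect_true(all(Rz[z > 42 & z < 88] < 0))
  expect_true(all(Rz[z > 92 & z < 118] > 0))
  expect_true(all(Rz[z > 122 & z < 188] < 0))
  expect_error(netReactionRate(makeProfile(c(0, 10), nitrate = c(1, 2)),
                               "nitrate"), "3 depths")
})

test_that("flux divergence between windows is consistent with the rate profile", {
  # on a smooth profile, [J(i+1) - J(i-1)] / dz ~ -R(i) (bulk rate)
  out <- generateProfile(presetScenario("GS14-like", spacing = 1))
  p <- out$profile
  z <- depths(p)
  Ds <- out$truth@Ds[["nitrite"]]
  R <- netReactionRate(p, "nitrite", Ds = Ds)
  i <- which(z == 105)  # inside the production zone, away from interfaces
  grad <- function(j) localGradient(p, "nitrite", (j - 1):(j + 1))$gradient
  Jm <- boundaryFlux(grad(i - 1), 0.7, Ds)$J
  Jp <- boundaryFlux(grad(i + 1), 0.7, Ds)$J
  div <- (Jp - Jm) / ((z[i + 1] - z[i - 1]) / 100)
  expect_equal(div, -R[i], tolerance = 0.02)
})

test_that("site fluxes recover analytic boundary fluxes on noise-free profiles", {
  out <- generateProfile(presetScenario("GS14-like", spacing = 2))
  zones <- deriveZones(out$profile)
  fl <- siteFluxes(out$profile, zones)
  tr <- out$truth
  Jno3 <- abs(truthFlux(tr, "nitrate", zones@nitrateDepletionDepth))
  Jup <- abs(truthFlux(tr, "nitrite", zones@nitriteInterval[1]))
  Jdn <- abs(truthFlux(tr, "nitrite", zones@nitriteInterval[2]))
  expect_equal(fl@JNO3In, Jno3, tolerance = 0.05)
  expect_equal(fl@JNO2Up, Jup, tolerance = 0.05)
  expect_equal(fl@JNO2Down, Jdn, tolerance = 0.05)
  expect_equal(fl@ratio, (Jup + Jdn) / Jno3, tolerance = 0.05)
})

test_that("site fluxes handle missing nitrite and missing windows explicitly", {
  # nitrite censored everywhere -> zero effluxes, zero ratio
  p <- censorToDetection(makeProfile(seq(0, 100, 10),
    nitrate = c(20, 16, 12, 8, 4, 2, 1, 0.5, 0.05, 0, 0),
    nitrite = rep(0, 11)))
  fl <- siteFluxes(p)
  expect_equal(fl@JNO2Up, 0)
  expect_equal(fl@JNO2Down, 0)
  expect_equal(fl@ratio, 0)
  expect_gt(fl@JNO3In, 0)

  # too few points above the crossing -> named flux error
  p2 <- censorToDetection(makeProfile(c(0, 10, 20),
    nitrate = c(20, 5, 0), nitrite = rep(0, 3)))
  expect_error(siteFluxes(p2), "nitrate window")

  # nitrite detected at only 2 depths -> named window error
  p3 <- censorToDetection(makeProfile(seq(0, 100, 10),
    nitrate = c(20, 16, 12, 8, 4, 2, 1, 0.5, 0.05, 0, 0),
    nitrite = c(0, 0, 0, 0.5, 0.6, 0, 0, 0, 0, 0, 0)))
  expect_error(siteFluxes(p3), "nitrite windows")
})

test_that("fluxes and ratio are invariant under depth-unit and concentration scaling", {
  out <- generateProfile(presetScenario("GS14-like", noiseSd = 0.1,
                                        seed = 3))
  p <- out$profile
  fl <- siteFluxes(p)

  # same data expressed in metres, read back through the m -> cm conversion
  tf <- withr::local_tempfile(fileext = ".csv")
  tab <- utils::read.csv(textConnection(
    paste(readLines(writeProfileTable(p, tf)), collapse = "\n")))
  tab$depth_cm <- tab$depth_cm / 100
  tf2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, tf2, row.names = FALSE, quote = FALSE)
  pm <- censorToDetection(readProfileTable(tf2, site = siteInfo(p),
                                           depthUnit = "m"))
  flm <- siteFluxes(pm)
  expect_equal(flm@JNO3In, fl@JNO3In, tolerance = 1e-9)
  expect_equal(flm@ratio, fl@ratio, tolerance = 1e-9)

  # concentrations (and DLs) scaled by a constant: ratio unchanged
  k <- 3.7
  scaled <- depthProfile(depths(p), concentrations(p) * k,
                         censored = isCensored(p), porosity = porosity(p),
                         solutes = lapply(p@solutes, function(s) {
                           s@detectionLimit <- s@detectionLimit * k
                           s
                         }), site = siteInfo(p))
  fls <- siteFluxes(censorToDetection(scaled))
  expect_equal(fls@ratio, fl@ratio, tolerance = 1e-9)
  expect_equal(fls@JNO3In, k * fl@JNO3In, tolerance = 1e-9)
})

test_that("ratio summary reproduces the textbook t-interval", {
  rs <- ratioSummary(c(a = 0.1, b = 0.2, c = 0.3, d = 0.4, e = 0.5))
  expect_equal(rs@mean, 0.3)
  oracle <- stats::t.test(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(rs@ci95Halfwidth,
               unname(diff(oracle$conf.int)) / 2, tolerance = 1e-12)

  # zero variance -> zero halfwidth; mean bounded by the ratios
  expect_equal(ratioSummary(rep(0.4, 4))@ci95Halfwidth, 0)
  for (seed in 1:10) {
    x <- withr::with_seed(seed, stats::runif(8))
    rs2 <- ratioSummary(x)
    expect_gte(rs2@mean, min(x))
    expect_lte(rs2@mean, max(x))
  }

  # n = 1: mean defined, CI undefined
  one <- ratioSummary(c(s = 0.3))
  expect_equal(one@mean, 0.3)
  expect_true(is.na(one@ci95Halfwidth))
  expect_error(ratioSummary(numeric()), "no flux results")

  # outlier flagging at the configured threshold
  rs3 <- ratioSummary(c(a = 0.2, b = 1.3), outlierThreshold = 1)
  expect_equal(rs3@outlierSites, "b")
})
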