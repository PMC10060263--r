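test_that("depletion depth interpolates the detection-limit crossing", {
  p <- censorToDetection(makeProfile(c(0, 100, 200),
                                     nitrate = c(20, 10, 0)))
  zd <- findDepletionDepth(p, "nitrate")
  # crossing of C = 0.1 on the segment (100, 10) -> (200, 0)
  expect_equal(as.numeric(zd), 100 + (10 - 0.1) / 10 * 100)
  expect_equal(attr(zd, "firstCensored"), 200)
  expect_equal(as.numeric(findDepletionDepth(p, "nitrate",
                                             interpolate = FALSE)), 200)

  # never depleted -> NA
  p2 <- censorToDetection(makeProfile(c(0, 50), oxygen = c(15, 5)))
  expect_true(is.na(findDepletionDepth(p2, "oxygen")))

  expect_error(findDepletionDepth(p, "oxygen"), "absent")
})

test_that("oxic zone spans surface to oxygen depletion with degenerate cases", {
  p <- censorToDetection(makeProfile(c(0, 10, 23),
                                     oxygen = c(15, 5, 0)))
  oz <- findOxicZone(p)
  expect_equal(oz[1], 0)
  expect_gt(oz[2], 10)
  expect_lte(oz[2], 23)

  # oxygen never depleted -> extends to core bottom
  p2 <- censorToDetection(makeProfile(c(0, 50, 100),
                                      oxygen = c(200, 150, 100)))
  expect_equal(findOxicZone(p2), c(0, 100))

  # all censored -> empty interval at the top
  p3 <- censorToDetection(makeProfile(c(5, 50), oxygen = c(0, 0)))
  expect_equal(findOxicZone(p3), c(5, 5))
})

test_that("nitrite interval applies the more-than-two-detects coherence rule", {
  # exactly 2 consecutive detects -> not coherent
  p2 <- censorToDetection(makeProfile(seq(0, 40, 10),
    nitrite = c(0, 0.5, 0.6, 0, 0)))
  iv2 <- findNitriteInterval(p2)
  expect_false(iv2$coherent)
  expect_equal(iv2$interval, c(10, 20))

  # 3 consecutive detects -> coherent
  p3 <- censorToDetection(makeProfile(seq(0, 40, 10),
    nitrite = c(0, 0.5, 0.6, 0.5, 0)))
  iv3 <- findNitriteInterval(p3)
  expect_true(iv3$coherent)
  expect_equal(iv3$interval, c(10, 30))
  expect_equal(iv3$maximum, c(20, 0.6))

  # longest run wins; equal maxima tie to the shallowest depth
  p4 <- censorToDetection(makeProfile(seq(0, 70, 10),
    nitrite = c(0.5, 0.5, 0, 0.7, 0.7, 0.7, 0.2, 0)))
  iv4 <- findNitriteInterval(p4)
  expect_equal(iv4$interval, c(30, 60))
  expect_equal(iv4$maximum, c(30, 0.7))

  # nowhere detected
  p5 <- censorToDetection(makeProfile(c(0, 10), nitrite = c(0, 0)))
  expect_false(findNitriteInterval(p5)$coherent)
  expect_true(all(is.na(findNitriteInterval(p5)$interval)))
})

test_that("NATZ distinguishes separated and overlapping topologies", {
  # nitrate depleted ~130, ammonium appearing ~213 -> separated gap
  p <- censorToDetection(makeProfile(c(0, 60, 120, 130, 213, 240),
    nitrate = c(20, 10, 1, 0, 0, 0),
    ammonium = c(0, 0, 0, 0, 3, 8)))
  natz <- findNATZ(p)
  expect_equal(natz$relation, "separated")
  expect_lt(natz$interval[1], 130)
  expect_gt(natz$interval[2], 130)

  # ammonium appears above the nitrate depletion -> overlap
  p2 <- censorToDetection(makeProfile(c(0, 60, 120, 190, 240),
    nitrate = c(20, 10, 5, 0, 0),
    ammonium = c(0, 0, 2, 6, 9)))
  natz2 <- findNATZ(p2)
  expect_equal(natz2$relation, "overlap")
  expect_lt(natz2$interval[1], 120)
  expect_lt(natz2$interval[2], 190)

  # ammonium never detected -> undefined with reason
  p3 <- censorToDetection(makeProfile(c(0, 100, 200),
    nitrate = c(20, 5, 0), ammonium = c(0, 0, 0)))
  natz3 <- findNATZ(p3)
  expect_equal(natz3$relation, "undefined")
  expect_match(natz3$reason, "ammonium")
})

test_that("zonation recovers prescribed boundaries within one grid step", {
  h <- 2
  out <- generateProfile(presetScenario("GS14-like", spacing = h))
  zones <- deriveZones(out$profile)
  tr <- out$truth

  o2cross <- truthCrossing(tr, "oxygen", 2, 1, 100)
  expect_lt(abs(zones@oxicZone[2] - o2cross), h)

  no3cross <- truthCrossing(tr, "nitrate", 0.1, 100, 133)
  expect_lt(abs(zones@nitrateDepletionDepth - no3cross), h)

  no2top <- truthCrossing(tr, "nitrite", 0.1, 1, 106)
  no2bot <- truthCrossing(tr, "nitrite", 0.1, 106, 239)
  expect_lt(abs(zones@nitriteInterval[1] - no2top), h)
  expect_lt(abs(zones@nitriteInterval[2] - no2bot), h)

  # nitrite maximum inside the prescribed production zone (90-120 cm)
  expect_gte(zones@nitriteMaximum[1], 90)
  expect_lte(zones@nitriteMaximum[1], 120)
})

test_that("consumption zones match prescribed sink boundaries on a forward model", {
  sc <- nitriteThreeZoneScenario(spacing = 2)
  out <- generateProfile(sc)
  iv <- findNitriteInterval(out$profile)
  expect_true(iv$coherent)
  cz <- classifyConsumptionZones(out$profile, iv)
  expect_false(any(cz$fallback))
  # prescribed sinks are [40, 90] and [120, 190]
  expect_lte(abs(cz$upper[1] - 40), 2)
  expect_lte(abs(cz$upper[2] - 90), 2)
  expect_lte(abs(cz$lower[1] - 120), 2)
  expect_lte(abs(cz$lower[2] - 190), 2)
  # upper strictly above the maximum, lower strictly below
  expect_lt(cz$upper[2], iv$maximum[1])
  expect_gt(cz$lower[1], iv$maximum[1])
})

test_that("a strictly linear nitrite limb yields no consumption on that limb", {
  # piecewise-linear bump: zero curvature on both limbs away from the kink
  z <- seq(0, 100, by = 5)
  bump <- pmax(0, 3 - abs(z - 50) / 10)
  p <- censorToDetection(makeProfile(z, nitrite = bump))
  iv <- findNitriteInterval(p)
  cz <- classifyConsumptionZones(p, iv)
  # only the kink at the maximum carries curvature; both limbs fall back
  expect_true(all(cz$fallback))
})

test_that("zonation is invariant under uniform concentration rescaling", {
  out <- generateProfile(presetScenario("GS14-like", noiseSd = 0.15,
                                        seed = 11))
  raw <- out$profile
  for (k in c(0.1, 10)) {
    scaled <- depthProfile(depths(raw), concentrations(raw) * k,
                           censored = isCensored(raw),
                           porosity = porosity(raw),
                           solutes = lapply(raw@solutes, function(s) {
                             s@detectionLimit <- s@detectionLimit * k
                             s
                           }),
                           site = siteInfo(raw))
    z1 <- deriveZones(censorToDetection(raw))
    z2 <- deriveZones(censorToDetection(scaled))
    expect_equal(z2@oxicZone, z1@oxicZone)
    expect_equal(z2@nitrateDepletionDepth, z1@nitrateDepletionDepth)
    expect_equal(z2@nitriteInterval, z1@nitriteInterval)
    expect_equal(z2@nitriteMaximum[1], z1@nitriteMaximum[1])
    expect_equal(z2@natz, z1@natz)
    expect_equal(z2@upperConsumptionZone, z1@upperConsumptionZone)
    expect_equal(z2@lowerConsumptionZone, z1@lowerConsumptionZone)
  }
})

test_that("zone interval export flattens defined zones only", {
  out <- generateProfile(presetScenario("GS14-like"))
  zones <- deriveZones(out$profile)
  tab <- zonesToIntervals(zones)
  expect_true(all(c("oxic", "nitrite_interval", "natz_separated",
                    "upper_consumption", "lower_consumption") %in%
                  tab$zone_label))
  expect_true(all(tab$start_cm <= tab$end_cm))
})
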