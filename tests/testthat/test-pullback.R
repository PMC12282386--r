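# Per-vessel physiological indices: resampling, monotone projection,
# drops, disease length, PPGi, local gradients and threshold flags.

test_that("resampleCurve interpolates onto a uniform 0.35-mm grid", {
  crv <- resampleCurve(c(0, 10), c(1.0, 0.8))
  expect_length(positions(crv), 29L)
  expect_equal(gridSpacing(crv), 0.35)
  expect_equal(mufrValues(crv)[positions(crv) == 5.25], 0.895)

  # constant two-point curve at exactly one spacing
  crv2 <- resampleCurve(c(0, 0.35), c(1.0, 1.0))
  expect_equal(mufrValues(crv2), c(1.0, 1.0))

  # a grid already uniform at the spacing is reproduced exactly
  crv3 <- resampleCurve(c(0, 0.35, 0.70), c(1.0, 0.9, 0.95))
  expect_equal(mufrValues(crv3), c(1.0, 0.9, 0.95))
  expect_equal(positions(crv3), c(0, 0.35, 0.70))

  # endpoints preserved when the length is a spacing multiple
  crv4 <- resampleCurve(c(0, 3, 7), c(1.0, 0.9, 0.8))
  expect_equal(mufrValues(crv4)[c(1, length(positions(crv4)))], c(1.0, 0.8))

  expect_error(resampleCurve(0, 1), "at least 2")
  expect_error(resampleCurve(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(resampleCurve(c(5, 1), c(1, 1)), "strictly increasing")
})

test_that("monotonize is the least-squares non-increasing projection", {
  expect_equal(mufrValues(monotonize(makeCurve(c(1.0, 0.9, 0.8)))),
               c(1.0, 0.9, 0.8))
  expect_equal(mufrValues(monotonize(makeCurve(c(1.0, 0.8, 0.9)))),
               c(1.0, 0.85, 0.85))
  expect_equal(mufrValues(monotonize(makeCurve(c(0.7, 0.7, 0.7)))),
               c(0.7, 0.7, 0.7))

  set.seed(11)
  for (rep in 1:20) {
    y <- pmin(pmax(1 - cumsum(runif(50, -0.02, 0.04)), 0), 1)
    crv <- makeCurve(y)
    m <- monotonize(crv)
    ym <- mufrValues(m)
    expect_true(all(diff(ym) <= 1e-12))
    # idempotent
    expect_equal(mufrValues(monotonize(m)), ym)
    # optimal among random feasible (non-increasing) candidates
    for (k in 1:10) {
      cand <- cummin(ym + rnorm(50, 0, 0.01))
      expect_gte(sum((cand - y)^2) + 1e-12, sum((ym - y)^2))
    }
  }
})

test_that("deltaMufrVessel is the endpoint drop on the monotonized trace", {
  expect_equal(deltaMufrVessel(makeCurve(c(1.0, 0.7, 0.3))), 0.7)
  expect_equal(deltaMufrVessel(makeCurve(c(1, 1, 1))), 0)
  expect_equal(deltaMufrVessel(makeCurve(c(1.0, 0.8, 0.9))), 0.15)
})

test_that("maxDrop20mm agrees with the independent sliding-window oracle", {
  # flat
  expect_equal(maxDrop20mm(makeCurve(rep(1, 100))), 0)
  # linear decline: 57 grid steps of 0.35 mm inside the 20-mm window
  lin <- linearCurve()
  expect_equal(maxDrop20mm(lin), 57 * 0.35 * 0.00375)
  expect_lt(abs(maxDrop20mm(lin) - 0.075), 1e-3)
  # a 0.30 step inside a 7-mm segment is fully captured
  st <- stepCurve()
  expect_equal(maxDrop20mm(st), 0.30)
  # whole-vessel drop when shorter than the window
  short <- makeCurve(seq(1, 0.8, length.out = 30))  # ~10 mm
  expect_equal(maxDrop20mm(short), 0.2)

  set.seed(7)
  for (rep in 1:50) {
    crv <- randomMonotoneCurve()
    expect_equal(maxDrop20mm(crv),
                 bruteMaxDrop(positions(crv), mufrValues(crv)),
                 tolerance = 1e-12)
  }
})

test_that("functionalDiseaseLength totals the segments above the gradient floor", {
  expect_equal(functionalDiseaseLength(makeCurve(rep(1, 100))), 0)
  lin <- linearCurve()  # 0.00375/mm everywhere, above the 0.001 floor
  expect_equal(functionalDiseaseLength(lin), totalLength(lin))
  st <- stepCurve()     # disease confined to the 7-mm ramp
  expect_lte(abs(functionalDiseaseLength(st) - 7), 0.35 + 1e-9)
})

test_that("computePpgi assembles the index from its two terms", {
  st <- stepCurve()
  pc <- computePpgi(st)
  expect_equal(pc@maxPpg20mm, 0.30)
  expect_equal(pc@deltaMufrVessel, 0.30)
  expect_equal(pc@diseaseLengthMm, 7)
  expect_equal(ppgiValue(pc), (1 + (1 - 7 / totalLength(st))) / 2)
  expect_lt(abs(ppgiValue(pc) - 0.956), 0.005)

  lin <- linearCurve()
  expect_equal(ppgiValue(computePpgi(lin)), 0.125)  # (0.25 + 0)/2

  expect_error(computePpgi(makeCurve(rep(1, 50))), "undefined")
})

test_that("PPGi lies in [0,1] on monotone curves and the formula invariant holds", {
  set.seed(21)
  for (rep in 1:100) {
    crv <- randomMonotoneCurve()
    if (deltaMufrVessel(crv) <= 0) next
    pc <- computePpgi(crv)
    expect_gte(ppgiValue(pc), 0)
    expect_lte(ppgiValue(pc), 1)
    expect_lte(pc@maxPpg20mm, pc@deltaMufrVessel + 1e-12)
    expect_equal(ppgiValue(pc),
                 (pc@maxPpg20mm / pc@deltaMufrVessel +
                  (1 - pc@diseaseLengthMm / pc@totalLengthMm)) / 2)
  }
})

test_that("PPGi is invariant to grid refinement on smooth curves", {
  for (w in c(10, 25, 50)) {
    s1 <- seq(0, 80.5, by = 0.35)
    s2 <- seq(0, 80.5, by = 0.175)
    f <- function(s) 1 - 0.3 * plogis((s - 40) / (w / (2 * log(19))))
    p1 <- ppgiValue(computePpgi(PullbackCurve(s1, f(s1))))
    p2 <- ppgiValue(computePpgi(PullbackCurve(s2, f(s2))))
    expect_lt(abs(p1 - p2), 0.01)
  }
})

test_that("concentrating a fixed drop into a shorter segment raises PPGi", {
  widths <- seq(5, 40, by = 5)
  ppgis <- vapply(widths, function(w) {
    ppgiValue(computePpgi(stepCurve(drop = 0.3, from = 40 - w / 2,
                                    to = 40 + w / 2, lengthMm = 79.8)))
  }, numeric(1))
  expect_true(all(diff(ppgis) < 0))
})

test_that("maxLocalGradient recovers slopes through smoothing", {
  expect_equal(maxLocalGradient(makeCurve(rep(1, 100))), 0)
  expect_lt(abs(maxLocalGradient(linearCurve()) - 0.00375), 1e-6)
  g <- maxLocalGradient(stepCurve())  # 0.30 over 7 mm
  expect_lt(abs(g - 0.30 / 7), 0.003)
  expect_true(hasMajorGradient(g))
})

test_that("threshold comparisons honour the printed boundary inclusivity", {
  expect_true(hasMajorGradient(0.025))
  expect_false(hasMajorGradient(0.0249))
  expect_true(hasMajorGradient(0.043))

  expect_equal(classifyByPpgiCutoff(0.78), "focal")
  expect_equal(classifyByPpgiCutoff(0.779), "diffuse")
  expect_equal(classifyByPpgiCutoff(0.956), "focal")

  rec <- function(d) {
    n <- 60
    v <- seq(1, d, length.out = n)
    VesselRecord("v", "p", makeCurve(v), referenceDiameter = 3.5)
  }
  expect_true(vesselFlags(rec(0.80))$significant)
  expect_false(vesselFlags(rec(0.81))$significant)
  expect_true(vesselFlags(rec(0.96))$noFunctionalDisease)
  f <- vesselFlags(rec(0.90))
  expect_false(f$significant)
  expect_false(f$noFunctionalDisease)
})

test_that("PullbackCurve and VesselRecord validity catch malformed input", {
  expect_error(PullbackCurve(c(0, 0.35, 0.5), c(1, 1, 1)), "uniformly spaced")
  expect_error(PullbackCurve(c(0, 0.35), c(1, 1), mld = c(2, -1)), "> 0")
  crv <- makeCurve(c(1, 0.9, 0.8))
  expect_error(new("VesselRecord", vesselId = "v", patientId = "p",
                   curve = crv, distalMufr = 0.5, referenceDiameter = 3,
                   label = character()), "distalMufr")
  expect_error(VesselRecord("v", "p", crv, 3.5, label = "weird"), "label")
  expect_silent(validObject(VesselRecord("v", "p", crv, 3.5, label = "focal")))
})
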