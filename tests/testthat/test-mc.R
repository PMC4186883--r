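test_that("isotensional energy: zero potential, work term, periodicity", {
  m0 <- zeroPotential(deds())
  expect_equal(totalEnergy(m0, c(10, 220, 300), force = 0), 0)
  # with a flat potential, energies differ only by -F * dR * 0.06022
  c1 <- c(60, 90, 60); c2 <- c(180, 180, 180)
  r1 <- atomDistance(buildCartesian(m0, c1), 1, 6)
  r2 <- atomDistance(buildCartesian(m0, c2), 1, 6)
  dE <- totalEnergy(m0, c2, 100) - totalEnergy(m0, c1, 100)
  expect_equal(dE, -100 * (r2 - r1) * 0.06022, tolerance = 1e-10)
  # the unit factor itself: 100 pN over 2 A is -12.044 kJ/mol
  expect_equal(-100 * 2 * 0.06022, -12.044)
  m <- deds()
  expect_equal(totalEnergy(m, c(60, 90, 300), 500),
               totalEnergy(m, c(60 + 360, 90, 300 - 360), 500),
               tolerance = 1e-9)
})

test_that("flat-energy sampling gives uniform dihedral marginals", {
  m0 <- zeroPotential(deds())
  ens <- metropolisSample(m0, force = 0, nSteps = 5.2e5, nBurnin = 2e4,
                          thinning = 50L, seed = 5)
  d <- ensembleSamples(ens)
  expect_gte(nrow(d), 9000)
  for (j in 1:3) {
    ks <- suppressWarnings(stats::ks.test(d[[j]], "punif", 0, 360))
    expect_gt(ks$p.value, 0.01)
  }
  expect_gt(ens@acceptRate, 0.99)  # flat energy: every proposal accepted
})

test_that("sampler matches the quadrature oracle within 3 SE", {
  m <- deds()
  for (f in c(0, 300)) {
    # 144 points/axis: the 130/230 band edges fall on bin boundaries, so
    # the oracle's state probabilities carry no discretization bias
    q <- quadratureReference(m, f, gridPoints = 144)
    ens <- metropolisSample(m, f, nSteps = 5e5, seed = 17 + f)
    se_R <- ssbridge:::.batchSE(ens@R)
    expect_lt(abs(mean(ens@R) - q$mean_R), 3 * se_R)
    d <- ens@dihedrals
    cc <- as.numeric(isClosed(d[, "chi1"]) & isClosed(d[, "chi2"]))
    expect_lt(abs(mean(cc) - q$p_joint["closed/closed"]),
              3 * max(ssbridge:::.batchSE(cc), 1e-4))
  }
  expect_error(quadratureReference(builtinModel("cystine"), 0), "3 dihedrals")
})

test_that("quadrature converges with grid refinement and obeys limits", {
  m <- deds()
  q1 <- quadratureReference(m, 500, gridPoints = 90)
  q2 <- quadratureReference(m, 500, gridPoints = 180)
  expect_lt(abs(q1$mean_R - q2$mean_R), 1e-3)
  # flat potential, zero force: closed/closed occupies (100/360)^2 of the torus
  q0 <- quadratureReference(zeroPotential(m), 0, gridPoints = 72)
  expect_equal(unname(q0$p_joint["closed/closed"]), (100 / 360)^2,
               tolerance = 1e-6)
  # huge force concentrates at maximal extension
  qF <- quadratureReference(zeroPotential(m), 5e4, gridPoints = 90)
  rmax <- atomDistance(buildCartesian(m, c(180, 180, 180)), 1, 6)
  expect_lt(rmax - qF$mean_R, 0.05)
})

test_that("closed/closed dominates DEDS at 300 pN and sampling is seed-deterministic", {
  m <- deds()
  ens <- metropolisSample(m, 300, nSteps = 3e5, seed = 7)
  d <- ens@dihedrals
  cc <- mean(isClosed(d[, "chi1"]) & isClosed(d[, "chi2"]))
  oc <- mean(xor(isClosed(d[, "chi1"]), isClosed(d[, "chi2"])))
  expect_gt(cc, 0.5)
  expect_gt(cc, oc)
  ens2 <- metropolisSample(m, 300, nSteps = 3e5, seed = 7)
  expect_identical(ens@dihedrals, ens2@dihedrals)
  ens3 <- metropolisSample(m, 300, nSteps = 3e5, seed = 8)
  expect_false(identical(ens@dihedrals, ens3@dihedrals))
})

test_that("DEDS landscape is chi1/chi2 transposition-symmetric", {
  m <- deds()
  for (f in c(0, 300)) {
    ens <- metropolisSample(m, f, nSteps = 6e5, seed = 23 + f)
    ls2 <- histogram2d(ens, nBins = 12)  # coarse bins: small per-bin MC error
    P <- landscapeP(ls2)
    n <- sum(ls2@counts)
    # per-bin binomial 3 SD bound on |P - t(P)|
    tol <- 3 * sqrt(2 * pmax(P, 1 / n) / n)
    expect_true(all(abs(P - t(P)) <= tol + 5 / n))
  }
})

test_that("builtin models have the declared structure and size ordering", {
  m1 <- deds(); m2 <- builtinModel("cystine"); m3 <- builtinModel("polypeptide-path")
  expect_equal(nrow(modelTorsions(m1)), 3)
  expect_identical(m1@pullPair, m1@calphaPair)
  expect_false(identical(m2@pullPair, m2@calphaPair))
  expect_equal(nrow(modelTorsions(m2)), 5)
  expect_equal(nrow(modelTorsions(m3)), 9)
  expect_error(builtinModel("nonesuch"))
  # chain-length ordering of the unstretched mean extension
  r <- vapply(list(m1, m2, m3), function(m)
    mean(metropolisSample(m, 0, nSteps = 1.5e5, seed = 31)@R), numeric(1))
  expect_true(r[3] > r[2] && r[2] > r[1])
})

test_that("model config reader reproduces a builtin topology", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("model deds-copy",
               "C1 C - - - - - -",
               "C2 C 1 - - 1.53 - -",
               "S3 S 2 1 - 1.82 114.7 -",
               "S4 S 3 2 1 2.05 103.7 CCSS:chi1",
               "C5 C 4 3 2 1.82 103.7 CSSC:chi3",
               "C6 C 5 4 3 1.53 114.7 CCSS:chi2",
               "pull 1 6", "calpha 1 6"), cfg)
  m <- readModelConfig(cfg)
  ref <- deds()
  conf <- c(72, 255, 140)
  expect_equal(buildCartesian(m, conf), buildCartesian(ref, conf),
               ignore_attr = TRUE)
  expect_equal(totalEnergy(m, conf, 250), totalEnergy(ref, conf, 250))
  expect_error(readModelConfig(tempfile()), "not found")
})
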