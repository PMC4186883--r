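test_that("periodic 2D histogram bins correctly and normalises", {
  mkEns <- function(chi1, chi2) {
    n <- length(chi1)
    new("ForceClampEnsemble", model = "toy", force = 0, temperature = 300,
        dihedrals = cbind(chi1 = chi1, chi2 = chi2),
        R = rep(1, n), dCalpha = rep(1, n), energy = rep(0, n),
        seed = 1L, nSteps = n, nBurnin = 0, thinning = 1L, acceptRate = 1)
  }
  ens <- mkEns(rep(180, 50), rep(180, 50))
  ls2 <- histogram2d(ens, nBins = 36)
  expect_equal(max(landscapeP(ls2)), 1)
  expect_equal(sum(landscapeP(ls2)), 1)
  expect_equal(sum(ls2@counts), 50)
  # 0 and 360 land in the same (first) bin
  ens2 <- mkEns(c(0, 360), c(0, 360))
  ls3 <- histogram2d(ens2, nBins = 36)
  expect_equal(ls3@counts[1, 1], 2)
  expect_error(histogram2d(ens, nBins = 4), "at least 8")
})

test_that("uniform draws give multinomially flat bins", {
  set.seed(202)
  n <- 2e5; nb <- 36
  ens <- new("ForceClampEnsemble", model = "unif", force = 0,
             temperature = 300,
             dihedrals = cbind(chi1 = runif(n, 0, 360),
                               chi2 = runif(n, 0, 360)),
             R = rep(1, n), dCalpha = rep(1, n), energy = rep(0, n),
             seed = 1L, nSteps = n, nBurnin = 0, thinning = 1L,
             acceptRate = 1)
  P <- landscapeP(histogram2d(ens, nBins = nb))
  p0 <- 1 / nb^2
  sd0 <- sqrt(p0 * (1 - p0) / n)
  expect_lt(max(abs(P - p0)), 5 * sd0)
})

test_that("Boltzmann inversion and its inverse are exact companions", {
  # uniform probability: flat zero free energy
  P <- matrix(1 / 16, 4, 4)
  inv <- boltzmannInvert(P, 300)
  expect_true(all(inv$fes == 0))
  # two-state: Delta F = kB T ln 4 at 300 K
  inv2 <- boltzmannInvert(c(0.8, 0.2), 300)
  expect_equal(diff(inv2$fes), 0.0083145 * 300 * log(4), tolerance = 1e-12)
  expect_equal(0.0083145 * 300 * log(4), 3.458, tolerance = 1e-3)
  # round trip identity on random positive P
  set.seed(9)
  P3 <- matrix(rexp(64), 8, 8); P3 <- P3 / sum(P3)
  back <- fesToP(boltzmannInvert(P3, 250)$fes, 250)
  expect_equal(back, P3, tolerance = 1e-10)
  # unsampled bins flagged, restored as zeros, never infinite
  P4 <- c(0.5, 0.5, 0)
  inv4 <- boltzmannInvert(P4, 300)
  expect_true(is.na(inv4$fes[3]) && inv4$unsampled[3])
  expect_true(all(is.finite(inv4$fes[1:2])))
  expect_equal(fesToP(inv4$fes, 300), P4)
  expect_error(boltzmannInvert(c(0, 0)), "all-zero")
})

test_that("open fraction: degenerate and uniform ensembles", {
  mk <- function(chi1, chi2) {
    n <- length(chi1)
    new("ForceClampEnsemble", model = "toy", force = 0, temperature = 300,
        dihedrals = cbind(chi1 = chi1, chi2 = chi2), R = rep(1, n),
        dCalpha = rep(1, n), energy = rep(0, n), seed = 1L, nSteps = n,
        nBurnin = 0, thinning = 1L, acceptRate = 1)
  }
  expect_equal(openFraction(mk(rep(180, 40), rep(180, 40)))$fraction, 0)
  expect_equal(openFraction(mk(rep(60, 40), rep(300, 40)))$fraction, 1)
  set.seed(77)
  u <- mk(runif(4e4, 0, 360), runif(4e4, 0, 360))
  of <- openFraction(u)
  expect_lt(abs(of$fraction - (1 - (100 / 360)^2)), 3 * max(of$se, 2e-3))
})

test_that("force scans are monotone within noise and reproducible", {
  sc <- forceScan(deds(), c(0, 100, 300, 1000), nSteps = 2e5, seed = 3)
  tb <- scanTable(sc)
  # open character decays, R grows, each within 3 combined SE per step
  for (i in seq_len(nrow(tb) - 1)) {
    expect_lt(tb$open_fraction[i + 1] - tb$open_fraction[i],
              3 * sqrt(tb$open_se[i]^2 + tb$open_se[i + 1]^2))
    expect_gt(tb$mean_R[i + 1] - tb$mean_R[i],
              -3 * sqrt(tb$R_se[i]^2 + tb$R_se[i + 1]^2))
  }
  # at 1000 pN the closed/closed state holds > 90% of the mass
  expect_gt(tb$closed_closed[tb$force == 1000], 0.9)
  # at zero force open states dominate
  expect_gt(tb$open_fraction[tb$force == 0], 0.5)
  # chi3 is pulled away from its +/-90 minima towards 180 under load
  expect_gt(tb$chi3_dev[tb$force == 1000], tb$chi3_dev[tb$force == 0])
  sc2 <- forceScan(deds(), c(0, 100, 300, 1000), nSteps = 2e5, seed = 3)
  expect_identical(scanTable(sc), scanTable(sc2))
})
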