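test_that("angle wrapping maps onto [0, 360) and rejects non-finite input", {
  expect_equal(wrapAngle(0), 0)
  expect_equal(wrapAngle(-170), 190)
  expect_equal(wrapAngle(540), 180)
  expect_equal(wrapAngle(360), 0)
  expect_error(wrapAngle(NaN), "finite")
  expect_equal(wrapTo180(c(190, 180, 350)), c(-170, 180, -10))
})

test_that("dihedral follows the IUPAC sign convention", {
  expect_equal(dihedralAngle(c(0,1,0), c(0,0,0), c(1,0,0), c(1,1,0)), 0)
  expect_equal(dihedralAngle(c(0,1,0), c(0,0,0), c(1,0,0), c(1,-1,0)), 180)
  expect_equal(dihedralAngle(c(0,1,0), c(0,0,0), c(1,0,0), c(1,0,1)), 90)
  expect_error(dihedralAngle(c(0,0,0), c(1,0,0), c(2,0,0), c(3,1,0)),
               "collinear")
})

test_that("dihedral is invariant under rigid motion and atom-order reversal", {
  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    d <- try(dihedralAngle(pts[1,], pts[2,], pts[3,], pts[4,]), silent = TRUE)
    if (inherits(d, "try-error")) next
    pts2 <- rigidTransform(pts, seed = i)
    d2 <- dihedralAngle(pts2[1,], pts2[2,], pts2[3,], pts2[4,])
    expect_equal(d2, d, tolerance = 1e-8)
    # reversing the atom order leaves a torsion unchanged; only mirror
    # reflection flips its sign
    dr <- dihedralAngle(pts[4,], pts[3,], pts[2,], pts[1,])
    expect_equal(dr, d, tolerance = 1e-8)
    dm <- dihedralAngle(pts[1,] * c(1, 1, -1), pts[2,] * c(1, 1, -1),
                        pts[3,] * c(1, 1, -1), pts[4,] * c(1, 1, -1))
    expect_lt(min(abs(wrapAngle(d + dm) - c(0, 360))), 1e-8)
  }
})

test_that("internal-to-Cartesian round trip recovers every rotatable dihedral", {
  for (name in c("DEDS", "cystine", "polypeptide-path")) {
    m <- builtinModel(name)
    k <- nrow(modelTorsions(m))
    confs <- randomConfs(if (name == "DEDS") 60 else 20, k, seed = nchar(name))
    a <- modelAtoms(m)
    for (r in seq_len(nrow(confs))) {
      xyz <- buildCartesian(m, confs[r, ])
      for (i in which(!is.na(a$dih_ref))) {
        got <- dihedralAngle(xyz[a$ref3[i], ], xyz[a$ref2[i], ],
                             xyz[a$ref1[i], ], xyz[i, ])
        want <- wrapAngle(confs[r, a$dih_ref[i]])
        expect_lt(min(abs(got - want), abs(got - want + 360),
                      abs(got - want - 360)), 1e-6)
      }
    }
  }
})

test_that("package dihedral agrees with the bio3d torsion routine", {
  m <- builtinModel("DEDS")
  confs <- randomConfs(25, 3, seed = 99)
  a <- modelAtoms(m)
  for (r in seq_len(nrow(confs))) {
    xyz <- buildCartesian(m, confs[r, ])
    for (i in which(!is.na(a$dih_ref))) {
      quad <- rbind(xyz[a$ref3[i], ], xyz[a$ref2[i], ],
                    xyz[a$ref1[i], ], xyz[i, ])
      ref <- wrapAngle(bio3d::torsion.xyz(as.numeric(t(quad)), atm.inc = 4))
      mine <- dihedralAngle(quad[1, ], quad[2, ], quad[3, ], quad[4, ])
      expect_lt(min(abs(mine - ref), 360 - abs(mine - ref)), 1e-4)
    }
  }
})

test_that("an anti chain is planar and extended beats gauche for DEDS", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("model chain4",
               "C1 C - - - - - -",
               "C2 C 1 - - 1.5 - -",
               "C3 C 2 1 - 1.5 109.47 -",
               "C4 C 3 2 1 1.5 109.47 SP3:d1",
               "pull 1 4", "calpha 1 4"), cfg)
  m4 <- readModelConfig(cfg)
  xyz <- buildCartesian(m4, 180)
  expect_equal(max(abs(xyz[, "z"])), 0, tolerance = 1e-10)
  m <- deds()
  ext <- atomDistance(buildCartesian(m, c(180, 180, 180)), 1, 6)
  gau <- atomDistance(buildCartesian(m, c(60, 90, 60)), 1, 6)
  expect_gt(ext, gau)
})

test_that("atom distances are Euclidean, symmetric, index-checked", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(atomDistance(xyz, 1, 2), 5)
  expect_equal(atomDistance(xyz, 2, 1), 5)
  expect_equal(atomDistance(xyz, 1, 1), 0)
  expect_error(atomDistance(xyz, 1, 3), "out of range")
  # for DEDS the pulled terminal carbons are also the alpha-carbon pair
  m <- deds()
  expect_identical(m@pullPair, m@calphaPair)
})
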