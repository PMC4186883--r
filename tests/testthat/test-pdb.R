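test_that("open/closed classification implements the 180 +/- 50 band", {
  expect_equal(classifyChi(180), "closed")
  expect_equal(classifyChi(60), "open")
  expect_equal(classifyChi(130), "closed")   # inclusive boundary
  expect_equal(classifyChi(230), "closed")
  expect_equal(classifyChi(129.99), "open")
  expect_equal(classifyChi(231), "open")
  a <- runif(50, -720, 720)
  expect_identical(classifyChi(a), classifyChi(a + 360))
})

test_that("writer -> parser -> measure recovers prescribed dihedrals", {
  td <- withr::local_tempdir()
  cases <- rbind(c(180, 180, 90), c(60, 300, 90), c(165, 178, 90),
                 c(131, 229, 270), c(300, 60, 255))
  states <- c("closed/closed", "open/open", "closed/closed",
              "closed/closed", "open/open")
  # PDB coordinates print at 1e-3 A, which quantizes dihedrals to ~0.03 deg
  # over these bond lengths; 0.05 deg is the format-limited bound
  for (i in seq_len(nrow(cases))) {
    p <- file.path(td, sprintf("c%d.pdb", i))
    writeDisulfidePdb(cases[i, 1], cases[i, 2], cases[i, 3], p)
    st <- parsePdb(p)
    expect_equal(nrow(st$ssbond), 1)
    g <- measureDisulfide(st, findDisulfides(st)[1, ])
    expect_lt(abs(g$chi1 - cases[i, 1]), 0.05)
    expect_lt(abs(g$chi2 - cases[i, 2]), 0.05)
    expect_lt(abs(g$chi3 - cases[i, 3]), 0.05)
    expect_equal(g$joint_state, states[i])
    expect_true(g$ss_length > 1.8 && g$ss_length < 2.5)
  }
})

test_that("geometric detection, deduplication and SSBOND union", {
  td <- withr::local_tempdir()
  p <- file.path(td, "geo.pdb")
  writeDisulfidePdb(180, 180, 90, p)
  # drop the SSBOND record: geometric SG-SG contact must still find the pair
  lines <- readLines(p)
  writeLines(lines[!startsWith(lines, "SSBOND")], p)
  st <- parsePdb(p)
  expect_equal(nrow(st$ssbond), 0)
  expect_equal(nrow(findDisulfides(st)), 1)
  # declared + geometric stays one deduplicated pair
  writeDisulfidePdb(180, 180, 90, p)
  expect_equal(nrow(findDisulfides(parsePdb(p))), 1)
  # a tight cutoff excludes the geometric pair
  st2 <- parsePdb(p)
  st2$ssbond <- st2$ssbond[0, ]
  expect_equal(nrow(findDisulfides(st2, sgCutoff = 1.0)), 0)
})

test_that("parser failure modes: truncation, empty, missing atoms", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "trunc.pdb")
  writeLines(c("ATOM      1  CA  CYS A   1      1.0"), bad)
  expect_error(parsePdb(bad), "line 1")
  none <- file.path(td, "noatoms.pdb")
  writeLines("HEADER    EMPTY", none)
  expect_error(parsePdb(none), "no ATOM")
  expect_error(parsePdb(file.path(td, "absent.pdb")), "cannot read")
  # declared pair whose CYS lacks SG: warned and excluded, not fatal
  p <- file.path(td, "missing.pdb")
  writeDisulfidePdb(180, 180, 90, p)
  lines <- readLines(p)
  keep <- !(grepl(" SG  CYS A   1 ", lines, fixed = TRUE) &
              startsWith(lines, "ATOM"))
  writeLines(lines[keep], p)
  st <- parsePdb(p)
  expect_warning(pairs <- findDisulfides(st), "missing atom")
  expect_equal(nrow(pairs), 0)
})

test_that("measurement is symmetric under pair order and rigid motion", {
  td <- withr::local_tempdir()
  p <- file.path(td, "sym.pdb")
  writeDisulfidePdb(165, 70, 95, p)
  st <- parsePdb(p)
  pair <- findDisulfides(st)[1, ]
  g1 <- measureDisulfide(st, pair)
  swapped <- data.frame(chain_a = pair$chain_b, res_a = pair$res_b,
                        chain_b = pair$chain_a, res_b = pair$res_a)
  g2 <- measureDisulfide(st, swapped)   # reordered internally: identical
  expect_equal(g1, g2)
  st3 <- st
  xyz <- rigidTransform(as.matrix(st$atoms[, c("x", "y", "z")]), seed = 5)
  st3$atoms[, c("x", "y", "z")] <- xyz
  g3 <- measureDisulfide(st3, pair)
  expect_equal(g3$chi1, g1$chi1, tolerance = 1e-6)
  expect_equal(g3$chi2, g1$chi2, tolerance = 1e-6)
  expect_equal(g3$chi3, g1$chi3, tolerance = 1e-6)
  expect_equal(g3$d_calpha, g1$d_calpha, tolerance = 1e-9)
})

test_that("interchain flag derives from differing chain identifiers", {
  td <- withr::local_tempdir()
  p <- file.path(td, "inter.pdb")
  writeDisulfidePdb(60, 60, 90, p, chainA = "A", chainB = "B", resA = 5, resB = 9)
  st <- parsePdb(p)
  g <- measureDisulfide(st, findDisulfides(st)[1, ])
  expect_true(g$interchain)
})

test_that("class summaries aggregate distance and closed/closed fraction", {
  rec <- data.frame(d_calpha = c(4, 6),
                    joint_state = c("closed/closed", "closed/closed"))
  s <- summarizeClass(rec, "toy")
  expect_equal(s$mean_d_calpha, 5)
  expect_equal(s$fraction_closed_closed, 1)
  expect_equal(s$n, 2)
  expect_error(summarizeClass(rec[0, ], "empty"), "empty")
  # synthetic populations: intrachain-Ig-like is closed/closed-rich and
  # longer than the TDi-like class
  specs <- defaultClassSpecs(4)
  ig <- summarizeClass(sampleClass(specs[["Ig-intrachain"]]), "Ig-intrachain")
  td <- summarizeClass(sampleClass(specs[["TDi"]]), "TDi")
  expect_gt(ig$fraction_closed_closed, 0.8)
  expect_lt(td$fraction_closed_closed, 0.05)
  expect_gt(ig$mean_d_calpha, td$mean_d_calpha)
})
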