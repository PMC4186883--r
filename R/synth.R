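# Synthetic inputs for the survey pipeline: PDB files of disulfide-bridged
# cystine fragments built at prescribed dihedrals, and per-class
# (chi1, chi2, d_calpha) scatter tables with the statistical structure of
# the published protein-class comparisons (closed/closed-centred for
# intrachain Ig; open-state-centred for TDi, DO and interchain Ig).

# Calpha-to-Calpha cystine fragment used to map drawn dihedrals to a
# Calpha-Calpha distance: CA-CB-S-S-CB-CA with rotatable chi1, chi3, chi2.
.fragmentModel <- function(params = torsionParams()) {
  atoms <- rbind(
    .atomRow("CA1", "C"),
    .atomRow("CB1", "C", ref1 = 1, bond_length = .BL["CC"]),
    .atomRow("SG1", "S", ref1 = 2, ref2 = 1, bond_length = .BL["CS"],
             bond_angle = .BA["CCS"]),
    .atomRow("SG2", "S", ref1 = 3, ref2 = 2, ref3 = 1, bond_length = .BL["SS"],
             bond_angle = .BA["CSS"], dih_ref = 1),
    .atomRow("CB2", "C", ref1 = 4, ref2 = 3, ref3 = 2, bond_length = .BL["CS"],
             bond_angle = .BA["CSS"], dih_ref = 2),
    .atomRow("CA2", "C", ref1 = 5, ref2 = 4, ref3 = 3, bond_length = .BL["CC"],
             bond_angle = .BA["CCS"], dih_ref = 3))
  torsions <- rbind(
    .torsionRow(params, "CCSS", "chi1"),
    .torsionRow(params, "CSSC", "chi3"),
    .torsionRow(params, "CCSS", "chi2"))
  new("TorsionalModel", name = "cystine-fragment", atoms = atoms,
      torsions = torsions, pullPair = c(1L, 6L), calphaPair = c(1L, 6L))
}

#' Write a synthetic cystine-fragment PDB at prescribed dihedrals
#'
#' Builds a disulfide-bridged two-cysteine fragment (standard bond lengths:
#' S-S 2.05, C-S 1.82, C-C 1.53 Angstrom) with the requested chi1, chi3,
#' chi2, writes valid ATOM records for both CYS residues plus an SSBOND
#' declaration. Re-parsing with \code{\link{parsePdb}} and
#' \code{\link{measureDisulfide}} recovers the angles.
#'
#' @param chi1,chi2,chi3 dihedrals in degrees
#' @param path output PDB path
#' @param chainA,chainB chain identifiers (differ for an interchain fixture)
#' @param resA,resB residue numbers
#' @return path, invisibly
#' @export
writeDisulfidePdb <- function(chi1, chi2, chi3, path,
                              chainA = "A", chainB = "A",
                              resA = 1L, resB = 2L) {
  if (!all(is.finite(c(chi1, chi2, chi3)))) stop("dihedrals must be finite")
  m <- .modelCystine(torsionParams())
  # conformation order: chiN, chi1, chi3, chi2, chiC
  xyz <- buildCartesian(m, c(300, chi1, chi3, chi2, 300))
  atoms <- data.frame(
    name = c("N", "CA", "CB", "SG", "SG", "CB", "CA", "C"),
    elem = c("N", "C", "C", "S", "S", "C", "C", "C"),
    chain = c(rep(chainA, 4), rep(chainB, 4)),
    resno = c(rep(resA, 4), rep(resB, 4)),
    stringsAsFactors = FALSE)
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(8), sprintf(" %-3s", atoms$name), "CYS", atoms$chain,
    atoms$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, atoms$elem)
  ss <- sprintf("SSBOND   1 CYS %1s %4d    CYS %1s %4d", chainA, resA,
                chainB, resB)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(ss, lines, "END"), con)
  invisible(path)
}

#' Specification of a synthetic protein-class population
#'
#' @param label class label
#' @param components data.frame with columns \code{c1}, \code{c2} (mixture
#'   centres for chi1/chi2, degrees), \code{spread} (wrapped-Gaussian SD,
#'   degrees), \code{weight} (sums to 1)
#' @param noiseSd Gaussian noise added to the geometric Calpha-Calpha
#'   distance, Angstrom
#' @param n number of disulfides to draw
#' @param seed RNG seed
#' @return a \code{ClassSpec} list
#' @export
classSpec <- function(label, components, noiseSd = 0.3, n = 100, seed = 1) {
  stopifnot(is.data.frame(components),
            all(c("c1", "c2", "spread", "weight") %in% names(components)))
  if (abs(sum(components$weight) - 1) > 1e-9)
    stop("mixture weights must sum to 1")
  if (any(components$spread <= 0)) stop("spreads must be positive")
  if (n < 1) stop("n must be at least 1")
  structure(list(label = label, components = components, noiseSd = noiseSd,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "ClassSpec")
}

#' Default synthetic class populations
#'
#' Four populations emulating the published survey classes: intrachain Ig
#' centred on the closed/closed basin (180/180), and TDi, DO and interchain
#' Ig spread over open-state centres (gauche C-C-S-S minima near +/-60 and
#' +/-85 degree regions). Sample sizes mirror the surveyed class sizes
#' (40, 27, 69, 927). Centres and spreads are emulation parameters of this
#' package, not measured values.
#'
#' @param seed master seed; per-class seeds are derived from it
#' @return named list of \code{ClassSpec}s
#' @export
defaultClassSpecs <- function(seed = 1) {
  comp <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(c1 = m[, 1], c2 = m[, 2], spread = m[, 3], weight = m[, 4])
  }
  s <- as.integer(seed)
  list(
    "TDi" = classSpec("TDi", comp(300, 300, 20, 0.5,
                                  60, 300, 20, 0.25,
                                  300, 60, 20, 0.25),
                      n = 40, seed = s + 101L),
    "DO" = classSpec("DO", comp(60, 60, 20, 0.5,
                                60, 300, 20, 0.5),
                     n = 27, seed = s + 202L),
    "Ig-interchain" = classSpec("Ig-interchain",
                                comp(300, 300, 20, 0.4,
                                     60, 60, 20, 0.3,
                                     85, 275, 20, 0.3),
                                n = 69, seed = s + 303L),
    "Ig-intrachain" = classSpec("Ig-intrachain",
                                comp(180, 180, 25, 1.0),
                                n = 927, seed = s + 404L))
}

#' Draw a synthetic class table
#'
#' Wrapped-Gaussian mixture draws of (chi1, chi2); chi3 is drawn near the
#' unstrained +/-90 S-S minima (SD 10 degrees, random sign); d_calpha is the
#' geometric fragment distance at the drawn dihedrals plus Gaussian noise.
#' Deterministic under the spec's seed.
#'
#' @param spec a \code{\link{classSpec}}
#' @return data.frame(chi1, chi2, chi3, d_calpha, joint_state)
#' @export
sampleClass <- function(spec) {
  stopifnot(inherits(spec, "ClassSpec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  cmp <- spec$components
  k <- sample.int(nrow(cmp), spec$n, replace = TRUE, prob = cmp$weight)
  chi1 <- wrapAngle(stats::rnorm(spec$n, cmp$c1[k], cmp$spread[k]))
  chi2 <- wrapAngle(stats::rnorm(spec$n, cmp$c2[k], cmp$spread[k]))
  chi3 <- wrapAngle(stats::rnorm(spec$n, sample(c(-90, 90), spec$n,
                                                replace = TRUE), 10))
  frag <- .fragmentModel()
  d <- vapply(seq_len(spec$n), function(i) {
    xyz <- buildCartesian(frag, c(chi1[i], chi3[i], chi2[i]))
    atomDistance(xyz, 1, 6)
  }, numeric(1))
  d <- d + stats::rnorm(spec$n, 0, spec$noiseSd)
  cc <- isClosed(chi1) & isClosed(chi2)
  oo <- !isClosed(chi1) & !isClosed(chi2)
  data.frame(chi1 = chi1, chi2 = chi2, chi3 = chi3, d_calpha = d,
             joint_state = ifelse(cc, "closed/closed",
                                  ifelse(oo, "open/open", "open/closed")),
             stringsAsFactors = FALSE)
}

#' Analytic closed/closed probability of a class spec
#'
#' Exact mixture probability that both chi1 and chi2 fall inside the
#' [130, 230] closed band, from wrapped-normal interval masses (three-image
#' wrapping is exact to numerical precision at spreads below ~60 degrees).
#'
#' @param spec a \code{\link{classSpec}}
#' @return probability in [0, 1]
#' @export
closedClosedProb <- function(spec) {
  stopifnot(inherits(spec, "ClassSpec"))
  band <- function(center, sd) {
    sum(vapply(c(-360, 0, 360), function(k)
      stats::pnorm(230, center + k, sd) - stats::pnorm(130, center + k, sd),
      numeric(1)))
  }
  cmp <- spec$components
  sum(cmp$weight * vapply(seq_len(nrow(cmp)), function(i)
    band(cmp$c1[i], cmp$spread[i]) * band(cmp$c2[i], cmp$spread[i]),
    numeric(1)))
}

#' Write the standard synthetic fixture set
#'
#' Produces, deterministically under \code{masterSeed}: twelve
#' single-disulfide PDB fragments spanning the (open|closed)^2 grid
#' including band-boundary angles, four class tables with 40, 27, 69 and 927
#' rows (TDi-, DO-, interchain-Ig- and intrachain-Ig-like), one malformed
#' PDB (negative fixture), and a JSON manifest.
#'
#' @param outDir output directory (created if needed)
#' @param masterSeed integer seed
#' @return the manifest as a list, invisibly
#' @export
makeShippedFixtures <- function(outDir, masterSeed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  grid <- data.frame(
    chi1 = c(180, 180, 60, 60, 300, 300, 131, 229, 165, 129, 231, 90),
    chi2 = c(180, 60, 180, 300, 300, 180, 229, 131, 178, 180, 180, 270),
    chi3 = c(90, 90, 90, 270, 270, 90, 90, 270, 90, 90, 270, 90))
  pdbs <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pdbs[i] <- file.path(outDir, sprintf("ss_%02d_chi1_%g_chi2_%g.pdb", i,
                                         grid$chi1[i], grid$chi2[i]))
    writeDisulfidePdb(grid$chi1[i], grid$chi2[i], grid$chi3[i], pdbs[i])
  }
  specs <- defaultClassSpecs(masterSeed)
  tables <- character(length(specs))
  for (j in seq_along(specs)) {
    tab <- sampleClass(specs[[j]])
    tables[j] <- file.path(outDir, paste0("class_", names(specs)[j], ".tsv"))
    utils::write.table(format(tab, digits = 10, trim = TRUE), tables[j],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bad <- file.path(outDir, "malformed.pdb")
  writeLines(c("ATOM      1  CA  CYS A   1      bad line"), bad)
  manifest <- list(master_seed = as.integer(masterSeed),
                   pdb_fixtures = basename(pdbs),
                   prescribed = grid,
                   class_tables = basename(tables),
                   class_n = vapply(specs, function(s) s$n, integer(1)),
                   malformed = basename(bad))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
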