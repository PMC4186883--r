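# PDB disulfide survey: parse structures, locate S-S bridges, measure
# chi1/chi2/chi3 and the Calpha-Calpha distance, classify conformers and
# aggregate per protein class. ATOM/HETATM handling is delegated to
# bio3d::read.pdb; SSBOND records, line validation and altloc resolution are
# layered on top (bio3d does not expose SSBOND).

#' Parse a PDB file for the disulfide survey
#'
#' Reads ATOM/HETATM coordinates (first model of multi-model files, with a
#' notice) and SSBOND declarations. Alternate locations are resolved to the
#' highest-occupancy conformer, ties broken by altloc identifier order.
#'
#' @param path PDB-format file
#' @return list with \code{atoms} (data.frame: chain, resno, insert, resid,
#'   elety, alt, occ, x, y, z) and \code{ssbond} (data.frame: chain_a,
#'   res_a, chain_b, res_b; zero rows when no SSBOND records)
#' @export
parsePdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM records in ", path, ": empty structure")
  short <- which(is_atom & nchar(lines) < 54)
  if (length(short))
    stop("truncated ATOM record at line ", short[1], " of ", path)
  if (sum(rec == "MODEL ") > 1)
    message("multi-model file ", basename(path), ": using the first model only")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(chain = ifelse(is.na(a$chain), " ", a$chain),
                      resno = a$resno,
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      resid = a$resid, elety = a$elety,
                      alt = ifelse(is.na(a$alt), "", a$alt),
                      occ = ifelse(is.na(a$o), 1, a$o),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  # altloc: keep the highest-occupancy conformer per (chain, res, atom name)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$elety, sep = "|")), ]
  ss_lines <- lines[rec == "SSBOND"]
  ssbond <- if (length(ss_lines)) {
    data.frame(chain_a = trimws(substr(ss_lines, 16, 16)),
               res_a = as.integer(substr(ss_lines, 18, 21)),
               chain_b = trimws(substr(ss_lines, 30, 30)),
               res_b = as.integer(substr(ss_lines, 32, 35)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain_a = character(), res_a = integer(),
               chain_b = character(), res_b = integer(),
               stringsAsFactors = FALSE)
  }
  list(atoms = atoms, ssbond = ssbond, path = path)
}

.getAtom <- function(atoms, chain, resno, elety) {
  hit <- atoms$chain == chain & atoms$resno == resno & atoms$elety == elety
  if (!any(hit)) return(NULL)
  as.numeric(atoms[which(hit)[1], c("x", "y", "z")])
}

#' Locate disulfide bridges in a parsed structure
#'
#' Union of declared SSBOND pairs and geometric pairs (SG-SG distance at most
#' \code{sgCutoff} between distinct CYS residues), deduplicated and ordered
#' by (chain, residue number). Pairs missing any of CA/CB/SG on either side
#' are dropped with a warning.
#'
#' @param structure result of \code{\link{parsePdb}}
#' @param sgCutoff Angstrom; default 2.5 (covalent S-S is about 2.05)
#' @return data.frame(chain_a, res_a, chain_b, res_b), possibly empty
#' @export
findDisulfides <- function(structure, sgCutoff = 2.5) {
  atoms <- structure$atoms
  cys_sg <- atoms[atoms$resid == "CYS" & atoms$elety == "SG", , drop = FALSE]
  pairs <- structure$ssbond
  if (nrow(cys_sg) >= 2) {
    xyz <- as.matrix(cys_sg[, c("x", "y", "z")])
    dd <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(dd) & dd <= sgCutoff, arr.ind = TRUE)
    if (nrow(idx)) {
      geo <- data.frame(chain_a = cys_sg$chain[idx[, 1]],
                        res_a = cys_sg$resno[idx[, 1]],
                        chain_b = cys_sg$chain[idx[, 2]],
                        res_b = cys_sg$resno[idx[, 2]],
                        stringsAsFactors = FALSE)
      pairs <- rbind(pairs, geo)
    }
  }
  if (nrow(pairs) == 0) return(pairs)
  # canonical order within pair, then dedupe
  flip <- pairs$chain_a > pairs$chain_b |
    (pairs$chain_a == pairs$chain_b & pairs$res_a > pairs$res_b)
  pairs[flip, ] <- pairs[flip, c("chain_b", "res_b", "chain_a", "res_a")]
  pairs <- pairs[!duplicated(paste(pairs$chain_a, pairs$res_a,
                                   pairs$chain_b, pairs$res_b)), , drop = FALSE]
  keep <- rep(TRUE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (side in c("a", "b")) {
      ch <- pairs[[paste0("chain_", side)]][i]
      rn <- pairs[[paste0("res_", side)]][i]
      for (at in c("CA", "CB", "SG")) {
        if (is.null(.getAtom(atoms, ch, rn, at))) {
          warning(sprintf("disulfide pair %s%d-%s%d: missing atom %s on %s%d; excluded",
                          pairs$chain_a[i], pairs$res_a[i], pairs$chain_b[i],
                          pairs$res_b[i], at, ch, rn))
          keep[i] <- FALSE
        }
      }
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  pairs[order(pairs$chain_a, pairs$res_a, pairs$chain_b, pairs$res_b), ,
        drop = FALSE]
}

#' Measure the geometry of one disulfide bridge
#'
#' chi1 = CA-CB-SG-SG' of the first residue, chi2 the same for the second,
#' chi3 = CB-SG-SG'-CB' (the central C-S-S-C dihedral); angles in [0, 360)
#' with signed (-180, 180] companions. Residues are ordered by
#' (chain, residue number).
#'
#' @param structure result of \code{\link{parsePdb}}
#' @param pair one-row data.frame or list with chain_a, res_a, chain_b,
#'   res_b
#' @return one-row data.frame: identifiers, chi1, chi2, chi3 (degrees,
#'   [0, 360)), chi1_signed, chi2_signed, d_calpha, ss_length (Angstrom),
#'   state_a, state_b, joint_state, interchain
#' @export
measureDisulfide <- function(structure, pair) {
  atoms <- structure$atoms
  ids <- data.frame(chain = c(pair$chain_a, pair$chain_b),
                    res = c(pair$res_a, pair$res_b),
                    stringsAsFactors = FALSE)
  ids <- ids[order(ids$chain, ids$res), ]
  geta <- function(side, at) {
    p <- .getAtom(atoms, ids$chain[side], ids$res[side], at)
    if (is.null(p))
      stop(sprintf("residue %s%d: missing atom %s", ids$chain[side],
                   ids$res[side], at))
    p
  }
  ca_a <- geta(1, "CA"); cb_a <- geta(1, "CB"); sg_a <- geta(1, "SG")
  ca_b <- geta(2, "CA"); cb_b <- geta(2, "CB"); sg_b <- geta(2, "SG")
  chi1 <- dihedralAngle(ca_a, cb_a, sg_a, sg_b)
  chi2 <- dihedralAngle(ca_b, cb_b, sg_b, sg_a)
  chi3 <- dihedralAngle(cb_a, sg_a, sg_b, cb_b)
  st_a <- classifyChi(chi1)
  st_b <- classifyChi(chi2)
  joint <- if (st_a == "closed" && st_b == "closed") "closed/closed"
           else if (st_a == "open" && st_b == "open") "open/open"
           else "open/closed"
  data.frame(chain_a = ids$chain[1], res_a = ids$res[1],
             chain_b = ids$chain[2], res_b = ids$res[2],
             chi1 = chi1, chi2 = chi2, chi3 = chi3,
             chi1_signed = wrapTo180(chi1), chi2_signed = wrapTo180(chi2),
             d_calpha = sqrt(sum((ca_a - ca_b)^2)),
             ss_length = sqrt(sum((sg_a - sg_b)^2)),
             state_a = st_a, state_b = st_b, joint_state = joint,
             interchain = ids$chain[1] != ids$chain[2],
             stringsAsFactors = FALSE)
}

#' Survey disulfides across PDB files
#'
#' Full pipeline per file: parse, locate bridges, measure each. S-S bond
#' lengths outside [1.8, 2.5] Angstrom are dropped with a warning (likely
#' mis-declared or broken bridges).
#'
#' @param paths character vector of PDB files
#' @param sgCutoff geometric detection cutoff, Angstrom
#' @return data.frame, one row per accepted disulfide, with a leading
#'   \code{pdb_id} column (file base name)
#' @export
surveyPdb <- function(paths, sgCutoff = 2.5) {
  rows <- list()
  for (p in paths) {
    st <- parsePdb(p)
    pairs <- findDisulfides(st, sgCutoff = sgCutoff)
    if (nrow(pairs) == 0) next
    for (i in seq_len(nrow(pairs))) {
      g <- measureDisulfide(st, pairs[i, ])
      if (g$ss_length < 1.8 || g$ss_length > 2.5) {
        warning(sprintf("%s %s%d-%s%d: S-S length %.2f A outside [1.8, 2.5]; dropped",
                        basename(p), g$chain_a, g$res_a, g$chain_b, g$res_b,
                        g$ss_length))
        next
      }
      rows[[length(rows) + 1]] <-
        cbind(pdb_id = sub("\\.(pdb|ent)$", "", basename(p)), g,
              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pdb_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Per-class summary of disulfide geometries
#'
#' Arithmetic mean and SD of the Calpha-Calpha distance and the fraction of
#' closed/closed bridges, for one protein class (TDi, DO, interchain or
#' intrachain Ig, or any user label).
#'
#' @param records data.frame of disulfide geometries (rows of
#'   \code{\link{surveyPdb}} or \code{\link{sampleClass}} tables with
#'   \code{d_calpha} and either \code{joint_state} or chi columns)
#' @param classLabel label attached to the summary
#' @return one-row data.frame: class_label, n, mean_d_calpha, sd_d_calpha,
#'   fraction_closed_closed
#' @export
summarizeClass <- function(records, classLabel) {
  if (is.null(records) || nrow(records) == 0)
    stop("cannot summarize an empty record set")
  if (!"joint_state" %in% names(records)) {
    cc <- isClosed(records$chi1) & isClosed(records$chi2)
  } else {
    cc <- records$joint_state == "closed/closed"
  }
  data.frame(class_label = classLabel, n = nrow(records),
             mean_d_calpha = mean(records$d_calpha),
             sd_d_calpha = stats::sd(records$d_calpha),
             fraction_closed_closed = mean(cc),
             stringsAsFactors = FALSE)
}
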