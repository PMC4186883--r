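# Builtin torsional models of the three disulfide compounds: diethyl
# disulfide (DEDS), cystine, and the force-bearing path of the
# disulfide-bridged polypeptide loop (Ile-Cys-...-Cys-Gln with the slack
# residues 3-9 omitted, since they carry no tension once the force path
# short-circuits through the S-S bridge).
#
# Bond lengths/angles are standard heavy-atom values (C-C 1.53 A, C-S 1.82 A,
# S-S 2.05 A, C-S-S 103.7 deg, C-C-S 114.7 deg, tetrahedral/peptide values
# for the backbone); they are frozen, only torsions move.

.BL <- c(CC = 1.53, CS = 1.82, SS = 2.05, NCA = 1.46, CAC = 1.52, CN = 1.33)
.BA <- c(CCS = 114.7, CSS = 103.7, SP3 = 110.5, NCAC = 111.0,
         CACN = 117.2, CNCA = 121.7)

#' Torsional Fourier parameter table
#'
#' Reads the editable torsion parameter file shipped with the package
#' (three-term Fourier amplitudes in kJ/mol with phase offsets in degrees,
#' one row per torsion type: \code{CCSS} for C-C-S-S, \code{CSSC} for the
#' central S-S torsion, \code{SP3} for generic single bonds).
#'
#' @param path optional path to an alternative parameter file with the same
#'   columns
#' @return data.frame with columns type, V1..V3, g1..g3
#' @export
torsionParams <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "torsion_params.tsv", package = "ssbridge",
                        mustWork = TRUE)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("type", "V1", "V2", "V3", "g1", "g2", "g3")
  if (!all(need %in% names(tb)))
    stop("torsion parameter file lacks columns: ",
         paste(setdiff(need, names(tb)), collapse = ", "))
  tb
}

.torsionRow <- function(params, type, label) {
  r <- params[params$type == type, , drop = FALSE]
  if (nrow(r) != 1) stop("no unique torsion parameters of type ", type)
  data.frame(label = label, V1 = r$V1, V2 = r$V2, V3 = r$V3,
             g1 = r$g1, g2 = r$g2, g3 = r$g3, stringsAsFactors = FALSE)
}

.atomRow <- function(name, element, ref1 = NA, ref2 = NA, ref3 = NA,
                     bond_length = NA, bond_angle = NA, dih_ref = NA,
                     dih_fixed = NA) {
  data.frame(name = name, element = element, ref1 = ref1, ref2 = ref2,
             ref3 = ref3, bond_length = bond_length, bond_angle = bond_angle,
             dih_ref = dih_ref, dih_fixed = dih_fixed,
             stringsAsFactors = FALSE)
}

#' Builtin disulfide model compounds
#'
#' Constructs one of the three reduced torsional models. \code{"DEDS"} is the
#' minimal CH3-CH2-S-S-CH2-CH3 compound (heavy atoms only; three rotatable
#' dihedrals chi1, chi3, chi2; the pulled terminal carbons double as the
#' alpha-carbon pair). \code{"cystine"} is the dipeptide: the
#' N-CA-CB-S-S-CB-CA-C heavy-atom path with five rotatable dihedrals, pulled
#' at the N and C termini. \code{"polypeptide-path"} is the force-bearing
#' path of the disulfide-bridged loop (flanking backbone, both cysteine
#' sidechains and the S-S bridge; nine rotatable dihedrals, peptide omega
#' dihedrals fixed at 180 degrees), pulled at the terminal backbone atoms.
#'
#' @param name one of \code{"DEDS"}, \code{"cystine"},
#'   \code{"polypeptide-path"}
#' @param params torsion parameter table, see \code{\link{torsionParams}}
#' @return a \linkS4class{TorsionalModel}
#' @examples
#' m <- builtinModel("DEDS")
#' chiIndices(m)
#' @export
builtinModel <- function(name = c("DEDS", "cystine", "polypeptide-path"),
                         params = torsionParams()) {
  name <- match.arg(name)
  switch(name,
         "DEDS" = .modelDEDS(params),
         "cystine" = .modelCystine(params),
         "polypeptide-path" = .modelPolypeptide(params))
}

.modelDEDS <- function(params) {
  atoms <- rbind(
    .atomRow("C1", "C"),
    .atomRow("C2", "C", ref1 = 1, bond_length = .BL["CC"]),
    .atomRow("S3", "S", ref1 = 2, ref2 = 1, bond_length = .BL["CS"],
             bond_angle = .BA["CCS"]),
    .atomRow("S4", "S", ref1 = 3, ref2 = 2, ref3 = 1, bond_length = .BL["SS"],
             bond_angle = .BA["CSS"], dih_ref = 1),
    .atomRow("C5", "C", ref1 = 4, ref2 = 3, ref3 = 2, bond_length = .BL["CS"],
             bond_angle = .BA["CSS"], dih_ref = 2),
    .atomRow("C6", "C", ref1 = 5, ref2 = 4, ref3 = 3, bond_length = .BL["CC"],
             bond_angle = .BA["CCS"], dih_ref = 3))
  torsions <- rbind(
    .torsionRow(params, "CCSS", "chi1"),
    .torsionRow(params, "CSSC", "chi3"),
    .torsionRow(params, "CCSS", "chi2"))
  new("TorsionalModel", name = "DEDS", atoms = atoms, torsions = torsions,
      pullPair = c(1L, 6L), calphaPair = c(1L, 6L))
}

.modelCystine <- function(params) {
  atoms <- rbind(
    .atomRow("N1",  "N"),
    .atomRow("CA1", "C", ref1 = 1, bond_length = .BL["NCA"]),
    .atomRow("CB1", "C", ref1 = 2, ref2 = 1, bond_length = .BL["CC"],
             bond_angle = .BA["SP3"]),
    .atomRow("SG1", "S", ref1 = 3, ref2 = 2, ref3 = 1, bond_length = .BL["CS"],
             bond_angle = .BA["CCS"], dih_ref = 1),
    .atomRow("SG2", "S", ref1 = 4, ref2 = 3, ref3 = 2, bond_length = .BL["SS"],
             bond_angle = .BA["CSS"], dih_ref = 2),
    .atomRow("CB2", "C", ref1 = 5, ref2 = 4, ref3 = 3, bond_length = .BL["CS"],
             bond_angle = .BA["CSS"], dih_ref = 3),
    .atomRow("CA2", "C", ref1 = 6, ref2 = 5, ref3 = 4, bond_length = .BL["CC"],
             bond_angle = .BA["CCS"], dih_ref = 4),
    .atomRow("C2",  "C", ref1 = 7, ref2 = 6, ref3 = 5, bond_length = .BL["CAC"],
             bond_angle = .BA["SP3"], dih_ref = 5))
  torsions <- rbind(
    .torsionRow(params, "SP3",  "chiN"),   # N-CA-CB-SG rotamer
    .torsionRow(params, "CCSS", "chi1"),
    .torsionRow(params, "CSSC", "chi3"),
    .torsionRow(params, "CCSS", "chi2"),
    .torsionRow(params, "SP3",  "chiC"))   # SG-CB-CA-C rotamer
  new("TorsionalModel", name = "cystine", atoms = atoms, torsions = torsions,
      pullPair = c(1L, 8L), calphaPair = c(2L, 7L))
}

.modelPolypeptide <- function(params) {
  atoms <- rbind(
    .atomRow("N1",   "N"),
    .atomRow("CA1",  "C", ref1 = 1, bond_length = .BL["NCA"]),
    .atomRow("C1",   "C", ref1 = 2, ref2 = 1, bond_length = .BL["CAC"],
             bond_angle = .BA["NCAC"]),
    .atomRow("N2",   "N", ref1 = 3, ref2 = 2, ref3 = 1, bond_length = .BL["CN"],
             bond_angle = .BA["CACN"], dih_ref = 1),          # psi1
    .atomRow("CA2",  "C", ref1 = 4, ref2 = 3, ref3 = 2, bond_length = .BL["NCA"],
             bond_angle = .BA["CNCA"], dih_fixed = 180),      # omega fixed
    .atomRow("CB2",  "C", ref1 = 5, ref2 = 4, ref3 = 3, bond_length = .BL["CC"],
             bond_angle = .BA["SP3"], dih_ref = 2),           # N-CA rotation
    .atomRow("SG2",  "S", ref1 = 6, ref2 = 5, ref3 = 4, bond_length = .BL["CS"],
             bond_angle = .BA["CCS"], dih_ref = 3),           # CA-CB rotation
    .atomRow("SG10", "S", ref1 = 7, ref2 = 6, ref3 = 5, bond_length = .BL["SS"],
             bond_angle = .BA["CSS"], dih_ref = 4),           # chi1
    .atomRow("CB10", "C", ref1 = 8, ref2 = 7, ref3 = 6, bond_length = .BL["CS"],
             bond_angle = .BA["CSS"], dih_ref = 5),           # chi3
    .atomRow("CA10", "C", ref1 = 9, ref2 = 8, ref3 = 7, bond_length = .BL["CC"],
             bond_angle = .BA["CCS"], dih_ref = 6),           # chi2
    .atomRow("C10",  "C", ref1 = 10, ref2 = 9, ref3 = 8, bond_length = .BL["CAC"],
             bond_angle = .BA["SP3"], dih_ref = 7),           # CB-CA rotation
    .atomRow("N11",  "N", ref1 = 11, ref2 = 10, ref3 = 9, bond_length = .BL["CN"],
             bond_angle = .BA["CACN"], dih_ref = 8),          # psi10
    .atomRow("CA11", "C", ref1 = 12, ref2 = 11, ref3 = 10, bond_length = .BL["NCA"],
             bond_angle = .BA["CNCA"], dih_fixed = 180),      # omega fixed
    .atomRow("C11",  "C", ref1 = 13, ref2 = 12, ref3 = 11, bond_length = .BL["CAC"],
             bond_angle = .BA["NCAC"], dih_ref = 9))          # phi11
  torsions <- rbind(
    .torsionRow(params, "SP3",  "psi1"),
    .torsionRow(params, "SP3",  "phi2"),
    .torsionRow(params, "SP3",  "chiCA2"),
    .torsionRow(params, "CCSS", "chi1"),
    .torsionRow(params, "CSSC", "chi3"),
    .torsionRow(params, "CCSS", "chi2"),
    .torsionRow(params, "SP3",  "chiCA10"),
    .torsionRow(params, "SP3",  "psi10"),
    .torsionRow(params, "SP3",  "phi11"))
  new("TorsionalModel", name = "polypeptide-path", atoms = atoms,
      torsions = torsions, pullPair = c(1L, 14L), calphaPair = c(5L, 10L))
}

#' Locate chi1/chi2/chi3 among a model's rotatable dihedrals
#'
#' @param model a \linkS4class{TorsionalModel} whose torsion labels include
#'   \code{chi1}, \code{chi2}, \code{chi3}
#' @return named list of integer indices into the conformation vector
#' @export
chiIndices <- function(model) {
  stopifnot(is(model, "TorsionalModel"))
  lab <- model@torsions$label
  idx <- lapply(c(chi1 = "chi1", chi2 = "chi2", chi3 = "chi3"),
                function(l) match(l, lab))
  if (any(vapply(idx, is.na, logical(1))))
    stop("model '", model@name, "' does not label chi1/chi2/chi3 torsions")
  idx
}

#' Read a torsional model from a plain-text config
#'
#' One record per atom, whitespace-separated columns:
#' \code{name element ref1 ref2 ref3 bond_length bond_angle dih}. The three
#' seed atoms use \code{-} for unused fields. \code{dih} is either
#' \code{fixed:<degrees>} or a torsion type from the parameter table
#' (\code{CCSS}, \code{CSSC}, \code{SP3}, ...), which appends a rotatable
#' dihedral; an optional \code{:<label>} suffix names it. Directives
#' \code{pull i j} and \code{calpha i j} (1-based atom indices) declare the
#' force and observable pairs; \code{model <name>} names the model. Lines
#' starting with \code{#} are comments.
#'
#' @param path config file path
#' @param params torsion parameter table
#' @return a \linkS4class{TorsionalModel}
#' @export
readModelConfig <- function(path, params = torsionParams()) {
  if (!file.exists(path)) stop("model config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  atoms <- NULL
  torsions <- NULL
  pull <- NULL; calpha <- NULL; mname <- "user"
  num <- function(x) if (x == "-") NA_real_ else as.numeric(x)
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] == "model") { mname <- f[2]; next }
    if (f[1] == "pull") { pull <- as.integer(f[2:3]); next }
    if (f[1] == "calpha") { calpha <- as.integer(f[2:3]); next }
    if (length(f) != 8)
      stop("malformed atom record (need 8 fields): '", ln, "'")
    dih <- f[8]
    dih_ref <- NA_integer_; dih_fixed <- NA_real_
    if (startsWith(dih, "fixed:")) {
      dih_fixed <- as.numeric(sub("^fixed:", "", dih))
    } else if (dih != "-") {
      parts <- strsplit(dih, ":")[[1]]
      label <- if (length(parts) > 1) parts[2] else
        paste0("d", if (is.null(torsions)) 1 else nrow(torsions) + 1)
      torsions <- rbind(torsions, .torsionRow(params, parts[1], label))
      dih_ref <- nrow(torsions)
    }
    ri <- function(x) if (x == "-") NA_integer_ else as.integer(x)
    atoms <- rbind(atoms, .atomRow(f[1], f[2], ri(f[3]), ri(f[4]), ri(f[5]),
                                   num(f[6]), num(f[7]), dih_ref, dih_fixed))
  }
  if (is.null(pull) || is.null(calpha))
    stop("model config must declare 'pull' and 'calpha' pairs")
  new("TorsionalModel", name = mname, atoms = atoms, torsions = torsions,
      pullPair = pull, calphaPair = calpha)
}
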