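#' @import methods
NULL

#' Torsional model of a disulfide compound
#'
#' A reduced, torsion-only representation of a disulfide model compound
#' (diethyl disulfide, cystine, or the force-bearing path of a
#' disulfide-bridged polypeptide loop). Bond lengths and angles are frozen;
#' the only degrees of freedom are the declared rotatable dihedrals, each
#' carrying a three-term Fourier torsional potential. A collinear constant
#' force acts on \code{pullPair}; \code{calphaPair} marks the two alpha-carbon
#' (or alpha-carbon-equivalent) atoms whose separation is the strain proxy.
#'
#' @slot name model name (\code{"DEDS"}, \code{"cystine"},
#'   \code{"polypeptide-path"} or a user label)
#' @slot atoms data.frame with one row per atom: \code{name}, \code{element},
#'   \code{ref1}, \code{ref2}, \code{ref3} (1-based indices of the three
#'   previously placed atoms; \code{NA} for the seed atoms),
#'   \code{bond_length} (Angstrom), \code{bond_angle} (degrees),
#'   \code{dih_ref} (1-based index into the rotatable-dihedral list, or
#'   \code{NA}), \code{dih_fixed} (fixed dihedral in degrees where
#'   \code{dih_ref} is \code{NA})
#' @slot torsions data.frame with one row per rotatable dihedral:
#'   \code{label}, Fourier amplitudes \code{V1}, \code{V2}, \code{V3}
#'   (kJ/mol) and phases \code{g1}, \code{g2}, \code{g3} (degrees)
#' @slot pullPair integer(2), atoms receiving the external force
#' @slot calphaPair integer(2), alpha-carbon observable pair
#' @export
setClass("TorsionalModel",
  representation(name = "character", atoms = "data.frame",
                 torsions = "data.frame", pullPair = "integer",
                 calphaPair = "integer"))

setValidity("TorsionalModel", function(object) {
  a <- object@atoms
  msgs <- character()
  need <- c("name", "element", "ref1", "ref2", "ref3", "bond_length",
            "bond_angle", "dih_ref", "dih_fixed")
  if (!all(need %in% names(a)))
    return(paste("atoms table lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) < 4) msgs <- c(msgs, "model needs at least 4 atoms")
  if (any(a$bond_length[-1] <= 0, na.rm = TRUE))
    msgs <- c(msgs, "bond lengths must be positive")
  ba <- a$bond_angle[-(1:2)]
  if (any(!is.na(ba) & (ba <= 0 | ba >= 180)))
    msgs <- c(msgs, "bond angles must lie in (0, 180) degrees")
  for (i in seq_len(nrow(a))[-(1:3)]) {
    r <- unlist(a[i, c("ref1", "ref2", "ref3")])
    if (any(is.na(r)) || any(r >= i) || any(r < 1))
      msgs <- c(msgs, sprintf("atom %d references atoms not yet placed", i))
  }
  nd <- nrow(object@torsions)
  if (nd < 1) msgs <- c(msgs, "at least one rotatable dihedral required")
  if (!all(c("V1", "V2", "V3", "g1", "g2", "g3") %in% names(object@torsions)))
    msgs <- c(msgs, "torsions table lacks Fourier columns")
  else if (!all(is.finite(as.matrix(object@torsions[, c("V1", "V2", "V3")]))))
    msgs <- c(msgs, "Fourier coefficients must be finite")
  dref <- a$dih_ref
  if (any(!is.na(dref) & (dref < 1 | dref > nd)))
    msgs <- c(msgs, "dih_ref out of range of the torsion list")
  for (p in list(object@pullPair, object@calphaPair))
    if (length(p) != 2 || any(p < 1) || any(p > nrow(a)))
      msgs <- c(msgs, "pull/calpha pair must index existing atoms")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Constant-force Monte-Carlo ensemble
#'
#' Samples drawn from the isotensional (force-clamp) Boltzmann distribution
#' \eqn{\propto \exp[-(U(\phi) - F R(\phi))/k_B T]} over the rotatable
#' dihedrals of a \linkS4class{TorsionalModel}. \code{R} is the mechanical
#' coordinate: the distance between the two atoms the force is applied to.
#'
#' @slot model name of the sampled model
#' @slot force applied force in pN
#' @slot temperature K
#' @slot dihedrals numeric matrix, one row per retained sample, columns in
#'   the model's rotatable-dihedral order, degrees in [0, 360)
#' @slot R mechanical coordinate per sample, Angstrom
#' @slot dCalpha alpha-carbon pair distance per sample, Angstrom
#' @slot energy total energy per sample, kJ/mol
#' @slot seed,nSteps,nBurnin,thinning sampling metadata
#' @slot acceptRate fraction of proposals accepted
#' @export
setClass("ForceClampEnsemble",
  representation(model = "character", force = "numeric",
                 temperature = "numeric", dihedrals = "matrix",
                 R = "numeric", dCalpha = "numeric", energy = "numeric",
                 seed = "integer", nSteps = "numeric", nBurnin = "numeric",
                 thinning = "integer", acceptRate = "numeric"))

setValidity("ForceClampEnsemble", function(object) {
  n <- nrow(object@dihedrals)
  if (length(object@R) != n || length(object@dCalpha) != n ||
      length(object@energy) != n)
    return("sample vectors and dihedral matrix disagree in length")
  if (n > 0 && any(object@R <= 0)) return("mechanical coordinate must be positive")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' Periodic two-dimensional dihedral landscape
#'
#' A periodic histogram over the (chi1, chi2) torus holding raw counts, the
#' normalised probability P per bin, and the Boltzmann-inverted free-energy
#' surface -kB*T*log(P) shifted so its sampled minimum is zero. Bins never
#' visited by the sampler are flagged \code{unsampled} rather than being
#' assigned an infinite energy.
#'
#' @slot breaks bin edges in degrees, length nbins+1, spanning [0, 360]
#' @slot counts integer-valued matrix (chi1 rows, chi2 columns)
#' @slot P normalised probability per bin, sums to 1
#' @slot fes free energy per bin, kJ/mol, NA where unsampled
#' @slot unsampled logical matrix marking empty bins
#' @slot temperature K used in the inversion
#' @export
setClass("Landscape2D",
  representation(breaks = "numeric", counts = "matrix", P = "matrix",
                 fes = "matrix", unsampled = "matrix", temperature = "numeric"))

setValidity("Landscape2D", function(object) {
  nb <- length(object@breaks) - 1
  if (!all(dim(object@counts) == c(nb, nb))) return("counts dimension mismatch")
  if (abs(sum(object@P) - 1) > 1e-12) return("P must sum to 1")
  f <- object@fes[!object@unsampled]
  if (length(f) && (min(f) < -1e-9)) return("fes must be shifted to min 0")
  TRUE
})

#' Force scan summary
#'
#' Per-force summaries of a ladder of constant-force ensembles: total open
#' character (fraction of samples with at least one C-C-S-S dihedral outside
#' 180 +/- 50 degrees), closed/closed occupancy, mean mechanical coordinate,
#' mean alpha-carbon distance, and the mean absolute deviation of the central
#' C-S-S-C dihedral from its unstrained 90-degree minimum. Standard errors
#' are batch-means estimates (autocorrelation-aware).
#'
#' @slot model model name
#' @slot table data.frame with columns \code{force}, \code{open_fraction},
#'   \code{open_se}, \code{closed_closed}, \code{cc_se}, \code{mean_R},
#'   \code{R_se}, \code{mean_d_calpha}, \code{dca_se}, \code{chi3_dev},
#'   \code{chi3_se}
#' @slot temperature K
#' @slot seed master seed of the scan
#' @export
setClass("ForceScan",
  representation(model = "character", table = "data.frame",
                 temperature = "numeric", seed = "integer"))

setValidity("ForceScan", function(object) {
  tb <- object@table
  need <- c("force", "open_fraction", "open_se", "closed_closed", "cc_se",
            "mean_R", "R_se", "mean_d_calpha", "dca_se", "chi3_dev", "chi3_se")
  if (!all(need %in% names(tb))) return("scan table lacks required columns")
  fr <- c(tb$open_fraction, tb$closed_closed)
  if (any(fr < -1e-12 | fr > 1 + 1e-12)) return("fractions must lie in [0, 1]")
  TRUE
})

#' Stress-strain ruler
#'
#' Monotone calibration of the mean alpha-carbon distance of a disulfide
#' model against applied tensile force, invertible to read an effective
#' force off an observed distance.
#'
#' @slot model calibrating model name
#' @slot forces calibration forces, pN, strictly increasing, starting at 0
#' @slot meanD mean alpha-carbon distance at each force, Angstrom (after any
#'   within-SE isotonic adjustment)
#' @slot seD standard error of each mean
#' @slot adjusted logical, TRUE if isotonic adjustment was applied
#' @export
setClass("RulerCurve",
  representation(model = "character", forces = "numeric", meanD = "numeric",
                 seD = "numeric", adjusted = "logical"))

setValidity("RulerCurve", function(object) {
  if (length(object@forces) < 3) return("at least 3 calibration forces required")
  if (object@forces[1] != 0) return("calibration must include zero force")
  if (any(diff(object@forces) <= 0)) return("forces must be strictly increasing")
  if (any(diff(object@meanD) <= 0)) return("mean distances must be strictly increasing")
  TRUE
})

setMethod("show", "TorsionalModel", function(object) {
  cat(sprintf("TorsionalModel '%s': %d atoms, %d rotatable dihedrals\n",
              object@name, nrow(object@atoms), nrow(object@torsions)))
  cat(sprintf("  pull pair: %s-%s   Calpha pair: %s-%s\n",
              object@atoms$name[object@pullPair[1]],
              object@atoms$name[object@pullPair[2]],
              object@atoms$name[object@calphaPair[1]],
              object@atoms$name[object@calphaPair[2]]))
  cat("  dihedrals:", paste(object@torsions$label, collapse = ", "), "\n")
})

setMethod("show", "ForceClampEnsemble", function(object) {
  cat(sprintf("ForceClampEnsemble: %s at %g pN, %g K\n",
              object@model, object@force, object@temperature))
  cat(sprintf("  %d samples (%g steps, burn-in %g, thin %d), acceptance %.2f\n",
              nrow(object@dihedrals), object@nSteps, object@nBurnin,
              object@thinning, object@acceptRate))
  if (nrow(object@dihedrals))
    cat(sprintf("  <R> = %.3f A   <dCa-Ca> = %.3f A\n",
                mean(object@R), mean(object@dCalpha)))
})

setMethod("show", "Landscape2D", function(object) {
  nb <- length(object@breaks) - 1
  cat(sprintf("Landscape2D: %d x %d periodic bins on [0, 360) deg, T = %g K\n",
              nb, nb, object@temperature))
  cat(sprintf("  %d counts, %d unsampled bins, max FES %.2f kJ/mol\n",
              sum(object@counts), sum(object@unsampled),
              suppressWarnings(max(object@fes, na.rm = TRUE))))
})

setMethod("show", "ForceScan", function(object) {
  cat(sprintf("ForceScan: %s over %d forces (%g-%g pN), T = %g K\n",
              object@model, nrow(object@table), min(object@table$force),
              max(object@table$force), object@temperature))
  print(object@table[, c("force", "open_fraction", "closed_closed", "mean_R",
                         "mean_d_calpha")], row.names = FALSE, digits = 4)
})

setMethod("show", "RulerCurve", function(object) {
  cat(sprintf("RulerCurve (%s): %d points, %g-%g pN, d = %.3f-%.3f A%s\n",
              object@model, length(object@forces), min(object@forces),
              max(object@forces), min(object@meanD), max(object@meanD),
              if (object@adjusted) " (isotonically adjusted)" else ""))
})

# ---- accessors ----

#' Accessors for ensemble and scan objects
#'
#' \code{ensembleSamples} returns the retained samples of a
#' \linkS4class{ForceClampEnsemble} as a data.frame (dihedrals, mechanical
#' coordinate R, alpha-carbon distance, energy). \code{scanTable} returns the
#' per-force summary table of a \linkS4class{ForceScan}.
#' \code{modelAtoms} and \code{modelTorsions} expose a
#' \linkS4class{TorsionalModel}'s atom and torsion tables;
#' \code{landscapeP} and \code{landscapeFES} the probability and free-energy
#' matrices of a \linkS4class{Landscape2D}.
#'
#' @param x the object
#' @return see description
#' @name accessors
NULL

#' @rdname accessors
#' @export
ensembleSamples <- function(x) {
  stopifnot(is(x, "ForceClampEnsemble"))
  d <- as.data.frame(x@dihedrals)
  d$R <- x@R
  d$d_calpha <- x@dCalpha
  d$energy <- x@energy
  d
}

#' @rdname accessors
#' @export
scanTable <- function(x) {
  stopifnot(is(x, "ForceScan"))
  x@table
}

#' @rdname accessors
#' @export
modelAtoms <- function(x) {
  stopifnot(is(x, "TorsionalModel"))
  x@atoms
}

#' @rdname accessors
#' @export
modelTorsions <- function(x) {
  stopifnot(is(x, "TorsionalModel"))
  x@torsions
}

#' @rdname accessors
#' @export
landscapeP <- function(x) {
  stopifnot(is(x, "Landscape2D"))
  x@P
}

#' @rdname accessors
#' @export
landscapeFES <- function(x) {
  stopifnot(is(x, "Landscape2D"))
  x@fes
}
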