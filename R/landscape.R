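# From ensembles to observables: periodic (chi1, chi2) probability
# landscapes, Boltzmann inversion, open-character statistics and
# force-resolved summaries.

#' Open/closed classification of a C-C-S-S dihedral
#'
#' A dihedral is \emph{closed} when its wrapped value lies within 180 +/- 50
#' degrees (inclusive at both ends), i.e. in [130, 230]; every other value is
#' \emph{open} (sterically permissive to collinear nucleophilic attack on
#' sulfur).
#'
#' @param chi dihedral(s), degrees (any wrapping)
#' @return \code{isClosed}: logical; \code{classifyChi}: character
#'   \code{"open"}/\code{"closed"}
#' @examples
#' classifyChi(c(180, 60, 130))
#' @export
isClosed <- function(chi) {
  a <- wrapAngle(chi)
  a >= 130 & a <= 230
}

#' @rdname isClosed
#' @export
classifyChi <- function(chi) {
  ifelse(isClosed(chi), "closed", "open")
}

# batch-means standard error (20 batches): MC samples are autocorrelated,
# so the naive i.i.d. SE underestimates.
.batchSE <- function(x, nBatches = 20) {
  n <- length(x)
  if (n < 2 * nBatches) return(stats::sd(x) / sqrt(max(n, 1)))
  bsize <- floor(n / nBatches)
  means <- vapply(seq_len(nBatches), function(b)
    mean(x[((b - 1) * bsize + 1):(b * bsize)]), numeric(1))
  stats::sd(means) / sqrt(nBatches)
}

#' Periodic 2D dihedral histogram
#'
#' Bins the (chi1, chi2) samples of an ensemble on the periodic torus
#' [0, 360) x [0, 360), normalises to a probability per bin, and attaches
#' the Boltzmann-inverted free-energy surface.
#'
#' @param ensemble a \linkS4class{ForceClampEnsemble}
#' @param chi1Index,chi2Index columns of the dihedral matrix holding chi1
#'   and chi2; default taken from the torsion labels
#' @param nBins bins per axis (>= 8); default 72 (5-degree resolution)
#' @return a \linkS4class{Landscape2D}
#' @export
histogram2d <- function(ensemble, chi1Index = NULL, chi2Index = NULL,
                        nBins = 72) {
  stopifnot(is(ensemble, "ForceClampEnsemble"))
  if (nBins < 8) stop("nBins must be at least 8")
  d <- ensemble@dihedrals
  if (nrow(d) == 0) stop("ensemble holds no samples")
  if (is.null(chi1Index)) chi1Index <- match("chi1", colnames(d))
  if (is.null(chi2Index)) chi2Index <- match("chi2", colnames(d))
  if (is.na(chi1Index) || is.na(chi2Index))
    stop("chi1/chi2 columns not found; give chi1Index/chi2Index explicitly")
  breaks <- seq(0, 360, length.out = nBins + 1)
  b1 <- pmin(floor(wrapAngle(d[, chi1Index]) / 360 * nBins) + 1L, nBins)
  b2 <- pmin(floor(wrapAngle(d[, chi2Index]) / 360 * nBins) + 1L, nBins)
  counts <- matrix(0L, nBins, nBins)
  tab <- table(factor(b1, levels = seq_len(nBins)),
               factor(b2, levels = seq_len(nBins)))
  counts[] <- as.integer(tab)
  P <- counts / sum(counts)
  inv <- boltzmannInvert(P, ensemble@temperature)
  new("Landscape2D", breaks = breaks, counts = counts, P = P,
      fes = inv$fes, unsampled = inv$unsampled,
      temperature = ensemble@temperature)
}

#' Boltzmann inversion between probabilities and free energies
#'
#' \code{boltzmannInvert} maps per-bin probabilities to a free-energy
#' surface \eqn{-k_B T \ln P}, shifted so the sampled minimum is zero;
#' empty bins are flagged unsampled (NA energy) rather than infinite.
#' \code{fesToP} is the inverse: renormalised \eqn{\exp(-F/k_B T)} with
#' unsampled bins restored as zero probability. The round trip
#' P -> FES -> P is the identity on sampled bins.
#'
#' @param P non-negative probabilities (any array shape), at least one
#'   positive entry
#' @param fes free energies in kJ/mol, NA marking unsampled bins
#' @param temperature K
#' @return \code{boltzmannInvert}: list(fes, unsampled);
#'   \code{fesToP}: probability array summing to 1
#' @export
boltzmannInvert <- function(P, temperature = 300) {
  if (any(P < 0)) stop("probabilities must be non-negative")
  if (all(P == 0)) stop("all-zero probability field cannot be inverted")
  unsampled <- P == 0
  fes <- P
  fes[] <- NA_real_
  fes[!unsampled] <- -.KB * temperature * log(P[!unsampled])
  fes <- fes - min(fes, na.rm = TRUE)
  list(fes = fes, unsampled = unsampled)
}

#' @rdname boltzmannInvert
#' @export
fesToP <- function(fes, temperature = 300) {
  w <- fes
  w[] <- 0
  ok <- !is.na(fes)
  if (!any(ok)) stop("free-energy field is entirely unsampled")
  w[ok] <- exp(-fes[ok] / (.KB * temperature))
  w / sum(w)
}

#' Total open character of an ensemble
#'
#' Fraction of samples in which at least one of the two C-C-S-S dihedrals is
#' open (the complement of closed/closed occupancy), with a batch-means
#' standard error.
#'
#' @param ensemble a \linkS4class{ForceClampEnsemble}
#' @param chi1Index,chi2Index dihedral columns; default from labels
#' @return list(fraction, se)
#' @export
openFraction <- function(ensemble, chi1Index = NULL, chi2Index = NULL) {
  stopifnot(is(ensemble, "ForceClampEnsemble"))
  d <- ensemble@dihedrals
  if (nrow(d) == 0) stop("ensemble holds no samples")
  if (is.null(chi1Index)) chi1Index <- match("chi1", colnames(d))
  if (is.null(chi2Index)) chi2Index <- match("chi2", colnames(d))
  open <- as.numeric(!(isClosed(d[, chi1Index]) & isClosed(d[, chi2Index])))
  list(fraction = mean(open), se = .batchSE(open))
}

#' Force ladder scan of a torsional model
#'
#' Runs \code{\link{metropolisSample}} at each force (per-force seeds derived
#' deterministically from the master seed) and summarises open character,
#' closed/closed occupancy, mean mechanical coordinate R, mean alpha-carbon
#' distance, and the mean absolute deviation of chi3 from its unstrained
#' 90-degree minimum (the nearer of the +/-90 wells).
#'
#' @param model a \linkS4class{TorsionalModel}
#' @param forces pN vector, length >= 2
#' @param temperature K
#' @param nSteps MC steps per force
#' @param seed master seed
#' @param ... further arguments to \code{\link{metropolisSample}}
#' @param keepEnsembles if TRUE, attach the per-force ensembles as an
#'   attribute \code{"ensembles"} of the returned object's table
#' @return a \linkS4class{ForceScan}
#' @export
forceScan <- function(model, forces, temperature = 300, nSteps = 2e5,
                      seed = 1, ..., keepEnsembles = FALSE) {
  stopifnot(is(model, "TorsionalModel"))
  if (length(forces) < 2) stop("a scan needs at least 2 forces")
  ci <- chiIndices(model)
  rows <- vector("list", length(forces))
  ensembles <- if (keepEnsembles) vector("list", length(forces)) else NULL
  for (i in seq_along(forces)) {
    # per-force seed: deterministic, distinct, independent of force ordering
    fseed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    ens <- metropolisSample(model, force = forces[i],
                            temperature = temperature, nSteps = nSteps,
                            seed = fseed, ...)
    d <- ens@dihedrals
    cc <- as.numeric(isClosed(d[, ci$chi1]) & isClosed(d[, ci$chi2]))
    chi3dev <- pmin(abs(wrapTo180(d[, ci$chi3] - 90)),
                    abs(wrapTo180(d[, ci$chi3] + 90)))
    rows[[i]] <- data.frame(
      force = forces[i],
      open_fraction = mean(1 - cc), open_se = .batchSE(1 - cc),
      closed_closed = mean(cc), cc_se = .batchSE(cc),
      mean_R = mean(ens@R), R_se = .batchSE(ens@R),
      mean_d_calpha = mean(ens@dCalpha), dca_se = .batchSE(ens@dCalpha),
      chi3_dev = mean(chi3dev), chi3_se = .batchSE(chi3dev))
    if (keepEnsembles) ensembles[[i]] <- ens
  }
  tb <- do.call(rbind, rows)
  if (keepEnsembles) attr(tb, "ensembles") <- ensembles
  new("ForceScan", model = model@name, table = tb,
      temperature = as.numeric(temperature), seed = as.integer(seed))
}

#' Write a landscape or scan to TSV
#'
#' Landscapes are written as a matrix with bin-centre header row/column
#' (probabilities per bin, not densities per square degree); scans one row
#' per force.
#'
#' @param x a \linkS4class{Landscape2D} or \linkS4class{ForceScan}
#' @param path output file
#' @return path, invisibly
#' @export
writeLandscapeTSV <- function(x, path) {
  if (is(x, "Landscape2D")) {
    nb <- length(x@breaks) - 1
    centers <- (x@breaks[-1] + x@breaks[-(nb + 1)]) / 2
    m <- x@P
    dimnames(m) <- list(chi1 = format(centers), chi2 = format(centers))
    utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  } else if (is(x, "ForceScan")) {
    utils::write.table(x@table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
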