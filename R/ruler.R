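# The stress-strain "ruler": a monotone calibration of mean Calpha-Calpha
# distance against tensile force, inverted to read an effective force off an
# observed distance, plus the Bell-model rate-enhancement calculator.

#' Calibrate a force-distance ruler from a force scan
#'
#' Fits a shape-preserving monotone piecewise-cubic interpolant (Hyman
#' filtering) through the (force, mean Calpha-Calpha distance) points of a
#' scan. If an adjacent pair of means decreases by more than its combined
#' 3 SE, calibration is refused; smaller (within-noise) violations are
#' repaired by isotonic regression and an epsilon strictification.
#'
#' @param scan a \linkS4class{ForceScan} whose forces include 0, or a
#'   data.frame with columns force, mean_d_calpha, dca_se
#' @return a \linkS4class{RulerCurve}
#' @export
calibrateRuler <- function(scan) {
  tb <- if (is(scan, "ForceScan")) scan@table else scan
  if (!all(c("force", "mean_d_calpha", "dca_se") %in% names(tb)))
    stop("scan lacks force/mean_d_calpha/dca_se columns")
  tb <- tb[order(tb$force), ]
  if (nrow(tb) < 3) stop("ruler calibration needs at least 3 forces")
  if (tb$force[1] != 0) stop("ruler calibration must include zero force")
  d <- tb$mean_d_calpha
  se <- tb$dca_se
  dd <- diff(d)
  tol <- 3 * sqrt(se[-length(se)]^2 + se[-1]^2)
  if (any(dd < -tol))
    stop("gross non-monotonicity in the calibration points ",
         "(decrease beyond combined 3 SE); refuse to calibrate")
  adjusted <- FALSE
  if (any(dd <= 0)) {
    d <- stats::isoreg(tb$force, d)$yf
    eps <- 1e-9 * max(d)
    d <- d + cumsum(c(0, (diff(d) <= 0))) * eps  # strictify flat runs
    adjusted <- TRUE
  }
  new("RulerCurve", model = if (is(scan, "ForceScan")) scan@model else "user",
      forces = tb$force, meanD = d, seD = se, adjusted = adjusted)
}

.rulerFun <- function(curve) {
  stats::splinefun(curve@forces, curve@meanD, method = "hyman")
}

#' Evaluate a ruler curve
#'
#' Mean Calpha-Calpha distance predicted at given force(s); passes exactly
#' through every calibration point.
#'
#' @param curve a \linkS4class{RulerCurve}
#' @param force pN, within the calibrated range
#' @return distance(s), Angstrom
#' @export
rulerDistance <- function(curve, force) {
  stopifnot(is(curve, "RulerCurve"))
  if (any(force < min(curve@forces) | force > max(curve@forces)))
    stop("force outside the calibrated range [",
         min(curve@forces), ", ", max(curve@forces), "] pN")
  .rulerFun(curve)(force)
}

#' Infer the effective tensile force from an observed distance
#'
#' Unique monotone inverse of the ruler to 0.1 pN, with the uncertainty
#' propagated from the calibration SEs through the local slope. Distances
#' below the zero-force mean return 0 pN flagged
#' \code{"compressive/unstrained"}; distances above the maximal calibrated
#' extension are an error.
#'
#' @param curve a \linkS4class{RulerCurve}
#' @param dObs observed Calpha-Calpha distance, Angstrom
#' @return data.frame(force, se, flag) with one row per observation
#' @export
inferForce <- function(curve, dObs) {
  stopifnot(is(curve, "RulerCurve"))
  f <- .rulerFun(curve)
  seFun <- stats::approxfun(curve@forces, curve@seD, rule = 2)
  lo <- min(curve@forces); hi <- max(curve@forces)
  dmin <- curve@meanD[1]; dmax <- curve@meanD[length(curve@meanD)]
  out <- lapply(dObs, function(d) {
    if (!is.finite(d)) stop("observed distance must be finite")
    if (d > dmax)
      stop(sprintf("distance %.3f A exceeds the maximal calibrated extension %.3f A",
                   d, dmax))
    if (d <= dmin)
      return(data.frame(force = 0, se = NA_real_,
                        flag = "compressive/unstrained",
                        stringsAsFactors = FALSE))
    root <- stats::uniroot(function(x) f(x) - d, lower = lo, upper = hi,
                           tol = 0.05)$root
    root <- round(root / 0.1) * 0.1     # report to 0.1 pN
    slope <- f(root, deriv = 1)
    data.frame(force = root,
               se = if (slope > 0) seFun(root) / slope else NA_real_,
               flag = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bell-model rate enhancement under force
#'
#' Phenomenological mechanochemical rate law: the rate of a
#' force-accelerated reaction grows exponentially with the applied force,
#' \eqn{k(F)/k_0 = \exp(F \Delta x / k_B T)}, with \eqn{\Delta x} the length
#' parameter (distance to the transition state along the pulling
#' coordinate).
#'
#' @param force pN, non-negative
#' @param deltaX length parameter, Angstrom, positive
#' @param temperature K
#' @param k0 reference zero-force rate (default 1: return the enhancement
#'   ratio)
#' @return k(F), same units as k0
#' @examples
#' rateEnhancement(100, deltaX = 0.41)  # severalfold at ~0.1 nN
#' @export
rateEnhancement <- function(force, deltaX, temperature = 300, k0 = 1) {
  if (any(force < 0)) stop("force must be non-negative")
  if (deltaX <= 0) stop("deltaX must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  k0 * exp(force * deltaX * .PNA / (.KB * temperature))
}

#' Serialize / restore a ruler curve as JSON
#'
#' @param curve a \linkS4class{RulerCurve}
#' @param path JSON file
#' @return \code{writeRuler}: path invisibly; \code{readRuler}: the curve
#' @export
writeRuler <- function(curve, path) {
  stopifnot(is(curve, "RulerCurve"))
  jsonlite::write_json(list(model = curve@model, forces = curve@forces,
                            mean_d = curve@meanD, se_d = curve@seD,
                            adjusted = curve@adjusted),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeRuler
#' @export
readRuler <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RulerCurve", model = x$model, forces = as.numeric(x$forces),
      meanD = as.numeric(x$mean_d), seD = as.numeric(x$se_d),
      adjusted = isTRUE(x$adjusted))
}
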