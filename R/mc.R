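# Constant-force (isotensional) sampling over the rotatable dihedrals.
# The ensemble energy is U(phi) - F * R(phi), with U the sum of three-term
# Fourier torsion potentials and R the distance between the pulled atoms;
# 1 pN * Angstrom = 0.06022 kJ/mol, kB = 0.0083145 kJ/(mol K).

.KB <- 0.0083145
.PNA <- 0.06022

#' Total isotensional energy of a conformation
#'
#' Torsional Fourier energy \eqn{\sum_k \sum_n \frac{1}{2} V_n [1 +
#' \cos(n\phi_k - \gamma_n)]} minus the mechanical work term
#' \eqn{F \cdot R(\phi)} (pN x Angstrom converted to kJ/mol).
#'
#' @param model a \linkS4class{TorsionalModel}
#' @param conf dihedral vector, degrees
#' @param force applied force, pN
#' @return energy in kJ/mol
#' @export
totalEnergy <- function(model, conf, force = 0) {
  stopifnot(is(model, "TorsionalModel"))
  if (length(conf) != nrow(model@torsions))
    stop("conformation length does not match the model's dihedral count")
  out <- .energyBatch(.modelToCpp(model), matrix(as.numeric(conf), nrow = 1),
                      as.numeric(force))
  out$energy[1]
}

#' Constant-force Metropolis Monte-Carlo sampling
#'
#' Samples the isotensional Boltzmann distribution of a torsional model with
#' single-dihedral Gaussian proposals (wrapped periodically) and Metropolis
#' acceptance. Deterministic given \code{seed}.
#'
#' @param model a \linkS4class{TorsionalModel}
#' @param force applied force, pN
#' @param temperature K
#' @param nSteps total MC steps
#' @param seed RNG seed
#' @param stepWidth proposal standard deviation, degrees, in (0, 180]
#' @param nBurnin steps discarded before recording (default 10\% of nSteps)
#' @param thinning record every \code{thinning}-th step
#' @param init optional starting conformation (degrees); default all-180
#' @return a \linkS4class{ForceClampEnsemble}
#' @examples
#' ens <- metropolisSample(builtinModel("DEDS"), force = 300,
#'                         nSteps = 2e4, seed = 1)
#' mean(ensembleSamples(ens)$R)
#' @export
metropolisSample <- function(model, force, temperature = 300,
                             nSteps = 2e6, seed = 1, stepWidth = 30,
                             nBurnin = floor(nSteps / 10), thinning = 10L,
                             init = NULL) {
  stopifnot(is(model, "TorsionalModel"))
  if (force < 0) stop("force must be non-negative")
  k <- nrow(model@torsions)
  if (is.null(init)) init <- rep(180, k)
  if (length(init) != k) stop("init conformation has wrong length")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  res <- .mcRun(.modelToCpp(model), as.numeric(force), as.numeric(temperature),
                as.numeric(nSteps), as.numeric(nBurnin), as.integer(thinning),
                as.numeric(stepWidth), as.numeric(init))
  dih <- res$dihedrals
  colnames(dih) <- model@torsions$label
  new("ForceClampEnsemble", model = model@name, force = as.numeric(force),
      temperature = as.numeric(temperature), dihedrals = dih,
      R = res$R, dCalpha = res$d_calpha, energy = res$energy,
      seed = as.integer(seed), nSteps = as.numeric(nSteps),
      nBurnin = as.numeric(nBurnin), thinning = as.integer(thinning),
      acceptRate = res$accept_rate)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Exact Boltzmann expectations by grid quadrature
#'
#' Brute-force reference for models with at most three rotatable dihedrals:
#' trapezoidal (periodic midpoint) sums of \eqn{\exp(-E/k_B T)} over a
#' regular grid of the dihedral torus. Serves as the independent oracle for
#' the Metropolis sampler.
#'
#' @param model a \linkS4class{TorsionalModel} with <= 3 rotatable dihedrals
#' @param force pN
#' @param temperature K
#' @param gridPoints grid points per dihedral (midpoints of equal bins)
#' @return list with \code{mean_R}, \code{mean_d_calpha}, \code{p_joint}
#'   (named numeric: closed/closed, open/closed, open/open probabilities of
#'   the chi1/chi2 states), \code{marginals} (matrix of per-dihedral
#'   densities over the grid), \code{grid} (midpoint angles, degrees)
#' @export
quadratureReference <- function(model, force, temperature = 300,
                                gridPoints = 72) {
  stopifnot(is(model, "TorsionalModel"))
  k <- nrow(model@torsions)
  if (k > 3)
    stop("quadrature oracle is restricted to models with <= 3 dihedrals ",
         "(grid blow-up); '", model@name, "' has ", k)
  mid <- (seq_len(gridPoints) - 0.5) * 360 / gridPoints
  grids <- rep(list(mid), k)
  confs <- as.matrix(expand.grid(grids))
  out <- .energyBatch(.modelToCpp(model), confs, as.numeric(force))
  e <- out$energy
  w <- exp(-(e - min(e)) / (.KB * temperature))   # max-shift underflow guard
  Z <- sum(w)
  if (!is.finite(Z) || Z <= 0) stop("quadrature normalization failed")
  w <- w / Z
  ci <- chiIndices(model)
  closed1 <- isClosed(confs[, ci$chi1])
  closed2 <- isClosed(confs[, ci$chi2])
  p_cc <- sum(w[closed1 & closed2])
  p_oo <- sum(w[!closed1 & !closed2])
  # expand.grid varies the first factor fastest: reshape to a k-dim array
  # and marginalize by dimension sums
  wa <- array(w, dim = rep(gridPoints, k))
  marg <- vapply(seq_len(k), function(j)
    as.numeric(apply(wa, j, sum)), numeric(gridPoints))
  colnames(marg) <- model@torsions$label
  list(mean_R = sum(w * out$R),
       mean_d_calpha = sum(w * out$d_calpha),
       p_joint = c("closed/closed" = p_cc,
                   "open/closed" = 1 - p_cc - p_oo,
                   "open/open" = p_oo),
       marginals = marg, grid = mid)
}
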