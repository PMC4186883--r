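# Shared fixtures: builtin models are cheap to construct, so each helper
# returns a fresh object.

deds <- function() builtinModel("DEDS")

# same topology, all torsional potentials zeroed (flat energy surface)
zeroPotential <- function(model) {
  model@torsions[, c("V1", "V2", "V3")] <- 0
  model
}

# random conformation matrix for property tests
randomConfs <- function(n, k, seed = 42) {
  set.seed(seed)
  matrix(runif(n * k, 0, 360), nrow = n)
}

# random rigid-body transform applied to a coordinate matrix
rigidTransform <- function(xyz, seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]      # proper rotation
  shift <- rnorm(3, sd = 10)
  sweep(xyz %*% Q, 2, -shift)
}
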