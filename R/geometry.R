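# Geometric primitives shared by the sampler, the survey stage and the
# synthetic-structure writer. All dihedrals follow the IUPAC sign convention
# (cis = 0, positive clockwise looking from atom 2 towards atom 3) and are
# reported wrapped to [0, 360) so the closed state is the single interval
# [130, 230] centred on 180.

#' Wrap an angle into [0, 360)
#'
#' @param angle angle(s) in degrees
#' @return the equivalent angle(s) in [0, 360)
#' @examples
#' wrapAngle(c(-170, 540))  # 190, 180
#' @export
wrapAngle <- function(angle) {
  if (!all(is.finite(angle))) stop("angle must be finite")
  angle %% 360
}

#' Wrap an angle into (-180, 180]
#'
#' Interoperability helper for tools that report signed dihedrals.
#'
#' @param angle angle(s) in degrees
#' @return equivalent angle(s) in (-180, 180]
#' @export
wrapTo180 <- function(angle) {
  a <- wrapAngle(angle)
  ifelse(a > 180, a - 360, a)
}

#' Dihedral angle of four points
#'
#' IUPAC convention: cis/eclipsed is 0 degrees, the sign is positive for a
#' clockwise rotation of p4 relative to p1 when viewed from p2 towards p3;
#' the result is wrapped to [0, 360).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom
#' @return dihedral in degrees, in [0, 360)
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 * sqrt(sum(b1^2)) * sqrt(sum(b2^2)))
    stop("degenerate geometry: points p1-p2-p3 are collinear or coincident")
  if (sqrt(sum(n2^2)) < 1e-10 * sqrt(sum(b2^2)) * sqrt(sum(b3^2)))
    stop("degenerate geometry: points p2-p3-p4 are collinear or coincident")
  b2h <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2h)
  wrapAngle(atan2(y, x) * 180 / pi)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build Cartesian coordinates from a torsional model and a conformation
#'
#' Places atoms sequentially from internal coordinates (NeRF placement:
#' first atom at the origin, second along +x, third in the xy-plane with
#' positive y). Recomputing any rotatable dihedral from the returned
#' coordinates reproduces the input conformation.
#'
#' @param model a \linkS4class{TorsionalModel}
#' @param conf numeric vector of rotatable-dihedral values in degrees, one
#'   per row of \code{modelTorsions(model)}
#' @return numeric matrix (atoms x 3), Angstrom, with atom names as rownames
#' @export
buildCartesian <- function(model, conf) {
  stopifnot(is(model, "TorsionalModel"))
  if (length(conf) != nrow(model@torsions))
    stop(sprintf("conformation has %d dihedrals; model '%s' declares %d",
                 length(conf), model@name, nrow(model@torsions)))
  if (!all(is.finite(conf))) stop("conformation must be finite")
  xyz <- .nerfBuild(.modelToCpp(model), as.numeric(conf))
  rownames(xyz) <- model@atoms$name
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Distance between two atoms of a structure
#'
#' @param xyz coordinate matrix (atoms x 3) as returned by
#'   \code{\link{buildCartesian}}
#' @param i,j atom indices
#' @return Euclidean distance in Angstrom
#' @export
atomDistance <- function(xyz, i, j) {
  n <- nrow(xyz)
  if (any(c(i, j) < 1) || any(c(i, j) > n))
    stop(sprintf("atom index out of range 1..%d", n))
  sqrt(sum((xyz[i, ] - xyz[j, ])^2))
}

# Pack a TorsionalModel into the plain list the C++ kernel expects.
# Cached per model object in an environment keyed by a content digest would
# be overkill at these sizes; packing is microseconds.
.modelToCpp <- function(model) {
  a <- model@atoms
  refs <- as.matrix(a[, c("ref1", "ref2", "ref3")])
  refs[is.na(refs)] <- 0L
  storage.mode(refs) <- "integer"
  refs <- refs - 1L                    # 0-based for C++
  didx <- ifelse(is.na(a$dih_ref), -1L, as.integer(a$dih_ref) - 1L)
  dfix <- ifelse(is.na(a$dih_fixed), 0, a$dih_fixed) * pi / 180
  tt <- model@torsions
  list(refs = refs,
       bond_length = as.numeric(ifelse(is.na(a$bond_length), 0, a$bond_length)),
       bond_angle_rad = as.numeric(ifelse(is.na(a$bond_angle), 0,
                                          a$bond_angle)) * pi / 180,
       dih_idx0 = as.integer(didx),
       dih_fixed_rad = as.numeric(dfix),
       fourier_v = as.matrix(tt[, c("V1", "V2", "V3")]),
       fourier_gamma_rad = as.matrix(tt[, c("g1", "g2", "g3")]) * pi / 180,
       pull_pair0 = as.integer(model@pullPair - 1L),
       calpha_pair0 = as.integer(model@calphaPair - 1L))
}
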