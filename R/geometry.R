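## Rigid-body geometry: Kabsch superposition, RMSD with per-residue
## deviations, and relative domain rotation angles.

#' Build a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0))
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))

#' Rotation about an axis
#'
#' Axis-angle rotation (Rodrigues), convenient for constructing known
#' transforms in tests and synthetic fixtures.
#'
#' @param axis length-3 axis (normalized internally).
#' @param angleDeg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply, compose and invert rigid transforms
#'
#' `applyTransform` maps points (n x 3 matrix, atom data.frame with x/y/z, or
#' a [PDBStructure-class]) through `x -> R x + t`.
#'
#' @param x points, atom table or structure.
#' @param transform a [RigidTransform-class].
#' @return object of the same kind as `x`.
#' @export
applyTransform <- function(x, transform) {
  R <- transform@rotation; tv <- transform@translation
  if (is(x, "PDBStructure")) {
    a <- x@atoms
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + tv[1]; a$y <- xyz[, 2] + tv[2]; a$z <- xyz[, 3] + tv[3]
    x@atoms <- a
    return(x)
  }
  if (is.data.frame(x)) {
    xyz <- as.matrix(x[, c("x", "y", "z")]) %*% t(R)
    x$x <- xyz[, 1] + tv[1]; x$y <- xyz[, 2] + tv[2]; x$z <- xyz[, 3] + tv[3]
    return(x)
  }
  sweep(x %*% t(R), 2, -tv)
}

#' @rdname applyTransform
#' @param a,b transforms; the composition applies `b` first, then `a`.
#' @export
composeTransforms <- function(a, b)
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)

#' @rdname applyTransform
#' @export
invertTransform <- function(transform)
  rigidTransform(t(transform@rotation),
                 as.numeric(-t(transform@rotation) %*% transform@translation))

#' Rotation angle of a transform
#'
#' `theta = arccos((trace(R) - 1)/2)`, in `[0, 180]` degrees.
#'
#' @param transform a [RigidTransform-class] (or 3x3 rotation matrix).
#' @return angle in degrees.
#' @export
rotationAngle <- function(transform) {
  R <- if (is(transform, "RigidTransform")) transform@rotation else transform
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Relative rotation angle between two transforms
#'
#' The angle of `R_B R_A^-1`: how much transform B rotates relative to
#' transform A. Invariant to a common change of reference frame. Used for
#' domain-rotation comparisons (e.g. how far the second EC1 protomer of a
#' strand-swap dimer rotates between an antibody-bound and an unbound
#' structure, after both are superposed on the first protomer).
#'
#' @param transformA,transformB [RigidTransform-class] objects.
#' @return angle in degrees, in `[0, 180]`.
#' @export
relativeRotationAngle <- function(transformA, transformB) {
  validObject(transformA); validObject(transformB)
  rotationAngle(transformB@rotation %*% t(transformA@rotation))
}

xyzOf <- function(x) {
  if (is(x, "PDBStructure")) return(coords(x))
  if (is.data.frame(x)) return(as.matrix(x[, c("x", "y", "z")]))
  as.matrix(x)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' correspondence-ordered point sets (SVD solution with reflection
#' correction), and reports the RMSD after fitting. When the mobile atoms
#' carry residue identity (a resolved-selection data.frame), per-residue mean
#' deviations are included.
#'
#' @param mobile,reference equal-length point sets: n x 3 matrices or atom
#'   data.frames (paired row-by-row), n >= 3 and non-degenerate.
#' @return a [SuperpositionResult-class]; the transform maps `mobile` onto
#'   `reference`.
#' @export
kabschSuperpose <- function(mobile, reference) {
  P <- xyzOf(mobile); Q <- xyzOf(reference)
  if (nrow(P) != nrow(Q)) stop("point sets must have equal length")
  if (nrow(P) < 3) stop("superposition is ill-posed for fewer than 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))         # H = P0^T Q0 ; R = V diag(1,1,d) U^T
  if (s$d[2] < 1e-10 * max(s$d[1], 1))
    stop("superposition is ill-posed: degenerate (collinear) geometry")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  fitted <- sweep(P %*% t(R), 2, -tr)
  dev <- sqrt(rowSums((fitted - Q)^2))
  perRes <- data.frame(chain = character(), resno = integer(),
                       deviation = numeric())
  if (is.data.frame(mobile) && all(c("chain", "resno") %in% names(mobile))) {
    key <- paste(mobile$chain, mobile$resno)
    agg <- tapply(dev, factor(key, levels = unique(key)), mean)
    first <- !duplicated(key)
    perRes <- data.frame(chain = mobile$chain[first],
                         resno = mobile$resno[first],
                         deviation = as.numeric(agg))
  }
  new("SuperpositionResult",
      transform = rigidTransform(R, tr),
      rmsd = sqrt(mean(dev^2)),
      perResidue = perRes, nAtoms = nrow(P))
}

pairSelections <- function(atomsA, atomsB) {
  # pair by (chain, author residue number, atom name); residues/atoms absent
  # from either side are dropped pairwise
  keyA <- paste(atomsA$chain, atomsA$resno, atomsA$insert, atomsA$elety)
  keyB <- paste(atomsB$chain, atomsB$resno, atomsB$insert, atomsB$elety)
  common <- intersect(keyA, keyB)
  list(a = atomsA[match(common, keyA), ], b = atomsB[match(common, keyB), ])
}

#' RMSD between two structures over a selection
#'
#' Resolves the selection in both structures, pairs atoms by (chain, author
#' residue number, atom name) dropping unpaired residues, optionally
#' superposes (Kabsch), and reports the scalar RMSD plus per-residue mean
#' deviations. The per-residue mean +/- SD (via [deviationSummary()]) is the
#' "x +/- y Angstrom" convention used when quoting main-chain RMSDs over a
#' residue window.
#'
#' @param structA,structB [PDBStructure-class] objects.
#' @param selection an [AtomSelection-class] or selection string; default
#'   main-chain atoms of all shared chains.
#' @param selectionB optional distinct selection for `structB` (paired to
#'   `selection` row-by-row after resolution; lengths must then match).
#' @param fit superpose before measuring (default TRUE). With `fit = FALSE`
#'   deviations are measured in the original frames.
#' @return a [SuperpositionResult-class].
#' @export
rmsdBetween <- function(structA, structB, selection = mainChainSelection(),
                        selectionB = NULL, fit = TRUE) {
  aA <- resolveSelection(structA, selection)
  aB <- resolveSelection(structB, if (is.null(selectionB)) selection else selectionB)
  if (is.null(selectionB)) {
    pr <- pairSelections(aA, aB)
    aA <- pr$a; aB <- pr$b
  } else if (nrow(aA) != nrow(aB)) {
    stop("distinct selections must resolve to equal atom counts")
  }
  nres <- length(unique(paste(aA$chain, aA$resno)))
  if (nres < 3) stop("fewer than 3 paired residues")
  if (fit) return(kabschSuperpose(aA, aB))
  dev <- sqrt(rowSums((xyzOf(aA) - xyzOf(aB))^2))
  key <- paste(aA$chain, aA$resno)
  agg <- tapply(dev, factor(key, levels = unique(key)), mean)
  first <- !duplicated(key)
  new("SuperpositionResult",
      transform = rigidTransform(),
      rmsd = sqrt(mean(dev^2)),
      perResidue = data.frame(chain = aA$chain[first], resno = aA$resno[first],
                              deviation = as.numeric(agg)),
      nAtoms = nrow(aA))
}

#' Domain rotation between two structures
#'
#' Frame-based domain rotation: both structures are superposed on a common
#' reference domain (e.g. chain A's EC1), then each structure's second
#' domain (e.g. chain B's EC1) is fitted to that of the first, and the angle
#' of the residual rotation is reported. This measures how much the second
#' domain reorients relative to the first between the two structures.
#'
#' @param structA,structB [PDBStructure-class] objects.
#' @param domainRef selection for the common reference domain.
#' @param domainMoving selection for the moving domain.
#' @return list with `angle` (degrees), the two fit RMSDs, and the residual
#'   [RigidTransform-class].
#' @export
domainRotation <- function(structA, structB, domainRef, domainMoving) {
  refFit <- rmsdBetween(structB, structA, domainRef)
  alignedB <- applyTransform(structB, refFit@transform)
  movA <- resolveSelection(structA, domainMoving)
  movB <- resolveSelection(alignedB, domainMoving)
  pr <- pairSelections(movA, movB)
  fit <- kabschSuperpose(pr$b, pr$a)   # transform carrying B's domain onto A's
  list(angle = rotationAngle(fit@transform),
       referenceFitRmsd = refFit@rmsd,
       movingFitRmsd = fit@rmsd,
       residualTransform = fit@transform)
}
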