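## Steric scoring: van der Waals overlap volume on a deterministic grid,
## signed clearance, clash-pair listing, and sphere-point SASA/BSA.

bodyAtoms <- function(body) {
  a <- if (is(body, "PDBStructure")) atoms(body) else as.data.frame(body)
  if (nrow(a) == 0) stop("empty body")
  if (is.null(a$radius)) stop("body has no vdW radii assigned")
  a
}

# logical occupancy of the union-of-spheres envelope on a fixed grid;
# grid cells are centres anchor + (i - 1/2) * h
gridOccupancy <- function(a, anchor, dims, h, inflate = 0) {
  occ <- array(FALSE, dim = dims)
  cx <- anchor[1] + (seq_len(dims[1]) - 0.5) * h
  cy <- anchor[2] + (seq_len(dims[2]) - 0.5) * h
  cz <- anchor[3] + (seq_len(dims[3]) - 0.5) * h
  for (i in seq_len(nrow(a))) {
    r <- a$radius[i] + inflate
    ix <- which(abs(cx - a$x[i]) <= r)
    iy <- which(abs(cy - a$y[i]) <= r)
    iz <- which(abs(cz - a$z[i]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (cx[ix] - a$x[i])^2
    dy2 <- (cy[iy] - a$y[i])^2
    dz2 <- (cz[iz] - a$z[i])^2
    # outer sums over the candidate sub-box only
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r * r
    occ[ix, iy, iz] <- as.vector(occ[ix, iy, iz]) | as.vector(sub)
  }
  occ
}

listClashPairs <- function(a, b, inflate = 0, slack = 0) {
  # pairs with centre distance < rA + rB + slack, chunked to bound memory
  pairs <- NULL
  bx <- b$x; by <- b$y; bz <- b$z; br <- b$radius + inflate
  chunk <- max(1L, floor(2e6 / max(1, nrow(b))))
  for (s in seq(1, nrow(a), by = chunk)) {
    idx <- s:min(nrow(a), s + chunk - 1)
    d <- sqrt(outer(a$x[idx], bx, "-")^2 + outer(a$y[idx], by, "-")^2 +
              outer(a$z[idx], bz, "-")^2)
    lim <- outer(a$radius[idx] + inflate, br, "+") + slack
    hit <- which(d < lim, arr.ind = TRUE)
    if (nrow(hit) > 0)
      pairs <- rbind(pairs, data.frame(
        atomA = idx[hit[, 1]], atomB = hit[, 2],
        distance = d[hit], overlap = (lim - d)[hit]))
  }
  if (is.null(pairs))
    pairs <- data.frame(atomA = integer(), atomB = integer(),
                        distance = numeric(), overlap = numeric())
  lab <- function(a, i) sprintf("%s:%d:%s", a$chain[i], a$resno[i], a$elety[i])
  if (nrow(pairs) > 0 && !is.null(a$chain) && !is.null(b$chain)) {
    pairs$labelA <- lab(a, pairs$atomA)
    pairs$labelB <- lab(b, pairs$atomB)
  }
  pairs[order(pairs$distance), , drop = FALSE]
}

#' Van der Waals overlap volume between two bodies
#'
#' The steric-compatibility score for hypothetical assemblies: the volume of
#' the intersection of the two bodies' union-of-spheres (vdW) envelopes,
#' measured by counting grid cells inside both envelopes. The grid is
#' deterministic, anchored at the corner of the intersection bounding box —
#' no randomness, so reported volumes are bit-reproducible at a given
#' spacing. Atom pairs whose centre distance is below the sum of radii are
#' listed as clash pairs.
#'
#' @param bodyA,bodyB atom tables (resolved selections) or
#'   [PDBStructure-class] objects with radii assigned.
#' @param gridSpacing grid cell edge in Angstrom, in (0.1, 1]; default 0.5.
#' @param inflate add this much (Angstrom) to every radius before measuring
#'   (used by [signedClearance()]).
#' @param clashSlack extra slack (Angstrom) on the centre-distance clash
#'   criterion for pair listing; default 0.
#' @return an [OverlapResult-class].
#' @export
overlapVolume <- function(bodyA, bodyB, gridSpacing = 0.5, inflate = 0,
                          clashSlack = 0) {
  if (gridSpacing <= 0.1 || gridSpacing > 1)
    stop("gridSpacing must be in (0.1, 1] Angstrom")
  a <- bodyAtoms(bodyA); b <- bodyAtoms(bodyB)
  ra <- max(a$radius) + inflate; rb <- max(b$radius) + inflate
  lo <- pmax(c(min(a$x) - ra, min(a$y) - ra, min(a$z) - ra),
             c(min(b$x) - rb, min(b$y) - rb, min(b$z) - rb))
  hi <- pmin(c(max(a$x) + ra, max(a$y) + ra, max(a$z) + ra),
             c(max(b$x) + rb, max(b$y) + rb, max(b$z) + rb))
  pairs <- listClashPairs(a, b, inflate = inflate, slack = clashSlack)
  if (any(hi <= lo))
    return(new("OverlapResult", volume = 0, clashPairs = pairs,
               gridSpacing = gridSpacing))
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / gridSpacing)))
  occA <- gridOccupancy(a, lo, dims, gridSpacing, inflate)
  occB <- gridOccupancy(b, lo, dims, gridSpacing, inflate)
  vol <- sum(occA & occB) * gridSpacing^3
  new("OverlapResult", volume = vol, clashPairs = pairs,
      gridSpacing = gridSpacing)
}

#' Signed steric clearance between two bodies
#'
#' A single signed score for "how badly do these bodies clash, or how close
#' are they to clashing": positive scores equal the vdW overlap volume
#' (clash); when the raw envelopes are disjoint, the score is minus the
#' overlap volume obtained after inflating every radius by a probe (default
#' 1.4 Angstrom, a water radius), i.e. a negative proximity margin. When
#' even the inflated envelopes are disjoint the score is 0 and the result is
#' flagged far-apart. The score is monotone in separation for two-sphere
#' systems. The negative branch is this package's explicit convention for
#' reporting near-miss margins; surface-based tools print small negative
#' "overlaps" for such geometries without documenting their meaning.
#'
#' @inheritParams overlapVolume
#' @param probe radius inflation (Angstrom) used for the negative branch.
#' @return an [OverlapResult-class] with `signedScore` set (and `farApart`
#'   when applicable); `volume` holds the raw overlap.
#' @export
signedClearance <- function(bodyA, bodyB, gridSpacing = 0.5, probe = 1.4) {
  raw <- overlapVolume(bodyA, bodyB, gridSpacing = gridSpacing)
  if (raw@volume > 0) {
    raw@signedScore <- raw@volume
    return(raw)
  }
  inflated <- overlapVolume(bodyA, bodyB, gridSpacing = gridSpacing,
                            inflate = probe)
  raw@signedScore <- -inflated@volume
  raw@farApart <- inflated@volume == 0
  raw
}

# deterministic Fibonacci-spiral points on the unit sphere (no RNG)
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA from the fraction of deterministic spiral test points on
#' each atom's probe-inflated sphere that are not buried inside any
#' neighbouring atom's probe-inflated sphere. Bit-reproducible: the point
#' set is a fixed Fibonacci spiral, not random.
#'
#' @param body atom table or [PDBStructure-class] with radii assigned.
#' @param probeRadius probe radius in Angstrom (default 1.4).
#' @param nPoints test points per atom (>= 100; default 960).
#' @return a [SasaResult-class].
#' @export
sasa <- function(body, probeRadius = 1.4, nPoints = 960L) {
  if (nPoints < 100) stop("nPoints must be >= 100")
  a <- bodyAtoms(body)
  n <- nrow(a)
  pts <- spherePoints(nPoints)
  R <- a$radius + probeRadius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  per <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    if (length(nb) == 0) {
      per[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
            (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj >= R[j]^2
    }
    per[i] <- 4 * pi * R[i]^2 * sum(free) / nPoints
  }
  perRes <- data.frame(chain = character(), resno = integer(), sasa = numeric())
  if (!is.null(a$chain) && !is.null(a$resno)) {
    key <- paste(a$chain, a$resno)
    agg <- tapply(per, factor(key, levels = unique(key)), sum)
    first <- !duplicated(key)
    perRes <- data.frame(chain = a$chain[first], resno = a$resno[first],
                         sasa = as.numeric(agg))
  }
  new("SasaResult", total = sum(per), perAtom = per, perResidue = perRes,
      probeRadius = probeRadius, nPoints = as.integer(nPoints))
}

#' Buried surface area of an interface
#'
#' `BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together)`: the
#' surface area occluded by forming the interface, the standard measure of
#' interface size. Symmetric in its arguments and non-negative up to
#' point-sampling noise.
#'
#' @param complex a [PDBStructure-class] containing both parts.
#' @param partA,partB disjoint [AtomSelection-class] objects (or strings).
#' @inheritParams sasa
#' @return numeric BSA in square Angstrom, with attribute `"components"`
#'   (the three SASA totals).
#' @export
buriedSurfaceArea <- function(complex, partA, partB, probeRadius = 1.4,
                              nPoints = 960L) {
  aA <- resolveSelection(complex, partA)
  aB <- resolveSelection(complex, partB)
  keyA <- paste(aA$chain, aA$resno, aA$elety)
  keyB <- paste(aB$chain, aB$resno, aB$elety)
  if (length(intersect(keyA, keyB)) > 0)
    stop("partA and partB must be disjoint")
  sA <- sasa(aA, probeRadius, nPoints)@total
  sB <- sasa(aB, probeRadius, nPoints)@total
  sAB <- sasa(rbind(aA, aB), probeRadius, nPoints)@total
  bsa <- sA + sB - sAB
  attr(bsa, "components") <- c(A = sA, B = sB, AB = sAB)
  bsa
}
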