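# Independent oracles and fixture helpers shared across the suite.

# one-atom "sphere body" for analytic sterics fixtures
sphereBody <- function(x, y = 0, z = 0, r = 2, chain = "S", resno = 1L) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = "SPH", elety = "CA", eleno = 1L, element = "C",
             altloc = "", occupancy = 1, x = x, y = y, z = z, radius = r,
             het = FALSE, stringsAsFactors = FALSE)
}

# brute-force rigid superposition: numerical minimization over a quaternion
# parameterization, independent of the SVD route
quaternionSuperposeOracle <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rotOf <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) mean(rowSums((P0 %*% t(rotOf(q)) - Q0)^2))
  best <- NULL
  starts <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
                  c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1), c(1, 1, 1, 1))
  for (i in seq_len(nrow(starts))) {
    op <- stats::optim(starts[i, ], obj, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-16))
    if (is.null(best) || op$value < best$value) best <- op
  }
  sqrt(best$value)
}

# Monte-Carlo estimate of the intersection volume of two union-of-spheres
# bodies (uniform samples over the intersection bounding box)
mcOverlapVolume <- function(a, b, nSamples = 1e6, seed = 1) {
  ra <- max(a$radius); rb <- max(b$radius)
  lo <- pmax(c(min(a$x) - ra, min(a$y) - ra, min(a$z) - ra),
             c(min(b$x) - rb, min(b$y) - rb, min(b$z) - rb))
  hi <- pmin(c(max(a$x) + ra, max(a$y) + ra, max(a$z) + ra),
             c(max(b$x) + rb, max(b$y) + rb, max(b$z) + rb))
  if (any(hi <= lo)) return(0)
  pts <- withSeed(seed, matrix(stats::runif(3 * nSamples), ncol = 3))
  pts <- sweep(sweep(pts, 2, hi - lo, "*"), 2, lo, "+")
  insideUnion <- function(body) {
    inside <- rep(FALSE, nSamples)
    for (i in seq_len(nrow(body))) {
      d2 <- (pts[, 1] - body$x[i])^2 + (pts[, 2] - body$y[i])^2 +
            (pts[, 3] - body$z[i])^2
      inside <- inside | d2 <= body$radius[i]^2
    }
    inside
  }
  mean(insideUnion(a) & insideUnion(b)) * prod(hi - lo)
}

# Monte-Carlo SASA: random (not spiral) surface points, independent of the
# deterministic implementation
mcSasa <- function(a, probe = 1.4, nPoints = 1e5, seed = 1) {
  R <- a$radius + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  total <- 0
  pts <- withSeed(seed, {
    z <- stats::runif(nPoints, -1, 1)
    phi <- stats::runif(nPoints, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(r * cos(phi), r * sin(phi), z)
  })
  for (i in seq_len(nrow(a))) {
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in seq_len(nrow(a))[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= R[j]^2
    }
    total <- total + 4 * pi * R[i]^2 * mean(free)
  }
  total
}

# random rigid transform under a fixed seed
randomTransform <- function(seed) {
  withSeed(seed, {
    ax <- stats::rnorm(3)
    rigidTransform(rotationAboutAxis(ax, stats::runif(1, 5, 175)),
                   stats::rnorm(3, 0, 20))
  })
}

# minimal hand-written PDB text for parser fixtures
pdbLines <- function(records) {
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  vapply(records, function(r)
    sprintf(fmt, r$type, r$eleno, paste0(" ", r$elety), r$alt, r$resid,
            r$chain, r$resno, "", r$x, r$y, r$z, r$occ, 0, r$elesy),
    character(1))
}
atomRec <- function(eleno, elety, resid, chain, resno, x, y, z,
                    occ = 1, alt = "", elesy = substr(elety, 1, 1),
                    type = "ATOM") {
  list(type = type, eleno = eleno, elety = elety, alt = alt, resid = resid,
       chain = chain, resno = resno, x = x, y = y, z = z, occ = occ,
       elesy = elesy)
}
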