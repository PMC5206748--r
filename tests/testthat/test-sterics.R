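test_that("disjoint spheres have zero overlap and no clash pairs", {
  ov <- overlapVolume(sphereBody(0, r = 2), sphereBody(10, r = 2), 0.3)
  expect_identical(ov@volume, 0)
  expect_identical(nrow(clashPairs(ov)), 0L)
})

test_that("coincident spheres recover the analytic sphere volume within 2%", {
  ov <- overlapVolume(sphereBody(0, r = 2), sphereBody(0, r = 2), 0.3)
  expect_equal(ov@volume, 4 / 3 * pi * 8, tolerance = 0.02)
  expect_identical(nrow(clashPairs(ov)), 1L)
})

test_that("two-sphere lens matches the analytic formula and Monte Carlo within 2%", {
  a <- sphereBody(0, r = 2); b <- sphereBody(1, r = 2)
  ov <- overlapVolume(a, b, 0.3)
  expect_equal(ov@volume, sphereLensVolume(2, 1), tolerance = 0.02)
  expect_equal(ov@volume, mcOverlapVolume(a, b, 1e6, seed = 31),
               tolerance = 0.02)
})

test_that("overlap volume converges as the grid is refined", {
  tc <- makeToyComplexAndTemplate(separation = 8, antibodyType = "cluster",
                                  seed = 32, antibodyOffset = 6)
  bodies <- lapply(1:2, function(i) {
    asm <- buildAssembly(tc$complex, tc$template, "A", "B", "A")
    resolveSelection(placedCopy(asm, i), "H")
  })
  v50 <- overlapVolume(bodies[[1]], bodies[[2]], 0.5)@volume
  v25 <- overlapVolume(bodies[[1]], bodies[[2]], 0.25)@volume
  expect_gt(v25, 0)
  expect_lt(abs(v50 - v25) / v25, 0.05)
})

test_that("overlap volume is invariant under a common rigid motion", {
  a <- sphereBody(0, r = 3); b <- sphereBody(2.5, r = 3)
  v0 <- overlapVolume(a, b, 0.3)@volume
  tr <- randomTransform(33)
  v1 <- overlapVolume(applyTransform(a, tr), applyTransform(b, tr), 0.3)@volume
  expect_lt(abs(v1 - v0) / v0, 0.02)
})

test_that("volume is positive iff clash pairs exist, and grid bounds are enforced", {
  near <- overlapVolume(sphereBody(0, r = 2), sphereBody(3.5, r = 2), 0.3)
  expect_gt(near@volume, 0)
  expect_gt(nrow(clashPairs(near)), 0)
  expect_error(overlapVolume(sphereBody(0), sphereBody(1), 2), "gridSpacing")
  expect_error(overlapVolume(sphereBody(0)[0, ], sphereBody(1)), "empty body")
})

test_that("signed clearance equals overlap volume when bodies clash", {
  sc <- signedClearance(sphereBody(0, r = 2), sphereBody(1, r = 2), 0.3)
  expect_identical(sc@signedScore, sc@volume)
  expect_gt(sc@signedScore, 0)
})

test_that("signed clearance of a near miss is the negated inflated lens", {
  # 1 A gap between r = 2 spheres; probe 1.4 inflates to r' = 3.4
  sc <- signedClearance(sphereBody(0, r = 2), sphereBody(5, r = 2), 0.3,
                        probe = 1.4)
  expect_identical(sc@volume, 0)
  expect_false(sc@farApart)
  expect_equal(sc@signedScore, -sphereLensVolume(3.4, 5), tolerance = 0.02)
})

test_that("bodies separated beyond twice the probe are flagged far apart", {
  sc <- signedClearance(sphereBody(0, r = 2), sphereBody(20, r = 2), 0.3)
  expect_identical(sc@signedScore, 0)
  expect_true(sc@farApart)
})

test_that("signed clearance is monotone within each branch as spheres approach", {
  score <- function(di) signedClearance(sphereBody(0, r = 2),
                                        sphereBody(di, r = 2),
                                        0.3)@signedScore
  # clash branch: deeper interpenetration, larger positive overlap
  clash <- vapply(c(3.5, 2.5, 1.5), score, numeric(1))
  expect_true(all(clash > 0) && all(diff(clash) > 0))
  # proximity branch: approaching contact, the margin magnitude grows
  margin <- vapply(c(6.5, 5.5, 4.5), score, numeric(1))
  expect_true(all(margin < 0) && all(diff(margin) < 0))
  # and the clash branch always dominates the margin branch
  expect_gt(min(clash), max(margin))
})

test_that("single-atom SASA matches the analytic sphere within 1%", {
  s <- sasa(sphereBody(0, r = 1.7), probeRadius = 1.4, nPoints = 960)
  expect_equal(s@total, 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("two distant atoms have exactly twice the single-atom SASA", {
  one <- sasa(sphereBody(0, r = 1.7))@total
  two <- sasa(rbind(sphereBody(0, r = 1.7),
                    sphereBody(100, r = 1.7, resno = 2)))@total
  expect_equal(two, 2 * one, tolerance = 1e-9)
})

test_that("cluster SASA matches a random-point Monte Carlo oracle within 2%", {
  pts <- withSeed(34, matrix(stats::rnorm(60, 0, 2.5), ncol = 3))
  cl <- do.call(rbind, lapply(seq_len(20), function(i)
    sphereBody(pts[i, 1], pts[i, 2], pts[i, 3], r = 1.7, resno = i)))
  expect_equal(sasa(cl)@total, mcSasa(cl, nPoints = 1e5, seed = 35),
               tolerance = 0.02)
})

test_that("SASA totals equal the per-atom sum and respect validity", {
  st <- structureFromAtoms(makeToyChain(8))
  s <- sasa(st)
  expect_equal(s@total, sum(s@perAtom), tolerance = 1e-9)
  expect_true(all(s@perAtom >= 0))
  expect_identical(nrow(s@perResidue), 8L)
})

test_that("BSA of parts 100 Angstrom apart is zero within sampling tolerance", {
  a <- makeToyChain(6, chain = "A")
  b <- makeToyChain(6, chain = "B")
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] + 100
  st <- structureFromAtoms(rbind(a, b))
  expect_lt(abs(buriedSurfaceArea(st, "A", "B")), 1e-6)
})

test_that("two-touching-atom BSA matches the analytic two-sphere value", {
  # spheres r+probe = 3.1, centres 3 A apart: each cap height h = R - d/2
  st <- structureFromAtoms(rbind(sphereBody(0, r = 1.7, chain = "A"),
                                 sphereBody(3, r = 1.7, chain = "B")))
  R <- 1.7 + 1.4; d <- 3
  analyticBuried <- 2 * (2 * pi * R * (R - d / 2))   # two spherical caps
  bsa <- buriedSurfaceArea(st, "A", "B")
  expect_equal(as.numeric(bsa), analyticBuried, tolerance = 0.02)
})

test_that("BSA is symmetric and non-negative on a toy dimer", {
  tc <- makeToyComplexAndTemplate(separation = 8, antibodyType = "cluster",
                                  seed = 36)
  st <- tc$template
  ab <- buriedSurfaceArea(st, "A", "B")
  ba <- buriedSurfaceArea(st, "B", "A")
  expect_equal(as.numeric(ab), as.numeric(ba), tolerance = 1e-9)
  expect_gte(as.numeric(ab), -1e-6)
  expect_error(buriedSurfaceArea(st, "A", "A"), "disjoint")
})
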