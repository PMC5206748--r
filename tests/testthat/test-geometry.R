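test_that("identical point sets superpose with identity rotation and zero RMSD", {
  P <- withSeed(1, matrix(stats::rnorm(60), ncol = 3))
  fit <- kabschSuperpose(P, P)
  expect_lt(fit@rmsd, 1e-9)
  expect_lt(max(abs(rotation(fit@transform) - diag(3))), 1e-9)
})

test_that("a planted rotation + translation is recovered exactly", {
  P <- withSeed(2, matrix(stats::rnorm(150), ncol = 3))
  planted <- rigidTransform(rotationAboutAxis(c(1, 2, -1), 37), c(4, -7, 2))
  fit <- kabschSuperpose(P, applyTransform(P, planted))
  expect_lt(fit@rmsd, 1e-9)
  comp <- composeTransforms(invertTransform(planted), fit@transform)
  expect_lt(rotationAngle(comp), 1e-6)
  expect_lt(max(abs(translation(comp))), 1e-6)
})

test_that("Kabsch RMSD matches a quaternion-search oracle under noise", {
  P <- withSeed(3, matrix(stats::rnorm(150), ncol = 3))
  Q <- applyTransform(P, randomTransform(4)) +
    withSeed(5, matrix(stats::rnorm(150, 0, 0.1), ncol = 3))
  expect_equal(kabschSuperpose(P, Q)@rmsd, quaternionSuperposeOracle(P, Q),
               tolerance = 1e-6)
})

test_that("Kabsch is optimal against 1000 random rigid placements", {
  P <- withSeed(6, matrix(stats::rnorm(90), ncol = 3))
  Q <- applyTransform(P, randomTransform(7)) +
    withSeed(8, matrix(stats::rnorm(90, 0, 0.3), ncol = 3))
  best <- kabschSuperpose(P, Q)@rmsd
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  worse <- withSeed(9, vapply(1:1000, function(i) {
    R <- rotationAboutAxis(stats::rnorm(3), stats::runif(1, 0, 360))
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }, numeric(1)))
  expect_true(all(worse >= best - 1e-12))
})

test_that("degenerate and too-small inputs are ill-posed errors", {
  expect_error(kabschSuperpose(matrix(0, 2, 3), matrix(0, 2, 3)), "fewer than 3")
  line <- cbind(1:10, 0, 0)
  expect_error(kabschSuperpose(line, line), "degenerate")
})

test_that("RMSD of a structure against itself is 0 +/- 0", {
  st <- structureFromAtoms(makeToyChain(12))
  res <- rmsdBetween(st, st)
  expect_lt(res@rmsd, 1e-9)
  ds <- deviationSummary(res)
  expect_lt(ds[["mean"]], 1e-9)
  expect_lt(ds[["sd"]], 1e-9)
})

test_that("no-fit RMSD of a 1 Angstrom translation is exactly 1", {
  st <- structureFromAtoms(makeToyChain(10))
  moved <- applyTransform(st, rigidTransform(diag(3), c(1, 0, 0)))
  expect_equal(rmsdBetween(st, moved, fit = FALSE)@rmsd, 1, tolerance = 1e-9)
  # with fitting the translation is absorbed
  expect_lt(rmsdBetween(st, moved)@rmsd, 1e-9)
})

test_that("RMSD is symmetric in its arguments", {
  st <- structureFromAtoms(makeToyChain(15))
  pert <- perturbStructure(st, 0.8, seed = 10)
  expect_equal(rmsdBetween(st, pert)@rmsd, rmsdBetween(pert, st)@rmsd,
               tolerance = 1e-9)
})

test_that("rmsd squared equals the mean of squared per-atom deviations", {
  st <- structureFromAtoms(makeToyChain(10))
  pert <- perturbStructure(st, 0.5, seed = 11)
  res <- rmsdBetween(st, pert, fit = FALSE)
  a <- resolveSelection(st, mainChainSelection())
  b <- resolveSelection(pert, mainChainSelection())
  dev2 <- rowSums((as.matrix(a[, c("x", "y", "z")]) -
                   as.matrix(b[, c("x", "y", "z")]))^2)
  expect_equal(res@rmsd^2, mean(dev2), tolerance = 1e-9)
})

test_that("residues absent from one side are dropped pairwise", {
  st <- structureFromAtoms(makeToyChain(20))
  df <- makeToyChain(20); df <- df[df$resno != 7, ]
  st2 <- structureFromAtoms(df)
  res <- rmsdBetween(st, st2)
  expect_identical(nrow(perResidueDeviation(res)), 19L)
  expect_lt(res@rmsd, 1e-9)
})

test_that("identical transforms give zero relative rotation", {
  tr <- randomTransform(12)
  expect_lt(relativeRotationAngle(tr, tr), 1e-9)
})

test_that("a constructed 10-degree offset is recovered to 1e-6", {
  trA <- randomTransform(13)
  trB <- rigidTransform(rotationAboutAxis(c(0, 1, 1), 10) %*% trA@rotation,
                        trA@translation)
  expect_equal(relativeRotationAngle(trA, trB), 10, tolerance = 1e-6)
})

test_that("relative rotation is invariant to a common frame change", {
  trA <- randomTransform(14); trB <- randomTransform(15)
  frame <- randomTransform(16)
  a2 <- composeTransforms(trA, frame)
  b2 <- composeTransforms(trB, frame)
  expect_equal(relativeRotationAngle(trA, trB),
               relativeRotationAngle(a2, b2), tolerance = 1e-9)
})

test_that("domain rotation recovers a planted hinge angle", {
  # two-domain toy: domain A fixed, domain B rotated by 8.6 degrees about an
  # axis through its centroid in the second structure
  domA <- makeToyChain(20, chain = "A")
  domB <- makeToyChain(20, chain = "B")
  domB[, c("x", "y", "z")] <- domB[, c("x", "y", "z")] + 30
  st1 <- structureFromAtoms(rbind(domA, domB))
  cB <- colMeans(as.matrix(domB[, c("x", "y", "z")]))
  R <- rotationAboutAxis(c(1, 0.5, 0.2), 8.6)
  hinge <- rigidTransform(R, as.numeric(cB - R %*% cB))
  domB2 <- applyTransform(domB, hinge)
  st2 <- structureFromAtoms(rbind(domA, domB2))
  # also move the whole second structure: the common-frame part must drop out
  st2 <- applyTransform(st2, randomTransform(17))
  rot <- domainRotation(st1, st2, mainChainSelection("A"),
                        mainChainSelection("B"))
  expect_equal(rot$angle, 8.6, tolerance = 1e-6)
  expect_lt(rot$referenceFitRmsd, 1e-9)
})

test_that("transform inversion and composition satisfy group identities", {
  tr <- randomTransform(18)
  id <- composeTransforms(tr, invertTransform(tr))
  # acos is ill-conditioned at 0, so the angle floor is ~sqrt(eps) degrees
  expect_lt(rotationAngle(id), 1e-5)
  expect_lt(max(abs(translation(id))), 1e-9)
  pts <- withSeed(19, matrix(stats::rnorm(30), ncol = 3))
  back <- applyTransform(applyTransform(pts, tr), invertTransform(tr))
  expect_lt(max(abs(back - pts)), 1e-9)
})
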