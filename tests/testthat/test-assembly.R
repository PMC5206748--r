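test_that("a template that is the antigen duplicated in place makes both copies coincide", {
  tc <- makeToyComplexAndTemplate(separation = 40, antibodyType = "cluster",
                                  seed = 21)
  antigen <- atoms(tc$complex)[atoms(tc$complex)$chain == "A", ]
  dup <- antigen; dup$chain <- "B"
  template <- structureFromAtoms(rbind(antigen, dup))
  asm <- buildAssembly(tc$complex, template, "A", "B", "A")
  d <- coords(placedCopy(asm, 1)) - coords(placedCopy(asm, 2))
  expect_lt(max(abs(d)), 1e-6)
  expect_lt(max(asm@fitRmsds), 1e-9)
})

test_that("a 200 Angstrom template separates the placed antibodies with zero contacts", {
  tc <- makeToyComplexAndTemplate(separation = 200, antibodyRadius = 8)
  asm <- buildAssembly(tc$complex, tc$template, "A", "B", "A")
  bA <- resolveSelection(placedCopy(asm, 1), "H")
  bB <- resolveSelection(placedCopy(asm, 2), "H")
  gap <- sqrt(sum((as.numeric(bA[1, c("x", "y", "z")]) -
                   as.numeric(bB[1, c("x", "y", "z")]))^2))
  expect_gte(gap, 100)
  ov <- overlapVolume(bA, bB)
  expect_identical(ov@volume, 0)
  expect_identical(nrow(clashPairs(ov)), 0L)
})

test_that("placed copies are rigid: internal distances preserved to 1e-6", {
  tc <- makeToyComplexAndTemplate(separation = 25, antibodyType = "cluster",
                                  seed = 22)
  asm <- buildAssembly(tc$complex, tc$template, "A", "B", "A")
  orig <- coords(tc$complex)
  idx <- withSeed(23, sample(nrow(orig), 30))
  for (copy in asm@placedCopies) {
    moved <- coords(copy)
    dOrig <- as.matrix(stats::dist(orig[idx, ]))
    dMoved <- as.matrix(stats::dist(moved[idx, ]))
    expect_lt(max(abs(dOrig - dMoved)), 1e-6)
  }
})

test_that("assembly construction is equivariant under rigid motion of the template", {
  tc <- makeToyComplexAndTemplate(separation = 12, antibodyRadius = 8)
  asm <- buildAssembly(tc$complex, tc$template, "A", "B", "A")
  v1 <- overlapVolume(resolveSelection(placedCopy(asm, 1), "H"),
                      resolveSelection(placedCopy(asm, 2), "H"), 0.5)@volume
  moved <- applyTransform(tc$template, randomTransform(24))
  asm2 <- buildAssembly(tc$complex, moved, "A", "B", "A")
  v2 <- overlapVolume(resolveSelection(placedCopy(asm2, 1), "H"),
                      resolveSelection(placedCopy(asm2, 2), "H"), 0.5)@volume
  # equal up to grid-discretization tolerance
  expect_lt(abs(v1 - v2) / max(v1, 1), 0.05)
})

test_that("poor antigen/protomer pairing fails; poor fit warns", {
  tc <- makeToyComplexAndTemplate()
  expect_error(buildAssembly(tc$complex, tc$template, "A:1-2", "B", "A:1-2"),
               "fewer than 3")
  # a badly distorted protomer still pairs but fits poorly -> warning
  bad <- tc$template
  a <- atoms(bad)
  mangle <- a$chain == "B"
  a$x[mangle] <- withSeed(25, a$x[mangle] + stats::rnorm(sum(mangle), 0, 8))
  a$y[mangle] <- withSeed(26, a$y[mangle] + stats::rnorm(sum(mangle), 0, 8))
  bad@atoms <- a
  expect_warning(buildAssembly(tc$complex, bad, "A", "B", "A"),
                 "exceeds")
})

test_that("serine-to-alanine truncates to CB with a bit-identical main chain", {
  st <- structureFromAtoms(makeToyChain(5, resid = "SER"))
  mu <- mutateResidue(st, "A", 3, "ALA")
  res3 <- atoms(mu)[atoms(mu)$resno == 3, ]
  expect_setequal(res3$elety, c("N", "CA", "C", "O", "CB"))
  expect_identical(unique(res3$resid), "ALA")
  keep <- atoms(st)$resno == 3 & atoms(st)$elety %in% c("N", "CA", "C", "O", "CB")
  expect_identical(coords(mu)[atoms(mu)$resno == 3, ],
                   coords(st)[keep, ])
  # other residues untouched
  expect_identical(coords(mu)[atoms(mu)$resno != 3, ],
                   coords(st)[atoms(st)$resno != 3, ])
})

test_that("serine-to-arginine builds the full idealized side chain", {
  st <- structureFromAtoms(makeToyChain(5, resid = "SER"))
  mu <- mutateResidue(st, "A", 3, "ARG")
  res3 <- atoms(mu)[atoms(mu)$resno == 3, ]
  expect_setequal(res3$elety,
                  c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ",
                    "NH1", "NH2"))
  xyz <- function(n) as.numeric(res3[res3$elety == n, c("x", "y", "z")])
  bond <- function(a, b) sqrt(sum((xyz(a) - xyz(b))^2))
  expect_equal(bond("CB", "CG"), 1.53, tolerance = 1e-6)
  expect_equal(bond("NE", "CZ"), 1.33, tolerance = 1e-6)
  # guanidinium nitrogens flank CZ symmetrically
  expect_equal(bond("CZ", "NH1"), bond("CZ", "NH2"), tolerance = 1e-6)
  # main chain bit-identical
  mc <- function(s) coords(s)[atoms(s)$resno == 3 &
                              atoms(s)$elety %in% c("N", "CA", "C", "O"), ]
  expect_identical(mc(mu), mc(st))
})

test_that("mutating both placed copies leaves main-chain RMSD at zero", {
  tc <- makeToyComplexAndTemplate(antibodyType = "cluster", seed = 27)
  # graft serines onto the antigen so the mutation machinery has a target
  cx <- tc$complex
  mu <- mutateResidue(mutateResidue(cx, "A", 5, "ARG"), "A", 20, "ARG")
  res <- rmsdBetween(cx, mu, mainChainSelection("A"))
  expect_lt(res@rmsd, 1e-9)
  a <- atoms(mu)
  expect_identical(sum(a$elety == "NH1"), 2L)
})

test_that("mutation placement is deterministic and unknown targets error", {
  st <- structureFromAtoms(makeToyChain(5, resid = "SER"))
  expect_identical(coords(mutateResidue(st, "A", 2, "TRP")),
                   coords(mutateResidue(st, "A", 2, "TRP")))
  expect_error(mutateResidue(st, "A", 2, "XXX"), "unsupported")
  expect_error(mutateResidue(st, "A", 99, "ALA"), "not found")
})
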