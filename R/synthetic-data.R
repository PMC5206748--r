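## Seeded synthetic fixtures with analytic ground truth: toy domains and
## antibody bodies, dimer templates with controlled protomer spacing,
## perturbed structures with exact planted RMSD, and ITC/SPR/epitope panels.
## Toy structures are legal PDB so the structure reader is exercised, not
## bypassed.

#' Analytic sphere-sphere lens volume
#'
#' Intersection volume of two equal spheres of radius `r` at centre distance
#' `d`: `pi (4 r + d)(2 r - d)^2 / 12` for `d < 2 r`, else 0. The analytic
#' oracle for sphere-approximable overlap fixtures.
#'
#' @param r sphere radius, Angstrom.
#' @param d centre distance, Angstrom.
#' @return volume in cubic Angstrom.
#' @export
sphereLensVolume <- function(r, d) {
  ifelse(d >= 2 * r, 0, pi * (4 * r + d) * (2 * r - d)^2 / 12)
}

#' Generate a toy protein chain
#'
#' An ideal-helix backbone trace (or a seeded globular cluster): N, CA, C, O
#' (plus CB) per residue with plausible local geometry. Deterministic for a
#' given seed; the same seed gives a bit-identical structure.
#'
#' @param nRes number of residues.
#' @param chain chain id.
#' @param shape "helix" (deterministic ideal trace) or "cluster" (seeded
#'   Gaussian blob of residues).
#' @param startResno first author residue number.
#' @param seed RNG seed (used by "cluster" only).
#' @param resid residue name for all residues.
#' @return atom data.frame consumable by [structureFromAtoms()].
#' @export
makeToyChain <- function(nRes, chain = "A", shape = c("helix", "cluster"),
                         startResno = 1L, seed = 1L, resid = "ALA") {
  shape <- match.arg(shape)
  resnos <- seq.int(startResno, length.out = nRes)
  if (shape == "helix") {
    # ideal alpha-helix CA trace: 2.3 A radius, 1.5 A rise, 100 deg/residue
    th <- (seq_len(nRes) - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(th), 2.3 * sin(th), (seq_len(nRes) - 1) * 1.5)
    u1 <- cbind(-sin(th), cos(th), 0)                       # tangential
    u2 <- cbind(-cos(th), -sin(th), 0)                      # inward radial
    n <- sweep(ca - 1.20 * u1 - 0.60 * u2, 2, c(0, 0, -0.45), "+")
    c_ <- sweep(ca + 1.25 * u1 - 0.55 * u2, 2, c(0, 0, 0.45), "+")
    o <- sweep(c_ + 0.95 * u2, 2, c(0, 0, 0.75), "+")
    cb <- sweep(ca - 1.30 * u2, 2, c(0, 0, -0.55), "+")
  } else {
    rng <- localRng(seed)
    centers <- matrix(rng$rnorm(nRes * 3, 0, 4), ncol = 3)
    ca <- centers
    n <- centers + matrix(rng$rnorm(nRes * 3, 0, 0.9), ncol = 3)
    c_ <- centers + matrix(rng$rnorm(nRes * 3, 0, 0.9), ncol = 3)
    o <- c_ + matrix(rng$rnorm(nRes * 3, 0, 0.7), ncol = 3)
    cb <- centers + matrix(rng$rnorm(nRes * 3, 0, 0.9), ncol = 3)
  }
  per <- function(xyz, name, element)
    data.frame(chain = chain, resno = resnos, resid = resid, elety = name,
               element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  df <- rbind(per(n, "N", "N"), per(ca, "CA", "C"), per(c_, "C", "C"),
              per(o, "O", "O"),
              if (resid != "GLY") per(cb, "CB", "C"))
  df <- df[order(df$resno, match(df$elety, c("N", "CA", "C", "O", "CB"))), ]
  rownames(df) <- NULL
  df
}

#' Toy antibody-antigen complex plus dimer template, with ground truth
#'
#' Emulates the template-guided assembly scenario: an "antigen" helix domain
#' (chain A) with a rigidly attached "antibody" body (chain H), plus a
#' two-protomer dimer template whose protomer spacing controls whether the
#' two placed antibody bodies clash. With `antibodyType = "sphere"` the
#' antibody is a single large sphere, so the expected overlap of the placed
#' pair has a closed form (the sphere-sphere lens), recorded in the ground
#' truth.
#'
#' @param separation distance between the two template protomers, Angstrom.
#' @param arrangement "translate" (protomer B is a translated copy; the
#'   placed antibody centres are exactly `separation` apart) or "c2"
#'   (protomer B is rotated 180 degrees about the template axis).
#' @param antigenRes residues in the antigen helix.
#' @param antibodyType "sphere" (one atom of radius `antibodyRadius`) or
#'   "cluster" (a seeded blob of ordinary atoms).
#' @param antibodyRadius sphere radius, Angstrom.
#' @param antibodyOffset displacement of the antibody body centre from the
#'   antigen centroid, Angstrom (along +x).
#' @param seed RNG seed (cluster body only).
#' @return list with `complex`, `template` ([PDBStructure-class]),
#'   `groundTruth` (list: planted protomer-B transform, antibody centre
#'   distance, analytic overlap volume where sphere-approximable, expected
#'   clash verdict, seed).
#' @export
makeToyComplexAndTemplate <- function(separation = 30,
                                      arrangement = c("translate", "c2"),
                                      antigenRes = 30,
                                      antibodyType = c("sphere", "cluster"),
                                      antibodyRadius = 8,
                                      antibodyOffset = 18, seed = 1L) {
  arrangement <- match.arg(arrangement)
  antibodyType <- match.arg(antibodyType)
  antigen <- makeToyChain(antigenRes, chain = "A", shape = "helix")
  centroid <- colMeans(as.matrix(antigen[, c("x", "y", "z")]))
  abCenter <- centroid + c(antibodyOffset, 0, 0)
  if (antibodyType == "sphere") {
    ab <- data.frame(chain = "H", resno = 1L, resid = "ABD", elety = "CA",
                     element = "C", x = abCenter[1], y = abCenter[2],
                     z = abCenter[3], radius = antibodyRadius,
                     stringsAsFactors = FALSE)
  } else {
    rng <- localRng(seed)
    nAb <- 40
    pts <- matrix(rng$rnorm(nAb * 3, 0, antibodyRadius / 2.5), ncol = 3)
    ab <- data.frame(chain = "H", resno = seq_len(nAb), resid = "ABD",
                     elety = "CA", element = "C",
                     x = abCenter[1] + pts[, 1], y = abCenter[2] + pts[, 2],
                     z = abCenter[3] + pts[, 3], stringsAsFactors = FALSE)
  }
  cols <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  complexDf <- rbind(antigen[, cols], ab[, cols])
  if (antibodyType == "sphere") complexDf$radius <- c(
    assignRadii(antigen$element, vdwRadiiTable()), antibodyRadius)
  complex <- structureFromAtoms(complexDf, entryId = "toy-complex")

  protA <- antigen
  if (arrangement == "translate") {
    plantedT <- rigidTransform(diag(3), c(separation, 0, 0))
  } else {
    # rotate 180 deg about the vertical axis through the template midpoint
    p <- centroid + c(separation / 2, 0, 0)
    R <- rotationAboutAxis(c(0, 0, 1), 180)
    plantedT <- rigidTransform(R, as.numeric(p - R %*% p))
  }
  protB <- applyTransform(protA, plantedT)
  protB$chain <- "B"
  template <- structureFromAtoms(rbind(protA, protB[, names(protA)]),
                                 entryId = "toy-template")

  abB <- applyTransform(matrix(abCenter, 1, 3), plantedT)
  dCenters <- sqrt(sum((abB - abCenter)^2))
  analytic <- if (antibodyType == "sphere")
    sphereLensVolume(antibodyRadius, dCenters) else NA_real_
  gt <- list(arrangement = arrangement, separation = separation,
             antibodyType = antibodyType, antibodyRadius = antibodyRadius,
             antibodyCentreDistance = dCenters,
             plantedRotation = plantedT@rotation,
             plantedTranslation = plantedT@translation,
             analyticOverlap = analytic,
             expectClash = if (antibodyType == "sphere")
               dCenters < 2 * antibodyRadius else NA,
             seed = seed)
  list(complex = complex, template = template, groundTruth = gt)
}

#' Perturb a structure to an exact planted RMSD
#'
#' Adds seeded Gaussian coordinate noise rescaled so that the realized
#' main-chain no-fit RMSD equals `targetRmsd` exactly (to numerical
#' precision). Side-chain atoms receive the same noise scale.
#'
#' @param structure a [PDBStructure-class].
#' @param targetRmsd desired main-chain RMSD, Angstrom (>= 0).
#' @param seed RNG seed.
#' @return perturbed [PDBStructure-class].
#' @export
perturbStructure <- function(structure, targetRmsd, seed = 1L) {
  if (targetRmsd < 0) stop("targetRmsd must be >= 0")
  if (targetRmsd == 0) return(structure)
  a <- atoms(structure)
  rng <- localRng(seed)
  noise <- matrix(rng$rnorm(nrow(a) * 3), ncol = 3)
  mc <- a$elety %in% MAIN_CHAIN_ATOMS & !a$het
  if (!any(mc)) mc <- rep(TRUE, nrow(a))
  realized <- sqrt(mean(rowSums(noise[mc, , drop = FALSE]^2)))
  noise <- noise * (targetRmsd / realized)
  a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
  structure@atoms <- a
  structure
}

#' Write / read ground truth JSON
#'
#' Ground truth is serialized alongside every generated fixture so a
#' pipeline run can be checked against what was planted.
#'
#' @param groundTruth a list (matrices allowed).
#' @param path JSON path.
#' @return `path` / the list.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  jsonlite::write_json(groundTruth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(gt$plantedRotation))
    gt$plantedRotation <- matrix(unlist(gt$plantedRotation), 3, 3, byrow = TRUE)
  gt
}

#' ITC fixture on disk
#'
#' Simulates a one-site titration and writes the CSV/YAML pair read by
#' [readItcExperiment()], plus `ground_truth.json`.
#'
#' @inheritParams simulateItc
#' @param dir output directory (created if needed).
#' @return list with `experiment`, `groundTruth`, `paths`.
#' @export
makeItcFixture <- function(dir, n = 1.5, K = 1e8, dH = -1e4,
                           layout = itcLayout(), noiseSd = 0, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exp <- simulateItc(n, K, dH, layout, noiseSd, seed)
  heatsCsv <- file.path(dir, "itc_heats.csv")
  headerYaml <- file.path(dir, "itc_header.yaml")
  utils::write.csv(data.frame(injection_volume_uL = exp@injectionVolumes * 1e6,
                              heat_ucal = exp@heats),
                   heatsCsv, row.names = FALSE)
  yaml::write_yaml(list(cell_concentration_M = exp@cellConc,
                        syringe_concentration_M = exp@syringeConc,
                        cell_volume_L = exp@cellVolume,
                        temperature_K = exp@temperature), headerYaml)
  gt <- list(model = "itc_one_site", n = n, K = K, dH = dH,
             noiseSd = noiseSd, seed = seed)
  gtPath <- file.path(dir, "ground_truth.json")
  writeGroundTruth(gt, gtPath)
  list(experiment = exp, groundTruth = gt,
       paths = c(heats = heatsCsv, header = headerYaml, groundTruth = gtPath))
}

#' SPR fixture on disk
#'
#' @inheritParams simulateSensorgram
#' @param dir output directory.
#' @return list with `experiment`, `groundTruth`, `paths`.
#' @export
makeSprFixture <- function(dir, kon = 1e6, koff = 1e-3, Rmax = 100,
                           concentrations = c(1.25, 2.5, 5, 10, 20) * 1e-9,
                           associationTime = 120, dissociationTime = 300,
                           noiseSd = 0, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exp <- simulateSensorgram(kon, koff, Rmax, concentrations, associationTime,
                            dissociationTime, dt = 1, noiseSd = noiseSd,
                            seed = seed)
  csv <- file.path(dir, "sensorgrams.csv")
  writeSprCsv(exp, csv)
  gt <- list(model = "spr_1to1", kon = kon, koff = koff, Rmax = Rmax,
             KD = koff / kon, noiseSd = noiseSd, seed = seed)
  gtPath <- file.path(dir, "ground_truth.json")
  writeGroundTruth(gt, gtPath)
  list(experiment = exp, groundTruth = gt,
       paths = c(sensorgrams = csv, groundTruth = gtPath))
}

#' Planted-epitope mutant panel
#'
#' Builds a mutant binding panel with disjoint planted epitopes: each of
#' `nAntibodies` antibodies owns `setsPerAntibody` mutant sets of 2-3
#' residue positions; binding levels are drawn at 5 +/- 3 percent of WT for
#' an antibody's own mutants (clipped at 0) and 95 +/- 5 percent otherwise.
#'
#' @param nAntibodies number of antibodies (default 3).
#' @param setsPerAntibody mutant sets per antibody (default 3; 9 sets total
#'   by default).
#' @param seed RNG seed.
#' @param dir optional directory; when given, writes `panel.csv` and
#'   `ground_truth.json`.
#' @return list with `panel` (data.frame), `groundTruth` (planted epitopes),
#'   and `paths` when written.
#' @export
makeEpitopePanel <- function(nAntibodies = 3, setsPerAntibody = 3, seed = 1L,
                             dir = NULL) {
  rng <- localRng(seed)
  abs <- paste0("ab", LETTERS[seq_len(nAntibodies)])
  nSets <- nAntibodies * setsPerAntibody
  sizes <- rng$sample(2:3, nSets, replace = TRUE)
  pool <- rng$sample(1:100, sum(sizes))          # disjoint positions
  sets <- split(pool, rep(seq_len(nSets), sizes))
  owner <- rep(seq_len(nAntibodies), each = setsPerAntibody)
  rows <- lapply(seq_len(nSets), function(i) {
    lv <- 0.95 + rng$rnorm(nAntibodies, 0, 0.05)
    lv[owner[i]] <- max(0, 0.05 + rng$rnorm(1, 0, 0.03))
    out <- data.frame(mutant_id = sprintf("mut%02d", i),
                      positions = paste(sort(sets[[i]]), collapse = ";"),
                      stringsAsFactors = FALSE)
    out[paste0("level_", abs)] <- as.list(pmax(0, lv))
    out
  })
  wt <- data.frame(mutant_id = "WT", positions = "", stringsAsFactors = FALSE)
  wt[paste0("level_", abs)] <- as.list(rep(1.0, nAntibodies))
  panel <- rbind(wt, do.call(rbind, rows))
  planted <- lapply(seq_len(nAntibodies), function(j)
    sort(unique(unlist(sets[owner == j]))))
  names(planted) <- abs
  gt <- list(model = "planted_epitopes", epitopes = planted, seed = seed)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(dir, "panel.csv")
    utils::write.csv(panel, csv, row.names = FALSE)
    gtPath <- file.path(dir, "ground_truth.json")
    writeGroundTruth(gt, gtPath)
    paths <- c(panel = csv, groundTruth = gtPath)
  }
  list(panel = panel, groundTruth = gt, paths = paths)
}
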