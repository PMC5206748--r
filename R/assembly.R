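## Hypothetical assemblies: place the antibody-antigen complex onto each
## protomer of a dimer template, and model point mutations with idealized
## rotamers for design screens.

#' Build a hypothetical dimer-plus-two-antibodies assembly
#'
#' Superposes the antigen domain of an antibody-antigen complex onto each of
#' the two protomers of a dimer template (main-chain atoms by default),
#' yielding two rigidly placed copies of the whole complex around the
#' template dimer. The template itself is never moved. The relative geometry
#' of the two placed antibody bodies is then scored by the sterics module:
#' if the dimer geometry forces the two antibodies into each other, antibody
#' binding and that dimer are sterically incompatible.
#'
#' @param complex [PDBStructure-class] of the antibody-antigen complex.
#' @param template [PDBStructure-class] of the dimer template (two protomers).
#' @param protomerA,protomerB [AtomSelection-class] (or strings) selecting
#'   each template protomer's superposition window.
#' @param antigen [AtomSelection-class] (or string) selecting the complex's
#'   antigen domain; paired to each protomer by author residue number and
#'   atom name.
#' @param sanityRmsd warn (not error) when an antigen-onto-protomer fit RMSD
#'   exceeds this bound (Angstrom).
#' @return an [AssemblyModel-class].
#' @export
buildAssembly <- function(complex, template, protomerA, protomerB, antigen,
                          sanityRmsd = 5) {
  if (is.character(antigen)) antigen <- parseSelection(antigen)
  if (is.character(protomerA)) protomerA <- parseSelection(protomerA)
  if (is.character(protomerB)) protomerB <- parseSelection(protomerB)
  antAtoms <- resolveSelection(complex, antigen)
  placeOn <- function(protSel) {
    prot <- resolveSelection(template, protSel)
    # pair antigen residues to protomer residues by residue number + atom name
    keyA <- paste(antAtoms$resno, antAtoms$insert, antAtoms$elety)
    keyP <- paste(prot$resno, prot$insert, prot$elety)
    common <- intersect(keyA, keyP)
    if (length(unique(sub(" [^ ]*$", "", common))) < 3)
      stop("antigen/protomer pairing failed: fewer than 3 shared residues")
    fit <- kabschSuperpose(antAtoms[match(common, keyA), ],
                           prot[match(common, keyP), ])
    if (fit@rmsd > sanityRmsd)
      warning(sprintf("antigen-onto-protomer fit RMSD %.2f A exceeds %.2f A",
                      fit@rmsd, sanityRmsd))
    list(copy = applyTransform(complex, fit@transform),
         transform = fit@transform, rmsd = fit@rmsd)
  }
  pa <- placeOn(protomerA)
  pb <- placeOn(protomerB)
  new("AssemblyModel", template = template,
      placedCopies = list(pa$copy, pb$copy),
      transforms = list(pa$transform, pb$transform),
      fitRmsds = c(pa$rmsd, pb$rmsd),
      antigen = antigen, protomerA = protomerA, protomerB = protomerB)
}

#' Extract one placed copy of an assembly
#'
#' @param assembly an [AssemblyModel-class].
#' @param which 1 (protomer A placement) or 2 (protomer B placement).
#' @return a [PDBStructure-class].
#' @export
placedCopy <- function(assembly, which) assembly@placedCopies[[which]]

## --- idealized side-chain construction -------------------------------------

# NERF placement: given positions a, b, c, place d with |cd| = bond,
# angle(b,c,d) = angle, torsion(a,b,c,d) = torsion (degrees)
placeAtomNerf <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180; torsion <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# side-chain topology beyond CB: atom, three reference atoms, bond length,
# bond angle, and torsion given as a chi index ("chi1".."chi4") optionally
# with a fixed offset
sideChainTopology <- function() {
  T <- function(...) {
    m <- rbind(...)
    data.frame(atom = m[, 1], r1 = m[, 2], r2 = m[, 3], r3 = m[, 4],
               bond = as.numeric(m[, 5]), angle = as.numeric(m[, 6]),
               chi = m[, 7], offset = as.numeric(m[, 8]),
               element = m[, 9], stringsAsFactors = FALSE)
  }
  list(
    ALA = NULL,
    SER = T(c("OG", "N", "CA", "CB", 1.42, 110.8, "chi1", 0, "O")),
    CYS = T(c("SG", "N", "CA", "CB", 1.81, 114.4, "chi1", 0, "S")),
    THR = T(c("OG1", "N", "CA", "CB", 1.43, 109.6, "chi1", 0, "O"),
            c("CG2", "N", "CA", "CB", 1.52, 110.5, "chi1", -120, "C")),
    VAL = T(c("CG1", "N", "CA", "CB", 1.52, 110.5, "chi1", 0, "C"),
            c("CG2", "N", "CA", "CB", 1.52, 110.5, "chi1", 122, "C")),
    LEU = T(c("CG", "N", "CA", "CB", 1.53, 116.3, "chi1", 0, "C"),
            c("CD1", "CA", "CB", "CG", 1.52, 110.7, "chi2", 0, "C"),
            c("CD2", "CA", "CB", "CG", 1.52, 110.7, "chi2", 122, "C")),
    ILE = T(c("CG1", "N", "CA", "CB", 1.53, 110.4, "chi1", 0, "C"),
            c("CG2", "N", "CA", "CB", 1.52, 110.5, "chi1", -122, "C"),
            c("CD1", "CA", "CB", "CG1", 1.52, 113.8, "chi2", 0, "C")),
    ASP = T(c("CG", "N", "CA", "CB", 1.52, 112.6, "chi1", 0, "C"),
            c("OD1", "CA", "CB", "CG", 1.25, 118.4, "chi2", 0, "O"),
            c("OD2", "CA", "CB", "CG", 1.25, 118.4, "chi2", 180, "O")),
    ASN = T(c("CG", "N", "CA", "CB", 1.52, 112.6, "chi1", 0, "C"),
            c("OD1", "CA", "CB", "CG", 1.23, 120.8, "chi2", 0, "O"),
            c("ND2", "CA", "CB", "CG", 1.33, 116.4, "chi2", 180, "N")),
    GLU = T(c("CG", "N", "CA", "CB", 1.53, 114.1, "chi1", 0, "C"),
            c("CD", "CA", "CB", "CG", 1.52, 112.6, "chi2", 0, "C"),
            c("OE1", "CB", "CG", "CD", 1.25, 118.4, "chi3", 0, "O"),
            c("OE2", "CB", "CG", "CD", 1.25, 118.4, "chi3", 180, "O")),
    GLN = T(c("CG", "N", "CA", "CB", 1.53, 114.1, "chi1", 0, "C"),
            c("CD", "CA", "CB", "CG", 1.52, 112.6, "chi2", 0, "C"),
            c("OE1", "CB", "CG", "CD", 1.23, 120.8, "chi3", 0, "O"),
            c("NE2", "CB", "CG", "CD", 1.33, 116.4, "chi3", 180, "N")),
    LYS = T(c("CG", "N", "CA", "CB", 1.53, 114.1, "chi1", 0, "C"),
            c("CD", "CA", "CB", "CG", 1.52, 111.3, "chi2", 0, "C"),
            c("CE", "CB", "CG", "CD", 1.52, 111.3, "chi3", 0, "C"),
            c("NZ", "CG", "CD", "CE", 1.49, 111.9, "chi4", 0, "N")),
    ARG = T(c("CG", "N", "CA", "CB", 1.53, 114.1, "chi1", 0, "C"),
            c("CD", "CA", "CB", "CG", 1.52, 111.3, "chi2", 0, "C"),
            c("NE", "CB", "CG", "CD", 1.46, 112.0, "chi3", 0, "N"),
            c("CZ", "CG", "CD", "NE", 1.33, 124.2, "chi4", 0, "C"),
            c("NH1", "CD", "NE", "CZ", 1.33, 120.0, "fixed", 0, "N"),
            c("NH2", "CD", "NE", "CZ", 1.33, 120.0, "fixed", 180, "N")),
    MET = T(c("CG", "N", "CA", "CB", 1.53, 114.1, "chi1", 0, "C"),
            c("SD", "CA", "CB", "CG", 1.80, 112.7, "chi2", 0, "S"),
            c("CE", "CB", "CG", "SD", 1.79, 100.8, "chi3", 0, "C")),
    PHE = T(c("CG", "N", "CA", "CB", 1.50, 113.8, "chi1", 0, "C"),
            c("CD1", "CA", "CB", "CG", 1.39, 120.8, "chi2", 0, "C"),
            c("CD2", "CA", "CB", "CG", 1.39, 120.8, "chi2", 180, "C"),
            c("CE1", "CB", "CG", "CD1", 1.39, 120.0, "fixed", 180, "C"),
            c("CE2", "CB", "CG", "CD2", 1.39, 120.0, "fixed", 180, "C"),
            c("CZ", "CG", "CD1", "CE1", 1.39, 120.0, "fixed", 0, "C")),
    TYR = T(c("CG", "N", "CA", "CB", 1.50, 113.8, "chi1", 0, "C"),
            c("CD1", "CA", "CB", "CG", 1.39, 120.8, "chi2", 0, "C"),
            c("CD2", "CA", "CB", "CG", 1.39, 120.8, "chi2", 180, "C"),
            c("CE1", "CB", "CG", "CD1", 1.39, 120.0, "fixed", 180, "C"),
            c("CE2", "CB", "CG", "CD2", 1.39, 120.0, "fixed", 180, "C"),
            c("CZ", "CG", "CD1", "CE1", 1.39, 120.0, "fixed", 0, "C"),
            c("OH", "CD1", "CE1", "CZ", 1.38, 120.0, "fixed", 180, "O")),
    HIS = T(c("CG", "N", "CA", "CB", 1.50, 113.8, "chi1", 0, "C"),
            c("ND1", "CA", "CB", "CG", 1.38, 122.7, "chi2", 0, "N"),
            c("CD2", "CA", "CB", "CG", 1.36, 131.0, "chi2", 180, "C"),
            c("CE1", "CB", "CG", "ND1", 1.32, 109.0, "fixed", 180, "C"),
            c("NE2", "CB", "CG", "CD2", 1.32, 107.0, "fixed", 180, "N")),
    TRP = T(c("CG", "N", "CA", "CB", 1.50, 113.8, "chi1", 0, "C"),
            c("CD1", "CA", "CB", "CG", 1.37, 127.0, "chi2", 0, "C"),
            c("CD2", "CA", "CB", "CG", 1.43, 126.6, "chi2", 180, "C"),
            c("NE1", "CB", "CG", "CD1", 1.38, 110.2, "fixed", 180, "N"),
            c("CE2", "CB", "CG", "CD2", 1.40, 107.2, "fixed", 180, "C"),
            c("CE3", "CB", "CG", "CD2", 1.40, 133.9, "fixed", 0, "C"),
            c("CZ2", "CG", "CD2", "CE2", 1.39, 122.4, "fixed", 180, "C"),
            c("CZ3", "CG", "CD2", "CE3", 1.39, 118.7, "fixed", 180, "C"),
            c("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, "fixed", 180, "C"))
  )
}

#' Most-common-rotamer chi angles
#'
#' Reads the shipped mini rotamer table (one most-common rotamer per residue
#' type; degrees).
#'
#' @param path optional alternative CSV with columns `resid,chi1..chi4`.
#' @return data.frame keyed by residue name.
#' @export
rotamerTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rotamers.csv", package = "xdclash",
                        mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Model a point mutation with an idealized rotamer
#'
#' Replaces the side chain of one residue with an idealized side chain of the
#' target residue type in its most common rotamer. Main-chain atoms (N, CA,
#' C, O) are untouched; an existing CB is kept and built outward from, so the
#' local frame of the mutation follows the parent structure. Placement is
#' deterministic (no refinement or clash relief): for a design screen the
#' estimate of a steric change must be reproducible, which matters more than
#' side-chain relaxation realism.
#'
#' @param structure a [PDBStructure-class].
#' @param chain chain id.
#' @param resno author residue number.
#' @param newResidue three-letter target residue name (supported: ALA, SER,
#'   CYS, THR, VAL, LEU, ILE, ASP, ASN, GLU, GLN, LYS, ARG, MET, PHE, TYR,
#'   HIS, TRP, GLY).
#' @param rotamers rotamer table from [rotamerTable()].
#' @param radii radii table from [vdwRadiiTable()].
#' @return a new [PDBStructure-class] with the mutated residue.
#' @export
mutateResidue <- function(structure, chain, resno, newResidue,
                          rotamers = rotamerTable(), radii = vdwRadiiTable()) {
  newResidue <- toupper(newResidue)
  topo <- sideChainTopology()
  if (!newResidue %in% c(names(topo), "GLY"))
    stop("unsupported target residue: ", newResidue)
  a <- atoms(structure)
  sel <- a$chain == chain & a$resno == resno & !a$het
  if (!any(sel)) stop("residue ", chain, ":", resno, " not found")
  res <- a[sel, ]
  getXyz <- function(name) {
    i <- which(res$elety == name)
    if (length(i) == 0) stop("residue ", chain, ":", resno,
                             " lacks required atom ", name)
    as.numeric(res[i[1], c("x", "y", "z")])
  }
  keep <- res$elety %in% MAIN_CHAIN_ATOMS
  if (newResidue != "GLY") {
    hasCB <- "CB" %in% res$elety
    if (hasCB) {
      keep <- keep | res$elety == "CB"
      cb <- getXyz("CB")
    } else {
      # build CB from the backbone frame (L-configuration improper)
      cb <- placeAtomNerf(getXyz("C"), getXyz("N"), getXyz("CA"),
                          1.53, 110.4, 122.5)
    }
  }
  core <- res[keep, ]
  core$resid <- newResidue
  newAtoms <- core
  if (newResidue != "GLY") {
    pos <- list(N = getXyz("N"), CA = getXyz("CA"), C = getXyz("C"), CB = cb)
    if (!"CB" %in% newAtoms$elety) {
      row <- newAtoms[newAtoms$elety == "CA", , drop = FALSE][1, ]
      row$elety <- "CB"; row$element <- "C"
      row$x <- cb[1]; row$y <- cb[2]; row$z <- cb[3]
      newAtoms <- rbind(newAtoms, row)
    }
    topo_r <- topo[[newResidue]]
    if (!is.null(topo_r)) {
      chis <- rotamers[rotamers$resid == newResidue, c("chi1", "chi2", "chi3", "chi4")]
      chis <- if (nrow(chis) == 1) as.numeric(chis) else rep(NA_real_, 4)
      for (i in seq_len(nrow(topo_r))) {
        tr <- topo_r[i, ]
        torsion <- if (tr$chi == "fixed") tr$offset
                   else chis[as.integer(sub("chi", "", tr$chi))] + tr$offset
        if (is.na(torsion))
          stop("no rotamer chi angle for ", newResidue, " ", tr$chi)
        p <- placeAtomNerf(pos[[tr$r1]], pos[[tr$r2]], pos[[tr$r3]],
                           tr$bond, tr$angle, torsion)
        pos[[tr$atom]] <- p
        row <- newAtoms[1, , drop = FALSE]
        row$elety <- tr$atom; row$element <- tr$element
        row$x <- p[1]; row$y <- p[2]; row$z <- p[3]
        row$occupancy <- 1; row$altloc <- ""
        newAtoms <- rbind(newAtoms, row)
      }
    }
  }
  newAtoms$radius <- assignRadii(newAtoms$element, radii)
  out <- rbind(a[!sel & seq_len(nrow(a)) < which(sel)[1], ],
               newAtoms,
               a[!sel & seq_len(nrow(a)) > which(sel)[1], ])
  out$eleno <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure@atoms <- out
  validObject(structure)
  structure
}
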