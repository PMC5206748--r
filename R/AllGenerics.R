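#' Atom table of a structure
#'
#' @param x a [PDBStructure-class].
#' @return data.frame of atoms (see [PDBStructure-class]).
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)

#' Chain identifiers of a structure
#' @param x a [PDBStructure-class].
#' @return character vector of chain ids in file order.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainIds
#' @export
setMethod("chainIds", "PDBStructure", function(x) unique(x@atoms$chain))

#' Number of atoms
#' @param x a [PDBStructure-class].
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "PDBStructure", function(x) nrow(x@atoms))

#' Coordinate matrix
#' @param x a [PDBStructure-class].
#' @return n x 3 numeric matrix of coordinates in Angstrom.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "PDBStructure", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' Entry identifier
#' @param x a [PDBStructure-class].
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))

#' @rdname entryId
#' @export
setMethod("entryId", "PDBStructure", function(x) x@entryId)

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  prot <- sum(!a$het)
  cat("PDBStructure",
      if (!is.na(object@entryId)) paste0(" <", object@entryId, ">"), "\n",
      "  chains: ", paste(unique(a$chain), collapse = ", "),
      "\n  atoms:  ", nrow(a), " (", prot, " protein, ", nrow(a) - prot, " hetero)",
      "\n  residues: ", nrow(unique(a[!a$het, c("chain", "resno", "insert")])),
      "\n", sep = "")
})

#' Rotation matrix / translation accessors
#' @param x a [RigidTransform-class].
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname rotation
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' @rdname rotation
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname rotation
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation angle:",
      format(rotationAngle(object), digits = 4), "deg\n  translation:",
      paste(format(object@translation, digits = 4), collapse = ", "), "A\n")
})

#' RMSD accessors
#' @param x a [SuperpositionResult-class].
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname rmsd
#' @export
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)

#' @rdname rmsd
#' @export
setGeneric("perResidueDeviation", function(x) standardGeneric("perResidueDeviation"))

#' @rdname rmsd
#' @export
setMethod("perResidueDeviation", "SuperpositionResult", function(x) x@perResidue)

#' Mean +/- SD of per-residue deviations
#'
#' The conventional "RMSD = x +/- y Angstrom over residues i-j" report: the
#' mean and standard deviation of per-residue mean main-chain deviations.
#'
#' @param x a [SuperpositionResult-class].
#' @return named numeric `c(mean =, sd =)`; `sd` is 0 for a single residue.
#' @export
setGeneric("deviationSummary", function(x) standardGeneric("deviationSummary"))

#' @rdname deviationSummary
#' @export
setMethod("deviationSummary", "SuperpositionResult", function(x) {
  d <- x@perResidue$deviation
  if (length(d) == 0) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0)
})

setMethod("show", "SuperpositionResult", function(object) {
  ds <- deviationSummary(object)
  cat("SuperpositionResult\n  atoms fitted: ", object@nAtoms,
      "\n  RMSD: ", format(object@rmsd, digits = 4), " A\n", sep = "")
  if (!is.na(ds["mean"]))
    cat("  per-residue deviation: ", format(ds["mean"], digits = 3), " +/- ",
        format(ds["sd"], digits = 3), " A over ", nrow(object@perResidue),
        " residues\n", sep = "")
})

#' Overlap volume accessors
#' @param x an [OverlapResult-class].
#' @export
setGeneric("overlapVolumeValue", function(x) standardGeneric("overlapVolumeValue"))

#' @rdname overlapVolumeValue
#' @export
setMethod("overlapVolumeValue", "OverlapResult", function(x) x@volume)

#' @rdname overlapVolumeValue
#' @export
setGeneric("signedScore", function(x) standardGeneric("signedScore"))

#' @rdname overlapVolumeValue
#' @export
setMethod("signedScore", "OverlapResult", function(x) x@signedScore)

#' @rdname overlapVolumeValue
#' @export
setGeneric("clashPairs", function(x) standardGeneric("clashPairs"))

#' @rdname overlapVolumeValue
#' @export
setMethod("clashPairs", "OverlapResult", function(x) x@clashPairs)

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult (grid ", object@gridSpacing, " A)\n  overlap volume: ",
      format(object@volume, digits = 6), " A^3\n  clash pairs: ",
      nrow(object@clashPairs), "\n", sep = "")
  if (!is.na(object@signedScore))
    cat("  signed score: ", format(object@signedScore, digits = 6), " A^3",
        if (object@farApart) " (far apart)", "\n", sep = "")
})

setMethod("show", "SasaResult", function(object) {
  cat("SasaResult\n  total SASA: ", format(object@total, digits = 6),
      " A^2 (probe ", object@probeRadius, " A, ", object@nPoints,
      " points/atom, ", length(object@perAtom), " atoms)\n", sep = "")
})

setMethod("show", "ItcFit", function(object) {
  cat("One-site ITC fit\n",
      "  n    = ", format(object@n, digits = 4),
      " +/- ", format(object@stderr["n"], digits = 2), "\n",
      "  K    = ", format(object@K, digits = 4), " 1/M (KD = ",
      format(1 / object@K, digits = 3), " M)\n",
      "  dH   = ", format(object@dH, digits = 4), " cal/mol\n",
      "  offset = ", format(object@offset, digits = 3), " ucal\n", sep = "")
})

setMethod("show", "KineticFit", function(object) {
  cat("1:1 SPR global fit\n",
      "  kon  = ", format(object@kon, digits = 4), " 1/(M s)\n",
      "  koff = ", format(object@koff, digits = 4), " 1/s\n",
      "  KD   = ", format(object@KD, digits = 4), " M\n",
      "  Rmax = ", format(object@Rmax, digits = 4), " RU\n", sep = "")
})

setMethod("show", "EpitopeCall", function(object) {
  cat("EpitopeCall (threshold ", object@threshold, ")\n", sep = "")
  for (ab in names(object@calls))
    cat("  ", ab, ": ",
        if (length(object@calls[[ab]]) > 0)
          paste(object@calls[[ab]], collapse = ", ") else "(none)",
        "\n", sep = "")
  if (length(object@flagged) > 0)
    cat("  flagged (multi-antibody loss): ",
        paste(object@flagged, collapse = ", "), "\n", sep = "")
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport:", object@analysis, "\n")
  print(object@results)
})

#' Epitope call accessor
#' @param x an [EpitopeCall-class].
#' @return named list antibody -> integer positions.
#' @export
setGeneric("epitopes", function(x) standardGeneric("epitopes"))

#' @rdname epitopes
#' @export
setMethod("epitopes", "EpitopeCall", function(x) x@calls)

#' Report results accessor
#' @param x an [AnalysisReport-class].
#' @export
setGeneric("reportResults", function(x) standardGeneric("reportResults"))

#' @rdname reportResults
#' @export
setMethod("reportResults", "AnalysisReport", function(x) x@results)
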