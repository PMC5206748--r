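#' @import methods
NULL

#' Macromolecular structure container
#'
#' Holds one model of a macromolecular structure as a flat atom table plus
#' entry-level metadata. Atoms are stored in file order with chain, author
#' residue number, insertion code, residue name, atom name, element, altloc,
#' occupancy, Cartesian coordinates in Angstrom, an element-wise van der Waals
#' radius, and a flag for non-protein (HETATM) records. Author residue
#' numbering is the coordinate convention throughout the package; residue
#' ranges are 1-based and inclusive.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `eleno`, `element`, `altloc`, `occupancy`, `x`, `y`, `z`,
#'   `radius`, `het`.
#' @slot entryId character, e.g. a PDB accession or a synthetic label.
#' @slot model integer model number.
#'
#' @seealso [readStructure()], [resolveSelection()], [atomSelection()]
#' @export
setClass("PDBStructure",
  representation(atoms = "data.frame", entryId = "character", model = "integer"),
  prototype(entryId = NA_character_, model = 1L)
)

setValidity("PDBStructure", function(object) {
  need <- c("chain", "resno", "insert", "resid", "elety", "eleno", "element",
            "altloc", "occupancy", "x", "y", "z", "radius", "het")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss) > 0)
    return(paste("atom table missing columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 0 && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  occ <- object@atoms$occupancy
  if (length(occ) > 0 && any(!is.na(occ) & (occ < 0 | occ > 1)))
    return("occupancy must lie in [0, 1]")
  r <- object@atoms$radius
  if (length(r) > 0 && any(!is.na(r) & r <= 0))
    return("assigned vdW radii must be positive")
  TRUE
})

#' Atom selection
#'
#' A declarative selection: chain identifiers, an inclusive author residue
#' number range, and an atom-name set. `NULL` fields match everything.
#' Resolving a selection against a [PDBStructure-class] yields a
#' deterministic, ordered atom table.
#'
#' @slot chains character vector of chain ids, or zero-length for all chains.
#' @slot range integer vector `c(first, last)` in author numbering, or
#'   zero-length for all residues.
#' @slot atomNames character vector of atom names (e.g. the main-chain set
#'   `N, CA, C, O`), or zero-length for all atoms.
#'
#' @export
setClass("AtomSelection",
  representation(chains = "character", range = "integer", atomNames = "character"),
  prototype(chains = character(), range = integer(), atomNames = character())
)

setValidity("AtomSelection", function(object) {
  if (length(object@range) %in% c(0L, 2L)) {
    if (length(object@range) == 2L && object@range[1] > object@range[2])
      return("range must be c(first, last) with first <= last")
    TRUE
  } else "range must be empty or length 2"
})

#' Rigid-body transform
#'
#' A proper rotation plus translation, mapping a point `x` to `R x + t`.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric length-3 vector (Angstrom).
#'
#' @seealso [kabschSuperpose()], [applyTransform()], [composeTransforms()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0))
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  TRUE
})

#' Superposition result
#'
#' Output of a least-squares rigid superposition: the fitted transform, the
#' scalar RMSD over the fitted atoms, and (when residue identity is known)
#' per-residue mean deviations whose mean +/- SD is the conventional way this
#' field reports "RMSD = x +/- y" over a residue window.
#'
#' @slot transform [RigidTransform-class] mapping mobile onto reference.
#' @slot rmsd numeric scalar RMSD (Angstrom) over all fitted atoms.
#' @slot perResidue data.frame with columns `chain`, `resno`, `deviation`
#'   (mean atomic deviation per residue, Angstrom); may have zero rows.
#' @slot nAtoms integer number of atom pairs used.
#'
#' @export
setClass("SuperpositionResult",
  representation(transform = "RigidTransform", rmsd = "numeric",
                 perResidue = "data.frame", nAtoms = "integer")
)

setValidity("SuperpositionResult", function(object) {
  if (length(object@rmsd) != 1L || object@rmsd < 0) return("rmsd must be a scalar >= 0")
  TRUE
})

#' Hypothetical dimer-plus-two-antibodies assembly
#'
#' The antibody-antigen complex superposed onto each protomer of a dimer
#' template. The template is never moved; each placed copy is a rigid
#' transform of the input complex.
#'
#' @slot template [PDBStructure-class] the dimer template.
#' @slot placedCopies list of two [PDBStructure-class] objects, the complex
#'   placed on protomer A and on protomer B.
#' @slot transforms list of two [RigidTransform-class] objects used for the
#'   placements.
#' @slot fitRmsds numeric length 2, antigen-onto-protomer fit RMSDs (Angstrom).
#' @slot antigen,protomerA,protomerB the [AtomSelection-class] mappings used.
#'
#' @export
setClass("AssemblyModel",
  representation(template = "PDBStructure", placedCopies = "list",
                 transforms = "list", fitRmsds = "numeric",
                 antigen = "AtomSelection", protomerA = "AtomSelection",
                 protomerB = "AtomSelection")
)

setValidity("AssemblyModel", function(object) {
  if (length(object@placedCopies) != 2L) return("placedCopies must have length 2")
  if (length(object@fitRmsds) != 2L) return("fitRmsds must have length 2")
  TRUE
})

#' Steric overlap result
#'
#' Grid-based van der Waals overlap between two atom bodies. `volume` is the
#' intersection volume of the two union-of-spheres envelopes; `signedScore`
#' is positive overlap volume when the bodies clash and minus the
#' probe-inflated overlap (a proximity margin) when they do not;
#' `clashPairs` lists atom pairs whose centre distance is below the sum of
#' radii.
#'
#' @slot volume numeric, cubic Angstrom, >= 0.
#' @slot signedScore numeric, cubic Angstrom (`NA` unless computed via
#'   [signedClearance()]).
#' @slot clashPairs data.frame with columns `atomA`, `atomB`, `distance`,
#'   `overlap`.
#' @slot gridSpacing numeric, Angstrom.
#' @slot farApart logical, `TRUE` when even probe-inflated envelopes are
#'   disjoint.
#'
#' @export
setClass("OverlapResult",
  representation(volume = "numeric", signedScore = "numeric",
                 clashPairs = "data.frame", gridSpacing = "numeric",
                 farApart = "logical"),
  prototype(signedScore = NA_real_, farApart = FALSE)
)

setValidity("OverlapResult", function(object) {
  if (object@volume < 0) return("overlap volume must be >= 0")
  TRUE
})

#' Solvent-accessible surface area result
#'
#' @slot total numeric, square Angstrom.
#' @slot perAtom numeric vector, square Angstrom per atom.
#' @slot perResidue data.frame with columns `chain`, `resno`, `sasa`.
#' @slot probeRadius numeric, Angstrom.
#' @slot nPoints integer, sphere sample points per atom.
#'
#' @export
setClass("SasaResult",
  representation(total = "numeric", perAtom = "numeric",
                 perResidue = "data.frame", probeRadius = "numeric",
                 nPoints = "integer")
)

setValidity("SasaResult", function(object) {
  if (any(object@perAtom < -1e-9)) return("per-atom SASA must be >= 0")
  if (abs(object@total - sum(object@perAtom)) > 1e-6 * max(1, object@total))
    return("total must equal the sum of per-atom values")
  TRUE
})

#' One-site ITC experiment
#'
#' Injection-level calorimetry data: the binding partner in the cell (here
#' the antibody), the titrant in the syringe (the cadherin construct), the
#' cell volume, per-injection volumes and measured heats.
#'
#' @slot cellConc molar concentration of the cell species.
#' @slot syringeConc molar concentration of the titrant.
#' @slot cellVolume cell volume in litre.
#' @slot injectionVolumes litre per injection.
#' @slot heats microcalories per injection.
#' @slot temperature kelvin.
#'
#' @export
setClass("ItcExperiment",
  representation(cellConc = "numeric", syringeConc = "numeric",
                 cellVolume = "numeric", injectionVolumes = "numeric",
                 heats = "numeric", temperature = "numeric"),
  prototype(temperature = 288.15)
)

setValidity("ItcExperiment", function(object) {
  if (object@cellConc <= 0 || object@syringeConc <= 0 || object@cellVolume <= 0)
    return("concentrations and cell volume must be positive")
  if (length(object@heats) != length(object@injectionVolumes))
    return("heats and injectionVolumes must have equal length")
  TRUE
})

#' One-site ITC fit
#'
#' @slot n stoichiometry (titrant bound per cell molecule), dimensionless.
#' @slot K association constant, 1/M.
#' @slot dH enthalpy, cal/mol.
#' @slot offset constant per-injection baseline heat, microcal.
#' @slot stderr named numeric vector of standard errors for n, K, dH, offset.
#' @slot residuals microcal residuals (fitted injections).
#' @slot molarRatio titrant/cell molar ratio per fitted injection.
#'
#' @export
setClass("ItcFit",
  representation(n = "numeric", K = "numeric", dH = "numeric",
                 offset = "numeric", stderr = "numeric",
                 residuals = "numeric", molarRatio = "numeric")
)

setValidity("ItcFit", function(object) {
  if (object@n <= 0) return("n must be positive")
  if (object@K <= 0) return("K must be positive")
  TRUE
})

#' SPR kinetic titration experiment
#'
#' Sensorgrams for a concentration series of one analyte over a shared
#' association/dissociation window, stored long-format.
#'
#' @slot data data.frame with columns `concentration` (M), `time` (s),
#'   `response` (RU), `phase` ("association"/"dissociation").
#' @slot associationTime,dissociationTime seconds.
#'
#' @export
setClass("SprExperiment",
  representation(data = "data.frame", associationTime = "numeric",
                 dissociationTime = "numeric")
)

setValidity("SprExperiment", function(object) {
  need <- c("concentration", "time", "response", "phase")
  if (!all(need %in% names(object@data)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  sp <- split(object@data$time, object@data$concentration)
  if (any(!vapply(sp, function(t) all(diff(t) > 0), logical(1))))
    return("time must be strictly increasing within each sensorgram")
  TRUE
})

#' 1:1 SPR kinetic fit
#'
#' Globally shared association rate, dissociation rate and saturation
#' response across the concentration series; `KD = koff/kon` by identity.
#'
#' @slot kon 1/(M s).
#' @slot koff 1/s.
#' @slot Rmax RU.
#' @slot KD M.
#' @slot stderr named numeric vector of standard errors.
#' @slot residuals RU residuals over all fitted points.
#'
#' @export
setClass("KineticFit",
  representation(kon = "numeric", koff = "numeric", Rmax = "numeric",
                 KD = "numeric", stderr = "numeric", residuals = "numeric")
)

setValidity("KineticFit", function(object) {
  if (object@kon <= 0 || object@koff <= 0 || object@Rmax <= 0)
    return("kon, koff and Rmax must be positive")
  if (abs(object@KD - object@koff / object@kon) >
      1e-12 * max(object@KD, .Machine$double.eps))
    return("KD must equal koff/kon")
  TRUE
})

#' Epitope call from a mutant binding panel
#'
#' @slot calls named list: antibody -> integer vector of epitope residue
#'   positions (author numbering).
#' @slot supportingMutants named list: antibody -> character vector of mutant
#'   ids whose binding fell below threshold.
#' @slot flagged character vector of mutant ids that lost binding to more
#'   than one antibody (possible fold disruption; still counted).
#' @slot threshold numeric, binding level (fraction of WT) below which a
#'   mutant set is called epitope.
#'
#' @export
setClass("EpitopeCall",
  representation(calls = "list", supportingMutants = "list",
                 flagged = "character", threshold = "numeric")
)

#' Pipeline analysis report
#'
#' Everything needed to re-run an analysis bit-identically: input provenance,
#' per-stage parameters, and results.
#'
#' @slot analysis character, "xdimer_compatibility" or "design_screen".
#' @slot inputs named list of input identifiers/paths/seeds.
#' @slot parameters named list of per-stage parameters (grid spacing, radii
#'   set, probe, selections, clash floor).
#' @slot results data.frame of per-template or per-mutation results.
#'
#' @export
setClass("AnalysisReport",
  representation(analysis = "character", inputs = "list",
                 parameters = "list", results = "data.frame")
)
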