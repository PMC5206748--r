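## Epitope calling from mutant binding panels: a mutant set whose binding to
## an antibody drops below a fraction of the wild-type signal marks its
## mutated positions as epitope residues for that antibody.

#' Read a mutant binding panel
#'
#' CSV with columns `mutant_id`, `positions` (residue positions separated by
#' `;`, author numbering; empty for WT) and one `level_<antibody>` column
#' per antibody giving the binding level as a fraction of WT. A `WT` row
#' must be present (levels 1.0 by construction).
#'
#' @param path CSV path.
#' @return data.frame panel (positions kept as `;`-strings).
#' @export
readMutantPanel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateMutantPanel(df)
  df
}

validateMutantPanel <- function(panel) {
  if (nrow(panel) == 0) stop("empty mutant panel")
  if (!all(c("mutant_id", "positions") %in% names(panel)))
    stop("panel needs columns mutant_id, positions")
  levels <- grep("^level_", names(panel), value = TRUE)
  if (length(levels) == 0) stop("panel has no level_<antibody> columns")
  if (!"WT" %in% panel$mutant_id)
    stop("panel is missing the WT reference row")
  if (any(panel[, levels] < 0)) stop("binding levels must be >= 0")
  invisible(levels)
}

parsePositions <- function(s) {
  if (is.na(s) || s == "") return(integer())
  sort(unique(as.integer(strsplit(s, ";", fixed = TRUE)[[1]])))
}

#' Call epitopes from a mutant binding panel
#'
#' For each antibody, the epitope is the union of the mutated positions of
#' every mutant set whose binding level is strictly below `threshold` times
#' the WT level (default 0.20, i.e. "below 20 percent of WT"; a level of
#' exactly 0.20 is not called). Mutants that lose binding to more than one
#' antibody are flagged as possible fold disruptions but still counted.
#'
#' @param panel data.frame from [readMutantPanel()] (or built in code).
#' @param threshold fraction of WT binding below which a mutant set is
#'   assigned to the epitope.
#' @return an [EpitopeCall-class].
#' @export
callEpitopes <- function(panel, threshold = 0.20) {
  levelCols <- validateMutantPanel(panel)
  abs <- sub("^level_", "", levelCols)
  mut <- panel[panel$mutant_id != "WT", , drop = FALSE]
  calls <- list(); support <- list()
  below <- matrix(FALSE, nrow(mut), length(abs),
                  dimnames = list(mut$mutant_id, abs))
  for (j in seq_along(abs)) {
    below[, j] <- mut[[levelCols[j]]] < threshold
    hit <- which(below[, j])
    pos <- sort(unique(unlist(lapply(mut$positions[hit], parsePositions))))
    calls[[abs[j]]] <- as.integer(pos)
    support[[abs[j]]] <- mut$mutant_id[hit]
  }
  flagged <- rownames(below)[rowSums(below) > 1]
  new("EpitopeCall", calls = calls, supportingMutants = support,
      flagged = as.character(flagged), threshold = threshold)
}

#' Compare two epitope calls
#'
#' Set algebra on the called residue positions of one antibody from each
#' call (or of two antibodies within one call).
#'
#' @param callA,callB [EpitopeCall-class] objects (same numbering scheme).
#' @param antibodyA,antibodyB which antibody to take from each; defaults to
#'   the first.
#' @return list with `shared`, `uniqueA`, `uniqueB` integer position vectors.
#' @export
epitopeOverlapReport <- function(callA, callB, antibodyA = NULL,
                                 antibodyB = NULL) {
  pick <- function(call, ab) {
    if (is.null(ab)) ab <- names(call@calls)[1]
    if (!ab %in% names(call@calls)) stop("no epitope call for ", ab)
    call@calls[[ab]]
  }
  a <- pick(callA, antibodyA); b <- pick(callB, antibodyB)
  list(shared = intersect(a, b),
       uniqueA = setdiff(a, b),
       uniqueB = setdiff(b, a))
}

#' Paint an epitope onto a structure's B-factor column
#'
#' Writes a PDB copy in which called epitope residues carry B-factor 100 and
#' everything else 0, for quick visual inspection in a molecular viewer.
#'
#' @param structure a [PDBStructure-class] (numbering matching the panel).
#' @param call an [EpitopeCall-class].
#' @param antibody which antibody's epitope to paint.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
paintEpitope <- function(structure, call, antibody, path) {
  if (!antibody %in% names(call@calls)) stop("no epitope call for ", antibody)
  a <- atoms(structure)
  b <- ifelse(a$resno %in% call@calls[[antibody]], 100, 0)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain, o = a$occupancy,
                   b = b, elesy = a$element)
  invisible(path)
}
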