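## End-to-end analyses: per-template steric compatibility of the
## antibody-bound complex with candidate dimer geometries, and a mutation
## design screen ranked by change in signed clearance.

resolveInput <- function(x) {
  if (is(x, "PDBStructure")) return(x)
  if (is.character(x)) return(readStructure(x))
  stop("inputs must be PDBStructure objects or file paths")
}

inputLabel <- function(x, fallback) {
  if (is.character(x)) return(x)
  if (is(x, "PDBStructure") && !is.na(entryId(x))) return(entryId(x))
  fallback
}

#' Steric compatibility of an antibody-bound complex with dimer templates
#'
#' For each dimer template: superpose the complex's antigen domain onto both
#' protomers, measure the vdW overlap volume between the two placed antibody
#' bodies, and return a clash / no-clash verdict (clash iff volume exceeds
#' `clashFloor`, default 0 at the working grid). A dimeric state whose
#' geometry forces the two bound antibodies into each other cannot form with
#' antibody bound — the structural reading of an antibody that blocks one
#' dimer but not another.
#'
#' @param complex [PDBStructure-class] or path: the antibody-antigen complex.
#' @param templates named list of templates ([PDBStructure-class] or paths).
#' @param antigen selection (string or [AtomSelection-class]) of the antigen
#'   domain in the complex.
#' @param protomerA,protomerB selections of the template protomers; either a
#'   single selection used for every template or a named list parallel to
#'   `templates`. Which template chain is protomer A is explicit input,
#'   never inferred.
#' @param antibody selection of the antibody body within the complex (the
#'   part tested for overlap).
#' @param gridSpacing overlap grid, Angstrom.
#' @param clashFloor volume floor for the clash verdict, cubic Angstrom.
#' @param verbose log stage progress to stderr.
#' @return an [AnalysisReport-class]; `results` has one row per template
#'   with overlap volume, signed score, clash-pair count, fit RMSDs and
#'   verdict.
#' @export
runXdimerCompatibility <- function(complex, templates, antigen, protomerA,
                                   protomerB, antibody, gridSpacing = 0.5,
                                   clashFloor = 0, verbose = FALSE) {
  if (length(templates) == 0) stop("empty template list")
  if (is.null(names(templates)) || any(names(templates) == ""))
    names(templates) <- paste0("template", seq_along(templates))
  cx <- resolveInput(complex)
  selOf <- function(sel, nm) if (is.list(sel)) sel[[nm]] else sel
  rows <- lapply(names(templates), function(nm) {
    if (verbose) message("[xdimer] template ", nm)
    tm <- resolveInput(templates[[nm]])
    asm <- buildAssembly(cx, tm, selOf(protomerA, nm), selOf(protomerB, nm),
                         antigen)
    bodyA <- resolveSelection(placedCopy(asm, 1), antibody)
    bodyB <- resolveSelection(placedCopy(asm, 2), antibody)
    ov <- signedClearance(bodyA, bodyB, gridSpacing = gridSpacing)
    data.frame(template = nm, overlapVolume = ov@volume,
               signedScore = ov@signedScore, clashPairs = nrow(ov@clashPairs),
               fitRmsdA = asm@fitRmsds[1], fitRmsdB = asm@fitRmsds[2],
               verdict = ifelse(ov@volume > clashFloor, "clash", "no-clash"),
               stringsAsFactors = FALSE)
  })
  new("AnalysisReport", analysis = "xdimer_compatibility",
      inputs = list(complex = inputLabel(complex, "complex"),
                    templates = vapply(seq_along(templates), function(i)
                      inputLabel(templates[[i]], names(templates)[i]),
                      character(1))),
      parameters = list(antigen = selText(antigen),
                        protomerA = selText(protomerA),
                        protomerB = selText(protomerB),
                        antibody = selText(antibody),
                        gridSpacing = gridSpacing, clashFloor = clashFloor,
                        radiiSet = "shipped-default"),
      results = do.call(rbind, rows))
}

selText <- function(sel) {
  if (is.list(sel)) return(vapply(sel, selText, character(1)))
  if (is.character(sel)) return(sel)
  if (is(sel, "AtomSelection"))
    return(paste(
      if (length(sel@chains)) paste(sel@chains, collapse = ",") else "*",
      if (length(sel@range)) paste(sel@range, collapse = "-") else "*",
      if (length(sel@atomNames)) paste(sel@atomNames, collapse = ",") else "*",
      sep = ":"))
  "custom"
}

#' Mutation design screen on a dimer template
#'
#' For each candidate mutation of the antibody, rebuilds the assembly on the
#' given template with the mutation applied to both placed copies and
#' reports the signed clearance before and after, ranked by the increase.
#' A mutation that flips the score from negative (clearance) to positive
#' (overlap) is predicted to make antibody binding incompatible with that
#' dimer — the designed steric-hindrance effect.
#'
#' @inheritParams runXdimerCompatibility
#' @param template one dimer template ([PDBStructure-class] or path).
#' @param mutations list of `list(chain=, resno=, to=)` mutations applied to
#'   the complex (e.g. an antibody framework serine to arginine).
#' @return an [AnalysisReport-class]; `results` ranked by delta signed score.
#' @export
runDesignScreen <- function(complex, template, mutations, antigen, protomerA,
                            protomerB, antibody, gridSpacing = 0.5,
                            verbose = FALSE) {
  cx <- resolveInput(complex)
  tm <- resolveInput(template)
  score <- function(cplx) {
    asm <- buildAssembly(cplx, tm, protomerA, protomerB, antigen)
    ov <- signedClearance(resolveSelection(placedCopy(asm, 1), antibody),
                          resolveSelection(placedCopy(asm, 2), antibody),
                          gridSpacing = gridSpacing)
    ov@signedScore
  }
  if (verbose) message("[design] baseline")
  base <- score(cx)
  rows <- lapply(mutations, function(m) {
    lab <- sprintf("%s:%d>%s", m$chain, m$resno, toupper(m$to))
    if (verbose) message("[design] ", lab)
    mutated <- mutateResidue(cx, m$chain, m$resno, m$to)
    s <- score(mutated)
    data.frame(mutation = lab, scoreBefore = base, scoreAfter = s,
               delta = s - base,
               signFlip = base <= 0 && s > 0, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$delta), ]
  rownames(res) <- NULL
  new("AnalysisReport", analysis = "design_screen",
      inputs = list(complex = inputLabel(complex, "complex"),
                    template = inputLabel(template, "template")),
      parameters = list(antigen = selText(antigen),
                        protomerA = selText(protomerA),
                        protomerB = selText(protomerB),
                        antibody = selText(antibody),
                        gridSpacing = gridSpacing,
                        radiiSet = "shipped-default"),
      results = res)
}

#' Serialize an analysis report to JSON
#'
#' The report records inputs and every stage parameter, so re-running from
#' the report reproduces all numbers (the grid is deterministic).
#'
#' @param report an [AnalysisReport-class].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(
    list(schema = "xdclash-report/1", analysis = report@analysis,
         inputs = report@inputs, parameters = report@parameters,
         results = report@results),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' End-to-end demonstration on synthetic fixtures
#'
#' Generates toy fixtures, runs assembly + overlap on a close and a wide
#' dimer template, fits a simulated ITC isotherm and SPR series, calls a
#' planted epitope panel, and checks every result against its ground truth.
#' Runs in well under two minutes on one CPU.
#'
#' @param seed RNG seed for all generators.
#' @param verbose log stages to stderr.
#' @return named list of results and logical `checks` (all TRUE on success).
#' @export
runDemo <- function(seed = 1L, verbose = FALSE) {
  close_ <- makeToyComplexAndTemplate(separation = 10, antibodyRadius = 8,
                                      seed = seed)
  wide <- makeToyComplexAndTemplate(separation = 60, antibodyRadius = 8,
                                    seed = seed)
  rep1 <- runXdimerCompatibility(
    close_$complex, list(close = close_$template, wide = wide$template),
    antigen = "A", protomerA = "A", protomerB = "B", antibody = "H",
    gridSpacing = 0.5, verbose = verbose)
  itc <- fitItc(simulateItc(1.5, 1e8, -1e4, noiseSd = 0.05,
                            seed = seed))
  spr <- fitSprGlobal(simulateSensorgram(1e6, 1e-3, 100, noiseSd = 0.5,
                                         seed = seed))
  pan <- makeEpitopePanel(seed = seed)
  call <- callEpitopes(pan$panel)
  res <- reportResults(rep1)
  checks <- c(
    closeClash = res$verdict[res$template == "close"] == "clash",
    wideClear = res$verdict[res$template == "wide"] == "no-clash",
    closeVolume = abs(res$overlapVolume[res$template == "close"] -
                      close_$groundTruth$analyticOverlap) /
                  close_$groundTruth$analyticOverlap < 0.05,
    itcN = abs(itc@n - 1.5) < 0.05,
    sprKD = abs(spr@KD - 1e-9) / 1e-9 < 0.1,
    epitopes = identical(lapply(epitopes(call), as.integer),
                         lapply(pan$groundTruth$epitopes, as.integer)))
  list(compatibility = rep1, itcFit = itc, sprFit = spr, epitopeCall = call,
       checks = checks)
}
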