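## Structure reading/writing and named selections. Parsing of the standard
## formats is delegated to bio3d; this layer resolves altlocs, assigns vdW
## radii and presents a single flat atom table.

MAIN_CHAIN_ATOMS <- c("N", "CA", "C", "O")

#' Load a van der Waals radii table
#'
#' Element-wise radii in Angstrom used for overlap volumes, clash listing and
#' SASA. The shipped default covers the common protein elements
#' (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20) plus frequent hetero elements.
#' Any CSV with columns `element,radius`, or a YAML mapping, can be swapped
#' in: reported volumes depend on the radii set, so it is explicit.
#'
#' @param path optional path to a CSV (`element,radius`) or YAML file;
#'   default uses the table shipped with the package.
#' @return named numeric vector, radii in Angstrom keyed by uppercase element.
#' @export
vdwRadiiTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vdw_radii.csv", package = "xdclash",
                        mustWork = TRUE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    r <- unlist(lst)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    r <- stats::setNames(df$radius, df$element)
  }
  names(r) <- toupper(names(r))
  if (any(r <= 0)) stop("vdW radii must be positive")
  r
}

guessElement <- function(elety) {
  # PDB atom names: element is the alphabetic stem once digits and primes are
  # stripped; leading digit (e.g. "1HB") marks hydrogens
  e <- toupper(gsub("[^A-Za-z].*$", "", sub("^[0-9]+", "H", elety)))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN", "CU"),
         two, one)
}

assignRadii <- function(element, radii, default = 1.70) {
  r <- unname(radii[element])
  r[is.na(r)] <- default
  r
}

#' Construct a structure from a raw atom table
#'
#' Fills defaults (empty altloc/insert, unit occupancy), derives elements from
#' atom names where absent, and assigns vdW radii. Used by the synthetic-data
#' generators and useful for programmatic model building.
#'
#' @param df data.frame with at least `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`; optional `insert`, `altloc`, `occupancy`, `element`,
#'   `eleno`, `het`, `radius`.
#' @param entryId character label stored as the entry id.
#' @param radii named radii vector from [vdwRadiiTable()].
#' @return a [PDBStructure-class].
#' @export
structureFromAtoms <- function(df, entryId = NA_character_,
                               radii = vdwRadiiTable()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  if (is.null(df$insert)) df$insert <- rep("", n)
  df$insert[is.na(df$insert)] <- ""
  if (is.null(df$altloc)) df$altloc <- rep("", n)
  df$altloc[is.na(df$altloc)] <- ""
  if (is.null(df$occupancy)) df$occupancy <- rep(1, n)
  df$occupancy[is.na(df$occupancy)] <- 1
  if (is.null(df$eleno)) df$eleno <- seq_len(n)
  if (is.null(df$het)) df$het <- rep(FALSE, n)
  if (is.null(df$element) || anyNA(df$element) || any(df$element == "")) {
    guess <- guessElement(df$elety)
    if (is.null(df$element)) df$element <- guess
    bad <- is.na(df$element) | df$element == ""
    df$element[bad] <- guess[bad]
  }
  df$element <- toupper(df$element)
  if (is.null(df$radius)) df$radius <- assignRadii(df$element, radii)
  keep <- c("chain", "resno", "insert", "resid", "elety", "eleno", "element",
            "altloc", "occupancy", "x", "y", "z", "radius", "het")
  df <- df[, keep]
  rownames(df) <- NULL
  new("PDBStructure", atoms = df, entryId = entryId, model = 1L)
}

resolveAltlocs <- function(df) {
  # keep the highest-occupancy conformer; ties broken alphabetically so the
  # retained single-conformer geometry is deterministic
  key <- paste(df$chain, df$resno, df$insert, df$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -df$occupancy, df$altloc)
  df <- df[ord, ]
  df <- df[!duplicated(paste(df$chain, df$resno, df$insert, df$elety,
                             sep = "\r")), ]
  df[order(match(paste(df$chain, df$resno, df$insert, sep = "\r"),
                 unique(paste(df$chain, df$resno, df$insert, sep = "\r")))), ]
}

#' Read a macromolecular structure
#'
#' Reads PDB (v3.3 fixed column) or mmCIF via bio3d, resolves alternate
#' locations to a single conformer (highest occupancy, ties alphabetical),
#' optionally drops hydrogens (crystal structures usually lack them), flags
#' but retains waters and other heteroatoms, and assigns element-wise vdW
#' radii.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "cif".
#' @param keepHydrogens logical; drop H atoms by default.
#' @param radii named radii vector from [vdwRadiiTable()].
#' @return a [PDBStructure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          keepHydrogens = FALSE, radii = vdwRadiiTable()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure: ", path)
  df <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    eleno = a$eleno,
    element = if (!is.null(a$elesy)) toupper(ifelse(is.na(a$elesy), "", a$elesy))
              else "",
    altloc = ifelse(is.na(a$alt), "", a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    stringsAsFactors = FALSE)
  blank <- df$element == ""
  df$element[blank] <- guessElement(df$elety[blank])
  df <- resolveAltlocs(df)
  if (!keepHydrogens) df <- df[df$element != "H", ]
  if (nrow(df) == 0) stop("empty structure after filtering: ", path)
  df$occupancy <- pmin(pmax(df$occupancy, 0), 1)
  st <- structureFromAtoms(df, entryId = sub("\\.[^.]*$", "", basename(path)),
                           radii = radii)
  st
}

#' Write a structure as PDB
#'
#' @param structure a [PDBStructure-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(structure, path) {
  a <- atoms(structure)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   alt = ifelse(a$altloc == "", NA, a$altloc),
                   o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Create an atom selection
#'
#' @param chains character vector of chain ids (`NULL` = all).
#' @param range inclusive author residue number range `c(first, last)`
#'   (`NULL` = all residues).
#' @param atomNames atom-name set, e.g. `c("N","CA","C","O")` (`NULL` = all
#'   atom names). [mainChainSelection()] is a shorthand for that set.
#' @return an [AtomSelection-class].
#' @export
atomSelection <- function(chains = NULL, range = NULL, atomNames = NULL) {
  new("AtomSelection",
      chains = if (is.null(chains)) character() else as.character(chains),
      range = if (is.null(range)) integer() else as.integer(range),
      atomNames = if (is.null(atomNames)) character() else as.character(atomNames))
}

#' @rdname atomSelection
#' @export
mainChainSelection <- function(chains = NULL, range = NULL)
  atomSelection(chains, range, MAIN_CHAIN_ATOMS)

#' Parse a selection string
#'
#' Grammar: `CHAINS[:RANGE[:ATOMS]]` with chains comma-separated, range
#' `first-last`, atoms comma-separated; `*` means "all" at any position.
#' Example: `"A:10-99:N,CA,C,O"`.
#'
#' @param text selection string.
#' @return an [AtomSelection-class].
#' @export
parseSelection <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  star <- function(p) length(p) == 0 || identical(p, "*") || p == ""
  chains <- if (length(parts) < 1 || star(parts[1])) NULL
            else strsplit(parts[1], ",")[[1]]
  range <- NULL
  if (length(parts) >= 2 && !star(parts[2])) {
    m <- regmatches(parts[2], regexec("^(-?[0-9]+)-(-?[0-9]+)$", parts[2]))[[1]]
    if (length(m) != 3) stop("bad residue range: ", parts[2])
    range <- as.integer(m[2:3])
  }
  atomNames <- if (length(parts) >= 3 && !star(parts[3]))
    strsplit(parts[3], ",")[[1]] else NULL
  atomSelection(chains, range, atomNames)
}

canonicalAtomOrder <- function(elety) {
  fixed <- c("N", "CA", "C", "O", "CB")
  match(elety, fixed, nomatch = length(fixed) + 1L) * 1e6 +
    match(elety, sort(unique(elety)))
}

#' Resolve a selection against a structure
#'
#' Returns the matching protein atoms ordered by (chain, residue number,
#' canonical atom-name order: N, CA, C, O, CB, then alphabetical) —
#' a deterministic ordering stable across runs. Residues missing within an
#' explicit range are skipped and reported in the `"gaps"` attribute.
#'
#' @param structure a [PDBStructure-class].
#' @param selection an [AtomSelection-class] or selection string for
#'   [parseSelection()].
#' @param includeHet include heteroatoms (default FALSE).
#' @return data.frame of atoms (same columns as [atoms()]) with attribute
#'   `"gaps"`: data.frame of `chain`, `resno` for missing residues in range.
#' @export
resolveSelection <- function(structure, selection, includeHet = FALSE) {
  if (is.character(selection)) selection <- parseSelection(selection)
  a <- atoms(structure)
  if (!includeHet) a <- a[!a$het, ]
  if (length(selection@chains) > 0) {
    missing <- setdiff(selection@chains, a$chain)
    if (length(missing) > 0)
      stop("chains not present in structure: ", paste(missing, collapse = ", "))
    a <- a[a$chain %in% selection@chains, ]
  }
  if (length(selection@range) == 2)
    a <- a[a$resno >= selection@range[1] & a$resno <= selection@range[2], ]
  if (length(selection@atomNames) > 0)
    a <- a[a$elety %in% selection@atomNames, ]
  if (nrow(a) == 0) stop("selection matches zero atoms")
  a <- a[order(a$chain, a$resno, a$insert, canonicalAtomOrder(a$elety)), ]
  rownames(a) <- NULL
  gaps <- data.frame(chain = character(), resno = integer())
  if (length(selection@range) == 2) {
    want <- selection@range[1]:selection@range[2]
    for (ch in unique(a$chain)) {
      absent <- setdiff(want, a$resno[a$chain == ch])
      if (length(absent) > 0)
        gaps <- rbind(gaps, data.frame(chain = ch, resno = absent))
    }
  }
  attr(a, "gaps") <- gaps
  a
}

#' Quick structure summary
#'
#' @param structure a [PDBStructure-class].
#' @return invisible list with chain, residue and atom counts (also printed).
#' @export
structureInfo <- function(structure) {
  a <- atoms(structure)
  res <- unique(a[!a$het, c("chain", "resno", "insert")])
  info <- list(entry = entryId(structure),
               chains = unique(a$chain),
               nResidues = nrow(res),
               nAtoms = nrow(a),
               nHet = sum(a$het),
               residueRange = vapply(split(res$resno, res$chain), range,
                                     numeric(2)))
  show(structure)
  invisible(info)
}
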