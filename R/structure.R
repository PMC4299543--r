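## PDB structures: reading (via bio3d), a small fixed-column writer for
## roundtrips, residue indexing and distance queries.

.ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                    SE = 1.90)

#' Van der Waals radius table
#'
#' Bondi/Chothia-style heavy-atom radii (Angstrom) used by the SASA and
#' electrostatics code. Returned as a named vector so callers can supply a
#' modified copy.
#'
#' @return named numeric vector, element symbol -> radius (A).
#' @export
vdwRadii <- function() .ELEMENT_RADII

.inferElement <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    ## fall back to the first letter of the atom name
    first <- sub("^[0-9]*", "", toupper(trimws(elety[miss])))
    el[miss] <- substr(first, 1, 1)
  }
  el
}

#' Read a protein structure from PDB format
#'
#' Parses ATOM/HETATM fixed-column records (via bio3d). By default waters and
#' hydrogens are dropped and alternate locations are reduced to the
#' highest-occupancy conformer (ties broken by altloc letter), so downstream
#' geometry is deterministic. Chain identifiers and insertion codes are
#' preserved in the residue index.
#'
#' @param source path to a PDB file, or a character vector / single string of
#'   PDB-format text.
#' @param keepWaters,keepHydrogens logical, default FALSE.
#' @param keepHetatm include HETATM records (default TRUE; waters still obey
#'   \code{keepWaters}).
#' @return A \linkS4class{PDBStructure}.
#' @export
readPDBStructure <- function(source, keepWaters = FALSE,
                             keepHydrogens = FALSE, keepHetatm = TRUE) {
  path <- source
  if (length(source) > 1L || grepl("\n", source[1]) ||
      grepl("^(ATOM|HETATM|HEADER|REMARK|CRYST)", source[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(source) > 1L) source
               else strsplit(source, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB input: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (!keepHetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (!keepWaters) a <- a[!a$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  el <- .inferElement(a$elesy, a$elety)
  if (!keepHydrogens) {
    keep <- el != "H" & el != "D"
    a <- a[keep, , drop = FALSE]; el <- el[keep]
  }
  if (nrow(a) == 0L) stop("no ATOM records after filtering")
  atoms <- data.frame(
    serial = a$eleno, name = trimws(a$elety), element = el,
    resName = trimws(a$resid), chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    stringsAsFactors = FALSE)
  ## altloc: keep highest occupancy per (residue, atom name); tie -> letter
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
    ord <- order(key, -atoms$occupancy, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$name)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  new("PDBStructure", atoms = atoms)
}

#' @rdname readPDBStructure
#' @param s a \linkS4class{PDBStructure}.
#' @export
structureAtoms <- function(s) s@atoms

#' Residue keys of a structure
#'
#' One row per residue in atom order: chain, resno, insert, resName and the
#' atom span (firstAtom/lastAtom row indices into \code{structureAtoms}).
#'
#' @param s a \linkS4class{PDBStructure}.
#' @export
residueTable <- function(s) {
  a <- s@atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  idx <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resName = a$resName[first],
             firstAtom = vapply(idx, min, 1L), lastAtom = vapply(idx, max, 1L),
             nAtoms = lengths(idx), row.names = NULL,
             stringsAsFactors = FALSE)
}

setMethod("show", "PDBStructure", function(object) {
  rt <- residueTable(object)
  cat(sprintf("PDBStructure: %d atoms, %d residues, chain(s) %s\n",
              nrow(object@atoms), nrow(rt),
              paste(unique(rt$chain), collapse = ", ")))
})

#' Write a structure in PDB format
#'
#' Fixed-column ATOM records with 3-decimal coordinates; a write-then-read
#' roundtrip reproduces coordinates to the format precision.
#'
#' @param s a \linkS4class{PDBStructure}.
#' @param file output path.
#' @export
writePDBStructure <- function(s, file) {
  a <- s@atoms
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, name4, substr(a$resName, 1, 3),
    substr(a$chain, 1, 1), a$resno %% 10000L,
    ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, a$occupancy, a$b, a$element)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

.atomRowsForResidues <- function(s, resno, chain = NULL, insert = NULL) {
  a <- s@atoms
  sel <- a$resno %in% resno
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(insert)) sel <- sel & a$insert %in% insert
  which(sel)
}

#' Minimum distance from a residue to a region
#'
#' Minimum Euclidean distance over all heavy-atom pairs between one residue
#' and a set of residues (e.g. the activation peptide). A residue contained
#' in the region returns 0. When a chain is not given, residue numbers are
#' matched across all chains.
#'
#' @param s a \linkS4class{PDBStructure}.
#' @param resno residue number of the query residue.
#' @param region integer vector of residue numbers defining the region.
#' @param chain optional chain id restricting both selections.
#' @return distance in Angstrom.
#' @export
minDistanceToRegion <- function(s, resno, region, chain = NULL) {
  if (!length(region)) stop("empty region")
  if (resno %in% region) return(0)
  ri <- .atomRowsForResidues(s, resno, chain)
  gi <- .atomRowsForResidues(s, region, chain)
  if (!length(ri)) stop("residue ", resno, " not in structure")
  if (!length(gi)) stop("no region residues found in structure")
  p <- as.matrix(s@atoms[ri, c("x", "y", "z")])
  q <- as.matrix(s@atoms[gi, c("x", "y", "z")])
  d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * tcrossprod(p, q)
  sqrt(max(0, min(d2)))
}
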