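## Shrake-Rupley solvent-accessible surface area.
##
## Test points are placed on a golden-spiral (Fibonacci) sphere, which is
## quasi-uniform and fully deterministic: no RNG is involved, so SASA values
## are reproducible to the bit for a fixed point count.

## Theoretical maximum accessible surface areas (A^2) of residue X in an
## extended Gly-X-Gly tripeptide (Tien et al. style theoretical values),
## used to normalise absolute SASA into relative exposure.
.MAX_SASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Theoretical maximum SASA per residue type
#'
#' The Gly-X-Gly extended-tripeptide maxima used as denominators for relative
#' solvent accessibility.
#'
#' @return named numeric vector (three-letter residue code -> A^2).
#' @export
maxSASATable <- function() .MAX_SASA

#' Deterministic quasi-uniform sphere points
#'
#' Golden-spiral point set on the unit sphere, used as Shrake-Rupley test
#' points.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by test-point counting: each heavy atom is covered with
#' \code{nPoints} quasi-uniform points on its solvent sphere (van der Waals
#' radius + probe radius); a point is accessible when it lies outside every
#' other atom's solvent sphere. Atom areas are summed into residues.
#' Deterministic for a fixed \code{nPoints}.
#'
#' @param s a \linkS4class{PDBStructure}.
#' @param probeRadius probe radius in Angstrom (default 1.4, water).
#' @param nPoints test points per atom (>= 100; default 960, giving about 1\%
#'   accuracy on isolated spheres).
#' @param radii named radius table, element symbol -> A (default
#'   \code{\link{vdwRadii}}).
#' @return A \linkS4class{SASAProfile}.
#' @export
shrakeRupleySASA <- function(s, probeRadius = 1.4, nPoints = 960L,
                             radii = vdwRadii()) {
  stopifnot(is(s, "PDBStructure"))
  nPoints <- as.integer(nPoints)
  if (nPoints < 100L) stop("nPoints must be >= 100")
  a <- s@atoms
  el <- a$element
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- unname(radii[el]) + probeRadius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  unit <- goldenSpiralPoints(nPoints)
  sasa <- numeric(n)
  ## neighbour search via squared-distance matrix (structures here are small);
  ## atom j can occlude i only if d(i,j) < r_i + r_j
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (!length(nb)) { sasa[i] <- 4 * pi * r[i]^2; next }
    pts <- sweep(unit * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dx <- pts[acc, 1] - xyz[j, 1]
      dy <- pts[acc, 2] - xyz[j, 2]
      dz <- pts[acc, 3] - xyz[j, 3]
      acc[acc] <- dx * dx + dy * dy + dz * dz >= r[j]^2
    }
    sasa[i] <- 4 * pi * r[i]^2 * sum(acc) / nPoints
  }
  atoms <- data.frame(a[, c("serial", "name", "element", "resName", "chain",
                            "resno", "insert")], sasa = sasa,
                      stringsAsFactors = FALSE)
  rt <- residueTable(s)
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  rsasa <- vapply(split(sasa, factor(key, levels = unique(key))), sum, 0)
  res <- data.frame(rt[, c("chain", "resno", "insert", "resName")],
                    sasa = unname(rsasa), relSASA = NA_real_,
                    stringsAsFactors = FALSE)
  new("SASAProfile", atoms = atoms, residues = res,
      probeRadius = probeRadius, nPoints = nPoints)
}

#' Relative solvent accessibility
#'
#' Divides each residue's absolute SASA by the theoretical Gly-X-Gly maximum
#' for its residue type. Fractions can slightly exceed 1 for very exposed
#' residues (the maxima are conformational references, not bounds).
#'
#' @param p a \linkS4class{SASAProfile}.
#' @param maxTable named maxima (three-letter code -> A^2), default
#'   \code{\link{maxSASATable}}.
#' @return The profile with the residue \code{relSASA} column filled.
#' @export
relativeSASA <- function(p, maxTable = maxSASATable()) {
  res <- p@residues
  unknown <- setdiff(unique(res$resName), names(maxTable))
  if (length(unknown))
    stop("no maximum SASA for residue type(s): ",
         paste(unknown, collapse = ", "))
  res$relSASA <- res$sasa / unname(maxTable[res$resName])
  initialize(p, residues = res)
}

#' @rdname relativeSASA
#' @export
residueSASA <- function(p) p@residues

#' @rdname relativeSASA
#' @export
atomSASA <- function(p) p@atoms

#' @rdname relativeSASA
#' @export
totalSASA <- function(p) sum(p@atoms$sasa)

setMethod("show", "SASAProfile", function(object) {
  cat(sprintf("SASAProfile: %d atoms / %d residues, total %.1f A^2 (probe %.2f A, %d points)\n",
              nrow(object@atoms), nrow(object@residues), totalSASA(object),
              object@probeRadius, object@nPoints))
})
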