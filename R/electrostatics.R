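## Screened-Coulomb (Debye-Hueckel) surface potential.
##
## This is a documented approximation to a full Poisson-Boltzmann solve: unit
## integer charges at one representative side-chain atom per charged residue,
## a uniform water dielectric, and exponential salt screening. It reproduces
## the qualitative charge pattern of a protein surface (which is what the
## design pipeline compares), not absolute PB potentials.

.BJERRUM_A <- 7.1  # Bjerrum length in water at 298 K, Angstrom (eps ~78.5)

## representative side-chain atom per charged residue type; first available
## atom wins, Cb then Ca as fallbacks
.CHARGE_ATOMS <- list(
  ASP = c("CG", "CB", "CA"), GLU = c("CD", "CG", "CB", "CA"),
  LYS = c("NZ", "CE", "CB", "CA"), ARG = c("CZ", "NE", "CB", "CA"))
.RES_CHARGE <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)

#' Debye screening parameter
#'
#' kappa (1/Angstrom) from ionic strength, using the Bjerrum length in water
#' at 298 K: \code{kappa = sqrt(8 * pi * lB * NA * I * 1e-27)} with I in
#' mol/L. About 0.104/A at I = 0.1 mol/L.
#'
#' @param ionicStrength mol/L.
#' @export
debyeKappa <- function(ionicStrength) {
  sqrt(8 * pi * .BJERRUM_A * 6.02214076e23 * ionicStrength * 1e-27)
}

#' Place unit point charges on a structure
#'
#' One integer charge per charged residue (Asp/Glu -1, Lys/Arg +1), placed on
#' the representative side-chain atom (Asp CG, Glu CD, Lys NZ, Arg CZ) with
#' CB/CA fallback when side-chain atoms are missing. When \code{seq} is
#' given, residue identities are taken from the sequence at matching
#' canonical numbers instead of from the structure's residue names -- this is
#' how a mutant's charge pattern is projected onto the parent model.
#'
#' @param s a \linkS4class{PDBStructure}.
#' @param seq optional \linkS4class{ProteinSequence} overriding residue
#'   identities by canonical number.
#' @param chain optional chain restriction.
#' @return data.frame: x, y, z (A), charge (+1/-1), resno.
#' @export
assignPointCharges <- function(s, seq = NULL, chain = NULL) {
  rt <- residueTable(s)
  if (!is.null(chain)) rt <- rt[rt$chain %in% chain, , drop = FALSE]
  one2three <- c(D = "ASP", E = "GLU", K = "LYS", R = "ARG")
  out <- vector("list", nrow(rt))
  for (i in seq_len(nrow(rt))) {
    resName <- rt$resName[i]
    if (!is.null(seq)) {
      pos <- rt$resno[i]
      if (pos < seq@firstResidueNumber ||
          pos > seq@firstResidueNumber + length(seq) - 1L) next
      one <- residueAt(seq, pos)
      if (!one %in% names(one2three)) next
      resName <- one2three[[one]]
    }
    if (!resName %in% names(.RES_CHARGE)) next
    rows <- rt$firstAtom[i]:rt$lastAtom[i]
    atoms <- s@atoms[rows, , drop = FALSE]
    pick <- NA_integer_
    for (nm in .CHARGE_ATOMS[[resName]]) {
      hit <- which(atoms$name == nm)
      if (length(hit)) { pick <- hit[1]; break }
    }
    if (is.na(pick)) pick <- 1L  # any atom of the residue as last resort
    out[[i]] <- data.frame(x = atoms$x[pick], y = atoms$y[pick],
                           z = atoms$z[pick],
                           charge = unname(.RES_CHARGE[resName]),
                           resno = rt$resno[i])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      charge = numeric(0), resno = integer(0)))
  do.call(rbind, out)
}

#' Screened-Coulomb potential at sample points
#'
#' \code{phi(p) = lB * sum_i q_i * exp(-kappa * d_i) / d_i} in kT/e, with
#' distances in Angstrom, Bjerrum length 7.1 A (water, 298 K) and kappa from
#' \code{\link{debyeKappa}}. Linear superposition holds exactly. The
#' temperature argument is recorded in the result; the dielectric model is
#' fixed at the 298 K water value (a documented approximation).
#'
#' @param charges data.frame with x, y, z, charge (and optionally resno), as
#'   from \code{\link{assignPointCharges}}.
#' @param points numeric matrix (n x 3) or data.frame with x, y, z columns;
#'   an optional \code{resno} column anchors points to residues.
#' @param ionicStrength mol/L.
#' @param temperature K (recorded only).
#' @return A \linkS4class{PotentialMap}.
#' @export
screenedCoulombPotential <- function(charges, points, ionicStrength = 0,
                                     temperature = 298) {
  pts <- if (is.data.frame(points)) as.matrix(points[, c("x", "y", "z")])
         else as.matrix(points)
  resno <- if (is.data.frame(points) && "resno" %in% names(points))
    points$resno else rep(NA_integer_, nrow(pts))
  q <- charges$charge
  cxyz <- as.matrix(charges[, c("x", "y", "z")])
  kap <- debyeKappa(ionicStrength)
  if (nrow(cxyz)) {
    d2 <- outer(rowSums(pts^2), rowSums(cxyz^2), "+") - 2 * tcrossprod(pts, cxyz)
    d <- sqrt(pmax(d2, 0))
    if (any(d < 0.5))
      stop("sample point within 0.5 A of a charge")
    phi <- as.vector((.BJERRUM_A * exp(-kap * d) / d) %*% q)
  } else {
    phi <- numeric(nrow(pts))
  }
  new("PotentialMap",
      points = data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          potential = phi, resno = resno),
      ionicStrength = ionicStrength, temperature = temperature)
}

#' @rdname screenedCoulombPotential
#' @param map a \linkS4class{PotentialMap}.
#' @export
potentialValues <- function(map) map@points$potential

#' @rdname screenedCoulombPotential
#' @export
potentialPoints <- function(map) map@points

setMethod("show", "PotentialMap", function(object) {
  cat(sprintf("PotentialMap: %d points, I = %.3g mol/L, range %.2f..%.2f kT/e\n",
              nrow(object@points), object@ionicStrength,
              min(object@points$potential), max(object@points$potential)))
})

#' Surface sample points of a structure
#'
#' Sample positions for potential maps: the heavy-atom centers of solvent-
#' exposed residues (relative SASA >= \code{minRelSASA}), pushed outward by
#' the probe radius along the direction from the structure centroid through
#' the atom. Deterministic.
#'
#' @param s a \linkS4class{PDBStructure}.
#' @param sasa optional precomputed \linkS4class{SASAProfile} (with relSASA);
#'   computed at default settings when missing.
#' @param minRelSASA exposure cutoff for anchor residues (default 0.2).
#' @param push outward displacement in Angstrom (default 1.4).
#' @return data.frame x, y, z, resno usable as \code{points} in
#'   \code{\link{screenedCoulombPotential}}.
#' @export
surfaceSamplePoints <- function(s, sasa = NULL, minRelSASA = 0.2, push = 1.4) {
  if (is.null(sasa)) sasa <- relativeSASA(shrakeRupleySASA(s))
  res <- residueSASA(sasa)
  keep <- res[res$relSASA >= minRelSASA, , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      resno = integer(0)))
  a <- s@atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  want <- paste(keep$chain, keep$resno, keep$insert, sep = "|")
  sel <- key %in% want
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  ctr <- colMeans(as.matrix(a[, c("x", "y", "z")]))
  dir <- sweep(xyz, 2, ctr)
  nrm <- sqrt(rowSums(dir^2))
  nrm[nrm < 1e-9] <- 1
  out <- xyz + dir / nrm * push
  data.frame(x = out[, 1], y = out[, 2], z = out[, 3], resno = a$resno[sel])
}

#' Similarity of two potential maps
#'
#' Pearson correlation of potential values over corresponding sample points.
#' The charge patterns of a designed variant and its homolog "match" when
#' this exceeds the constraint threshold (default 0.7).
#'
#' @param a,b \linkS4class{PotentialMap} objects.
#' @param correspondence two-column integer matrix of point indices (row i
#'   pairs point \code{correspondence[i,1]} of \code{a} with
#'   \code{correspondence[i,2]} of \code{b}). Default pairs points by
#'   position, requiring equal lengths.
#' @return correlation in [-1, 1].
#' @export
potentialSimilarity <- function(a, b, correspondence = NULL) {
  va <- potentialValues(a); vb <- potentialValues(b)
  if (is.null(correspondence)) {
    if (length(va) != length(vb))
      stop("maps differ in size; supply an explicit correspondence")
    correspondence <- cbind(seq_along(va), seq_along(vb))
  }
  if (nrow(correspondence) < 3L) stop("need at least 3 corresponding points")
  x <- va[correspondence[, 1]]; y <- vb[correspondence[, 2]]
  if (isTRUE(all.equal(x, y))) return(1)  # identical maps, variance aside
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in potential values")
  cor(x, y)
}

#' Export a potential map as CSV
#'
#' Columns x, y, z, potential_kT_per_e, residue.
#'
#' @param map a \linkS4class{PotentialMap}.
#' @param file output path.
#' @export
writePotentialMapCSV <- function(map, file) {
  p <- map@points
  utils::write.csv(data.frame(x = p$x, y = p$y, z = p$z,
                              potential_kT_per_e = p$potential,
                              residue = p$resno),
                   file, row.names = FALSE)
  invisible(file)
}
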