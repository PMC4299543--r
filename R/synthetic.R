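## Synthetic-data generators. Every generator is a pure function of its
## arguments including the seed: RNG state is saved and restored around each
## call, and all randomness flows from the single seed argument.

## sample k elements from x without base sample()'s length-1 surprise
.safeSample <- function(x, k = length(x)) x[sample.int(length(x), k)]

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Noise specification constructor
#'
#' @param kind "multiplicative" (fractional Gaussian, the default: activity
#'   assays typically have a roughly constant CV) or "additive".
#' @param sigma standard deviation (fraction for multiplicative, data units
#'   for additive). Default 0.05.
#' @param seed integer seed.
#' @return A \linkS4class{NoiseSpec}.
#' @export
noiseSpec <- function(kind = c("multiplicative", "additive"), sigma = 0.05,
                      seed = 1L) {
  new("NoiseSpec", kind = match.arg(kind), sigma = sigma,
      seed = as.integer(seed))
}

.applyNoise <- function(values, noise) {
  if (noise@sigma == 0) return(values)
  .withSeed(noise@seed, {
    eps <- stats::rnorm(length(values), 0, noise@sigma)
    switch(noise@kind,
           additive = values + eps,
           multiplicative = values * (1 + eps))
  })
}

.ONE2THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

## FCC lattice points (nearest-neighbour distance `spacing`) filling a
## compact quasi-spherical blob of exactly n points: all lattice sites sorted
## by distance from the origin (ties broken lexicographically), first n kept.
## Fully deterministic.
.fccBall <- function(n, spacing = 3.8) {
  half <- spacing / sqrt(2)          # cubic half-cell
  m <- ceiling((n * 1.5)^(1/3)) + 2L
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, , drop = FALSE]
  pts <- as.matrix(g) * half
  nrm <- sqrt(rowSums(pts^2))
  ord <- order(nrm, pts[, 1], pts[, 2], pts[, 3])
  pts <- pts[ord, , drop = FALSE]
  if (nrow(pts) < n) stop("lattice too small (internal)")
  pts[seq_len(n), , drop = FALSE]
}

## Build the toy PDBStructure: one CA per residue at its lattice point, plus
## an outward pseudo-side-chain atom (CB) for residues in the surface band.
.toyStructure <- function(pts, resNames, surfaceBand, offset,
                          cbPush = 2.5, chain = "A") {
  n <- nrow(pts)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial, name = "CA", element = "C", resName = resNames[i],
      chain = chain, resno = offset + i - 1L, insert = "",
      x = pts[i, 1], y = pts[i, 2], z = pts[i, 3],
      occupancy = 1, b = 0, stringsAsFactors = FALSE)
    if (surfaceBand[i]) {
      nrm <- sqrt(sum(pts[i, ]^2))
      dir <- if (nrm < 1e-9) c(0, 0, 1) else pts[i, ] / nrm
      ## outward pseudo side chain: centroid (CB) plus tip (CG), the tip
      ## standing in for the charge-bearing end of a charged side chain
      for (sc in list(c("CB", cbPush), c("CG", 2 * cbPush))) {
        serial <- serial + 1L
        push <- as.numeric(sc[2])
        rows[[length(rows) + 1L]] <- data.frame(
          serial = serial, name = sc[1], element = "C", resName = resNames[i],
          chain = chain, resno = offset + i - 1L, insert = "",
          x = pts[i, 1] + push * dir[1], y = pts[i, 2] + push * dir[2],
          z = pts[i, 3] + push * dir[3],
          occupancy = 1, b = 0, stringsAsFactors = FALSE)
      }
    }
  }
  new("PDBStructure", atoms = do.call(rbind, rows))
}

#' Generate a planted-truth homolog pair with a toy structure
#'
#' Emulates the target/homolog comparison the design pipeline consumes: two
#' sequences identical except at planted positions that differ in charge
#' class, plus a toy structure (a compact FCC-lattice ball of pseudo-residues
#' with outward side-chain atoms on the surface) in which the planted
#' "surface" sites are solvent-exposed (relative SASA >= 0.3 for any residue
#' type planted) and far (> 10.5 A) from the activation peptide, while the
#' planted "buried" sites are occluded (relative SASA <= 0.05). Site
#' eligibility is decided from the measured SASA and distances of the built
#' structure, so the planted truth satisfies the design filters by
#' construction for every seed. The first eight residues form a compact
#' surface patch and carry the activation-peptide sequence.
#'
#' @param nResidues total residues (default 60).
#' @param nSurfaceDiffs,nBuriedDiffs planted charge-difference counts
#'   (their sum must be <= nResidues/4).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param offset canonical number of the first residue (default 16, the
#'   zymogen-chain convention in which the activation peptide is 16..23).
#' @return A \linkS4class{PlantedDesignTruth}.
#' @export
genHomologPair <- function(nResidues = 60L, nSurfaceDiffs = 3L,
                           nBuriedDiffs = 1L, seed = 1L, offset = 16L) {
  nResidues <- as.integer(nResidues)
  if (nSurfaceDiffs + nBuriedDiffs > nResidues / 4)
    stop("infeasible planting counts: nSurfaceDiffs + nBuriedDiffs must be <= nResidues/4")
  if (nResidues < 30L) stop("nResidues too small for a two-zone toy structure")
  .withSeed(seed, {
    pts <- .fccBall(nResidues)
    nrm <- sqrt(rowSums(pts^2))
    surfaceBand <- nrm >= max(nrm) - 2.0

    ## activation-peptide patch: the 8 surface points closest to the topmost
    ## surface point (compact patch, so "far from the AP" is satisfiable)
    surfIdx <- which(surfaceBand)
    topPt <- surfIdx[which.max(pts[surfIdx, 3])]
    d2top <- rowSums(sweep(pts[surfIdx, , drop = FALSE], 2, pts[topPt, ])^2)
    apIdx <- surfIdx[order(d2top)][1:8]

    ## residue positions 1..8 are the AP; remaining positions are assigned to
    ## the remaining lattice points in random (seeded) order
    assign <- integer(nResidues)       # residue position -> lattice point
    assign[1:8] <- apIdx[order(d2top[match(apIdx, surfIdx)])]
    rest <- setdiff(seq_len(nResidues), apIdx)
    assign[9:nResidues] <- .safeSample(rest)

    ## background sequence (neutral-ish); AP carries the zymogen motif
    background <- c("A", "G", "L", "V", "I", "F", "N", "Q", "M", "P")
    targetRes <- c(strsplit("APFDDDDK", "")[[1]],
                   sample(background, nResidues - 8L, replace = TRUE))

    ## measure the geometry residues will see (absolute SASA is independent
    ## of residue names: all toy atoms are carbons)
    ptsByPos <- pts[assign, , drop = FALSE]
    bandByPos <- surfaceBand[assign]
    resNames0 <- unname(.ONE2THREE[targetRes])
    struct <- .toyStructure(ptsByPos, resNames0, bandByPos, offset)
    absSasa <- residueSASA(shrakeRupleySASA(struct))$sasa
    apResno <- offset + 0:7

    eligSurface <- which(seq_len(nResidues) > 8L & bandByPos &
                           absSasa >= 0.30 * 274)
    eligSurface <- eligSurface[vapply(eligSurface, function(i)
      minDistanceToRegion(struct, offset + i - 1L, apResno) > 10.5, TRUE)]
    eligBuried <- which(seq_len(nResidues) > 8L & !bandByPos &
                          absSasa <= 0.05 * 129)
    if (length(eligSurface) < nSurfaceDiffs ||
        length(eligBuried) < nBuriedDiffs)
      stop("infeasible planting counts for this geometry: ",
           length(eligSurface), " eligible surface and ",
           length(eligBuried), " eligible buried sites")

    surfPos <- sort(.safeSample(eligSurface, nSurfaceDiffs))
    buriedPos <- sort(.safeSample(eligBuried, nBuriedDiffs))

    ## plant charge-class differences
    classes <- list(neg = c("D", "E"), pos = c("K", "R"),
                    neu = c("A", "L", "N", "Q"))
    homologRes <- targetRes
    for (i in c(surfPos, buriedPos)) {
      pair <- sample(names(classes), 2L)   # two distinct charge classes
      targetRes[i] <- sample(classes[[pair[1]]], 1L)
      homologRes[i] <- sample(classes[[pair[2]]], 1L)
    }

    struct <- .toyStructure(ptsByPos, unname(.ONE2THREE[targetRes]),
                            bandByPos, offset)
    new("PlantedDesignTruth",
        target = proteinSequence(paste0("target_seed", seed),
                                 paste(targetRes, collapse = ""), offset),
        homolog = proteinSequence(paste0("homolog_seed", seed),
                                  paste(homologRes, collapse = ""), offset),
        structure = struct,
        surfaceSites = as.integer(offset + surfPos - 1L),
        buriedSites = as.integer(offset + buriedPos - 1L),
        offset = as.integer(offset))
  })
}

#' Accessors for PlantedDesignTruth
#' @param x a \linkS4class{PlantedDesignTruth}.
#' @export
truthTarget <- function(x) x@target

#' @rdname truthTarget
#' @export
truthHomolog <- function(x) x@homolog

#' @rdname truthTarget
#' @export
truthStructure <- function(x) x@structure

#' @rdname truthTarget
#' @export
truthSurfaceSites <- function(x) x@surfaceSites

#' @rdname truthTarget
#' @export
truthBuriedSites <- function(x) x@buriedSites

setMethod("show", "PlantedDesignTruth", function(object) {
  cat(sprintf("PlantedDesignTruth: %d residues, %d surface / %d buried planted site(s)\n",
              length(object@target), length(object@surfaceSites),
              length(object@buriedSites)))
  cat("  surface:", paste(object@surfaceSites, collapse = ", "),
      "| buried:", paste(object@buriedSites, collapse = ", "), "\n")
})

#' Generate a noisy activation time course
#'
#' Simulates the cascade and applies the noise model; optionally converts the
#' course to activity units via an enzyme spec. Reproducible per seed.
#'
#' @param p a \linkS4class{CascadeParams}.
#' @param tGrid minutes, starting at 0.
#' @param noise a \linkS4class{NoiseSpec} (sigma 0 gives the noiseless
#'   simulation).
#' @param asActivity optional \linkS4class{EnzymeSpec}; when given, the
#'   course is returned in U/mL.
#' @return A \linkS4class{TimeCourse}.
#' @export
genTimeCourse <- function(p, tGrid, noise = noiseSpec(sigma = 0),
                          asActivity = NULL) {
  tc <- simulateCascade(p, tGrid)
  vals <- .applyNoise(tc@value, noise)
  if (!is.null(asActivity))
    timeCourse(tGrid, concentrationToActivity(vals, asActivity), "U_per_mL")
  else
    timeCourse(tGrid, vals, "nmol_per_L")
}

#' Generate a Michaelis-Menten velocity dataset
#'
#' \code{v = kcat * E0 * S / (Km + S)} at the given substrate levels, plus
#' noise. Reproducible per seed.
#'
#' @param km umol/L.
#' @param kcat 1/s.
#' @param e0 enzyme concentration, nmol/L.
#' @param substrateLevels umol/L (positive).
#' @param noise a \linkS4class{NoiseSpec}.
#' @return An \linkS4class{MMDataset}.
#' @export
genMMData <- function(km, kcat, e0, substrateLevels,
                      noise = noiseSpec(sigma = 0)) {
  if (any(substrateLevels <= 0)) stop("substrate levels must be positive")
  v <- kcat * (e0 * 1e-3) * substrateLevels / (km + substrateLevels)
  mmDataset(substrateLevels, .applyNoise(v, noise), e0)
}

#' Build a synthetic sequence with a prescribed charged-residue composition
#'
#' Deterministically constructs a stand-in sequence with exactly
#' \code{nNegative} Asp/Glu and \code{nPositive} Lys/Arg residues and with
#' specific residues pinned at given canonical positions (tokens like
#' \code{"E31"}). Useful for charge-accounting worked examples when only a
#' protein's composition and a handful of positions are known, not its full
#' sequence; the result is synthetic and carries no homology to any real
#' protein.
#'
#' @param nNegative,nPositive required Asp+Glu and Lys+Arg counts.
#' @param anchors character vector of residue/position tokens, e.g.
#'   \code{c("E31", "R122")}.
#' @param length total residues (default 247).
#' @param offset canonical number of the first residue (default 16).
#' @param id sequence id.
#' @return A \linkS4class{ProteinSequence}.
#' @export
genCompositionSequence <- function(nNegative, nPositive,
                                   anchors = character(0), length = 247L,
                                   offset = 16L, id = "synthetic_composition") {
  length <- as.integer(length); offset <- as.integer(offset)
  chars <- rep("G", length)
  if (base::length(anchors)) {
    m <- regmatches(anchors, regexec("^([A-Za-z])([0-9]+)$", anchors))
    if (any(vapply(m, base::length, 1L) != 3L))
      stop("malformed anchor token(s)")
    res <- toupper(vapply(m, `[`, "", 2L))
    pos <- as.integer(vapply(m, `[`, "", 3L))
    idx <- pos - offset + 1L
    if (any(idx < 1L | idx > length)) stop("anchor position outside sequence")
    if (anyDuplicated(idx)) stop("duplicate anchor positions")
    chars[idx] <- res
  }
  free <- which(chars == "G")
  needNeg <- nNegative - sum(chars %in% c("D", "E"))
  needPos <- nPositive - sum(chars %in% c("K", "R"))
  if (needNeg < 0 || needPos < 0)
    stop("anchors already exceed the requested charged counts")
  if (needNeg + needPos > base::length(free))
    stop("sequence too short for the requested composition")
  if (needNeg) chars[free[seq_len(needNeg)]] <- "D"
  if (needPos) chars[free[needNeg + seq_len(needPos)]] <- "K"
  proteinSequence(id, paste(chars, collapse = ""), offset)
}
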