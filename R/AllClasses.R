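## Central S4 classes. Validity methods encode the structural invariants the
## rest of the package relies on; constructors live next to the module code.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## formal charge class of a one-letter residue code: D/E -1, K/R +1, else 0
## (His neutral at the working pH; termini ignored)
.chargeClass <- function(res) {
  ifelse(res %in% c("D", "E"), -1L, ifelse(res %in% c("K", "R"), 1L, 0L))
}

#' ProteinSequence class
#'
#' A one-letter amino-acid sequence with a canonical-numbering offset, the
#' unit of alignment and mutation. Canonical residue numbers (the numbering
#' used in mutation strings such as \code{"E79K"}) are
#' \code{firstResidueNumber + i - 1} for the i-th internal position, so
#' structures and literature numbering can be addressed directly even when
#' the construct does not start at residue 1.
#'
#' @slot id character label.
#' @slot residues single string over the 20 standard one-letter codes.
#' @slot firstResidueNumber integer canonical number of the first residue.
#' @exportClass ProteinSequence
setClass("ProteinSequence",
  representation(id = "character", residues = "character",
                 firstResidueNumber = "integer"))

setValidity("ProteinSequence", function(object) {
  if (length(object@residues) != 1L || nchar(object@residues) < 1L)
    return("residues must be one non-empty string")
  bad <- setdiff(strsplit(object@residues, "")[[1]], .AA20)
  if (length(bad))
    return(paste0("non-standard residue code(s): ", paste(unique(bad), collapse = ", ")))
  if (length(object@firstResidueNumber) != 1L || is.na(object@firstResidueNumber))
    return("firstResidueNumber must be a single integer")
  TRUE
})

#' GlobalAlignment class
#'
#' A global pairwise alignment under an affine gap model. Columns are stored
#' as two parallel integer vectors of internal (1-based) positions, with
#' \code{NA} marking a gap; no column is gap/gap and the non-gap entries of
#' each vector are strictly increasing and cover the sequence exactly once.
#'
#' @slot seqA,seqB the aligned \linkS4class{ProteinSequence} objects.
#' @slot alignedA,alignedB integer vectors (NA = gap), one entry per column.
#' @slot score alignment score in substitution-matrix units.
#' @slot matrixName substitution matrix used (e.g. "BLOSUM62").
#' @slot gapOpen,gapExtend gap penalties (cost of a length-L gap is
#'   \code{gapOpen + (L - 1) * gapExtend}).
#' @exportClass GlobalAlignment
setClass("GlobalAlignment",
  representation(seqA = "ProteinSequence", seqB = "ProteinSequence",
                 alignedA = "integer", alignedB = "integer",
                 score = "numeric", matrixName = "character",
                 gapOpen = "numeric", gapExtend = "numeric"))

setValidity("GlobalAlignment", function(object) {
  a <- object@alignedA; b <- object@alignedB
  if (length(a) != length(b)) return("column vectors differ in length")
  if (any(is.na(a) & is.na(b))) return("gap/gap column present")
  for (v in list(A = a[!is.na(a)], B = b[!is.na(b)])) {
    if (length(v) && (any(diff(v) <= 0))) return("non-increasing positions")
  }
  if (!identical(a[!is.na(a)], seq_len(nchar(object@seqA@residues))))
    return("alignment does not cover sequence A exactly once")
  if (!identical(b[!is.na(b)], seq_len(nchar(object@seqB@residues))))
    return("alignment does not cover sequence B exactly once")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    return("gap penalties must be non-negative")
  TRUE
})

#' MutationSet class
#'
#' An ordered set of point substitutions in canonical numbering, with unique
#' positions. \code{from} must match the sequence a set is applied to; a
#' mismatch signals a numbering-offset error and is a hard failure.
#'
#' @slot position integer canonical positions (unique).
#' @slot from,to one-letter residue codes, parallel to \code{position}.
#' @exportClass MutationSet
setClass("MutationSet",
  representation(position = "integer", from = "character", to = "character"))

setValidity("MutationSet", function(object) {
  n <- length(object@position)
  if (length(object@from) != n || length(object@to) != n)
    return("position/from/to lengths differ")
  if (anyDuplicated(object@position)) return("duplicate mutation positions")
  if (n && (!all(object@from %in% .AA20) || !all(object@to %in% .AA20)))
    return("residue codes must be standard one-letter codes")
  TRUE
})

#' PDBStructure class
#'
#' Heavy-atom coordinates parsed from PDB-format records. One row per atom;
#' the (chain, resno, insert) triple indexes residues. Waters and hydrogens
#' are excluded on reading by default; alternate locations are reduced to the
#' highest-occupancy conformer.
#'
#' @slot atoms data.frame with columns serial, name, element, resName, chain,
#'   resno, insert, x, y, z, occupancy, b.
#' @exportClass PDBStructure
setClass("PDBStructure", representation(atoms = "data.frame"))

setValidity("PDBStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resName", "chain", "resno",
            "insert", "x", "y", "z")
  if (!all(need %in% names(a))) return("missing atom columns")
  if (nrow(a) < 1L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  TRUE
})

#' SASAProfile class
#'
#' Per-atom and per-residue solvent-accessible surface area from the
#' Shrake-Rupley algorithm, optionally with relative (normalised) exposure.
#'
#' @slot atoms data.frame: atom identity plus \code{sasa} (A^2).
#' @slot residues data.frame: chain, resno, insert, resName, sasa, relSASA
#'   (relSASA is NA until \code{\link{relativeSASA}} fills it).
#' @slot probeRadius probe radius in Angstrom.
#' @slot nPoints sphere test points per atom.
#' @exportClass SASAProfile
setClass("SASAProfile",
  representation(atoms = "data.frame", residues = "data.frame",
                 probeRadius = "numeric", nPoints = "integer"))

setValidity("SASAProfile", function(object) {
  if (any(object@residues$sasa < -1e-9)) return("negative residue SASA")
  if (any(object@atoms$sasa < -1e-9)) return("negative atom SASA")
  TRUE
})

#' ChargeProfile class
#'
#' Counts of charged residues and the implied net charge. Negative = Asp+Glu,
#' positive = Lys+Arg, His neutral; \code{netCharge} must always equal
#' \code{nPositive - nNegative} (the invariant is re-checked whenever a
#' profile is produced or shifted).
#'
#' @slot nNegative,nPositive,netCharge integers.
#' @exportClass ChargeProfile
setClass("ChargeProfile",
  representation(nNegative = "integer", nPositive = "integer",
                 netCharge = "integer"))

setValidity("ChargeProfile", function(object) {
  if (object@nNegative < 0L || object@nPositive < 0L)
    return("counts must be non-negative")
  if (object@netCharge != object@nPositive - object@nNegative)
    return("netCharge != nPositive - nNegative")
  TRUE
})

#' PotentialMap class
#'
#' Electrostatic potential (kT/e) sampled at points just outside the solvent-
#' exposed surface, each anchored to a residue canonical number.
#'
#' @slot points data.frame: x, y, z (A), potential (kT/e), resno.
#' @slot ionicStrength mol/L.
#' @slot temperature K (recorded; the dielectric model is fixed at 298 K
#'   water, see \code{\link{screenedCoulombPotential}}).
#' @exportClass PotentialMap
setClass("PotentialMap",
  representation(points = "data.frame", ionicStrength = "numeric",
                 temperature = "numeric"))

setValidity("PotentialMap", function(object) {
  if (nrow(object@points) && !all(is.finite(object@points$potential)))
    return("non-finite potential values")
  if (object@ionicStrength < 0) return("negative ionic strength")
  TRUE
})

#' DesignConstraints class
#'
#' Filters applied to candidate charge-transfer substitutions.
#'
#' @slot minRelSASA minimum relative SASA for "on the surface" (default 0.20).
#' @slot minDistance minimum distance (A, strict >) from the activation
#'   peptide (default 10).
#' @slot activationPeptide integer canonical residue numbers of the
#'   activation peptide; length 0 means "first 8 residues of the chain".
#' @slot forbidHydroxyl if TRUE, homolog residues bearing a hydroxyl (S/T/Y)
#'   are replaced by PTM-safe fallbacks before becoming mutations.
#' @slot similarityThreshold Pearson correlation above which the variant's
#'   potential pattern is reported as matching the homolog's (default 0.7).
#' @exportClass DesignConstraints
setClass("DesignConstraints",
  representation(minRelSASA = "numeric", minDistance = "numeric",
                 activationPeptide = "integer", forbidHydroxyl = "logical",
                 similarityThreshold = "numeric"))

setValidity("DesignConstraints", function(object) {
  if (object@minRelSASA < 0 || object@minDistance < 0)
    return("thresholds must be non-negative")
  TRUE
})

#' DesignReport class
#'
#' Output of \code{\link{proposeChargeTransfer}}: the final mutation set plus
#' the full audit trail (every candidate with its measured filter values and
#' accept/reject provenance), charge profiles before and after, and the
#' predicted potential similarity to the homolog.
#'
#' @slot mutations final \linkS4class{MutationSet}.
#' @slot candidates data.frame, one row per candidate with origin, measured
#'   relSASA and distance, per-filter booleans, acceptance, chosen residue and
#'   any PTM fallback.
#' @slot profileBefore,profileAfter \linkS4class{ChargeProfile}.
#' @slot similarity Pearson correlation of variant vs homolog potential maps
#'   (NA when not computable).
#' @slot constraints the \linkS4class{DesignConstraints} used.
#' @slot mutatedSequence the variant \linkS4class{ProteinSequence}.
#' @exportClass DesignReport
setClass("DesignReport",
  representation(mutations = "MutationSet", candidates = "data.frame",
                 profileBefore = "ChargeProfile", profileAfter = "ChargeProfile",
                 similarity = "numeric", constraints = "DesignConstraints",
                 mutatedSequence = "ProteinSequence"))

#' EnzymeSpec class
#'
#' Identity and conversion constants of an enzyme preparation: molar mass and
#' specific activity link molar concentration to measured activity
#' (1 U = 1 umol substrate/min under assay conditions).
#'
#' @slot name character.
#' @slot molarMass g/mol (> 0).
#' @slot specificActivity U/mg (>= 0).
#' @exportClass EnzymeSpec
setClass("EnzymeSpec",
  representation(name = "character", molarMass = "numeric",
                 specificActivity = "numeric"))

setValidity("EnzymeSpec", function(object) {
  if (object@molarMass <= 0) return("molarMass must be > 0")
  if (object@specificActivity < 0) return("specificActivity must be >= 0")
  TRUE
})

#' TimeCourse class
#'
#' An activation time course: strictly increasing times in minutes and values
#' carrying a mandatory unit tag, either molar active-enzyme concentration
#' (\code{"nmol_per_L"}) or measured activity (\code{"U_per_mL"}).
#'
#' @slot time minutes, strictly increasing, >= 2 points.
#' @slot value finite numeric values.
#' @slot unit "nmol_per_L" or "U_per_mL".
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(time = "numeric", value = "numeric", unit = "character"))

setValidity("TimeCourse", function(object) {
  if (length(object@time) < 2L) return("need >= 2 points")
  if (length(object@time) != length(object@value)) return("time/value lengths differ")
  if (any(diff(object@time) <= 0)) return("times must be strictly increasing")
  if (!all(is.finite(object@value))) return("non-finite values")
  if (!object@unit %in% c("nmol_per_L", "U_per_mL")) return("unknown unit tag")
  TRUE
})

#' CascadeParams class
#'
#' Parameters of the activation cascade: zymogen Tg is converted to active
#' enzyme Tr both by Tr itself (bimolecular rate constant \code{kAuto}) and by
#' a constant pool of activating protease EP (\code{kEp}).
#'
#' @slot kAuto,kEp L/umol/min, >= 0.
#' @slot Tg0 initial zymogen, umol/L.
#' @slot Tr0 initial active enzyme, nmol/L.
#' @slot EP0 activating protease, nmol/L (constant over the course).
#' @exportClass CascadeParams
setClass("CascadeParams",
  representation(kAuto = "numeric", kEp = "numeric", Tg0 = "numeric",
                 Tr0 = "numeric", EP0 = "numeric"))

setValidity("CascadeParams", function(object) {
  v <- c(object@kAuto, object@kEp, object@Tg0, object@Tr0, object@EP0)
  if (any(!is.finite(v)) || any(v < 0)) return("rates and concentrations must be >= 0")
  TRUE
})

#' ActivationRateEstimate class
#'
#' Initial linear slope of an activation time course, in nmol/L/min, with the
#' fitted window and its R^2.
#'
#' @slot rate nmol/L/min.
#' @slot window c(tStart, tEnd) minutes.
#' @slot r2 coefficient of determination of the window fit, in [0, 1].
#' @slot nPoints points in the fitted window.
#' @exportClass ActivationRateEstimate
setClass("ActivationRateEstimate",
  representation(rate = "numeric", window = "numeric", r2 = "numeric",
                 nPoints = "integer"))

setValidity("ActivationRateEstimate", function(object) {
  if (object@r2 < -1e-9 || object@r2 > 1 + 1e-9) return("r2 outside [0, 1]")
  TRUE
})

#' MMDataset class
#'
#' A substrate-velocity dataset for Michaelis-Menten fitting.
#'
#' @slot substrate umol/L.
#' @slot velocity umol/L/s, parallel to substrate.
#' @slot e0 enzyme concentration, nmol/L.
#' @exportClass MMDataset
setClass("MMDataset",
  representation(substrate = "numeric", velocity = "numeric", e0 = "numeric"))

setValidity("MMDataset", function(object) {
  if (length(object@substrate) != length(object@velocity))
    return("substrate/velocity lengths differ")
  if (any(object@substrate <= 0)) return("substrate levels must be positive")
  if (object@e0 <= 0) return("e0 must be positive")
  TRUE
})

#' MMParams class
#'
#' Fitted Michaelis-Menten parameters; \code{efficiency} is kcat/Km.
#'
#' @slot km umol/L (> 0).
#' @slot kcat 1/s (> 0).
#' @slot efficiency L/umol/s, equal to kcat/Km.
#' @slot details list with fit diagnostics (may be empty).
#' @exportClass MMParams
setClass("MMParams",
  representation(km = "numeric", kcat = "numeric", efficiency = "numeric",
                 details = "list"))

setValidity("MMParams", function(object) {
  if (object@km <= 0 || object@kcat <= 0) return("Km and kcat must be > 0")
  if (abs(object@efficiency - object@kcat / object@km) >
      1e-9 * max(1, object@efficiency))
    return("efficiency != kcat/Km")
  TRUE
})

#' NoiseSpec class
#'
#' Noise model for synthetic data: additive or multiplicative Gaussian with a
#' seed, so every generated dataset is a pure function of its arguments.
#'
#' @slot kind "additive" or "multiplicative".
#' @slot sigma standard deviation (absolute units for additive, fractional
#'   for multiplicative), >= 0.
#' @slot seed integer RNG seed.
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(kind = "character", sigma = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (!object@kind %in% c("additive", "multiplicative")) return("unknown noise kind")
  if (object@sigma < 0) return("sigma must be >= 0")
  TRUE
})

#' PlantedDesignTruth class
#'
#' A synthetic design case with known ground truth: a target/homolog sequence
#' pair differing only at planted charge positions, a toy structure in which
#' the planted surface sites are exposed and distant from the activation
#' peptide while the planted buried sites are occluded, and the site lists.
#'
#' @slot target,homolog \linkS4class{ProteinSequence}.
#' @slot structure \linkS4class{PDBStructure} of the target.
#' @slot surfaceSites,buriedSites integer canonical positions (disjoint).
#' @slot offset canonical number of the first residue.
#' @exportClass PlantedDesignTruth
setClass("PlantedDesignTruth",
  representation(target = "ProteinSequence", homolog = "ProteinSequence",
                 structure = "PDBStructure", surfaceSites = "integer",
                 buriedSites = "integer", offset = "integer"))

setValidity("PlantedDesignTruth", function(object) {
  if (length(intersect(object@surfaceSites, object@buriedSites)))
    return("planted site lists must be disjoint")
  TRUE
})
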