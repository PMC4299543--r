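#' Design constraints constructor
#'
#' @param minRelSASA surface filter: minimum relative SASA (default 0.20, a
#'   common exposure cutoff).
#' @param minDistance minimum distance in Angstrom from the activation
#'   peptide, strict (default 10).
#' @param activationPeptide integer canonical residue numbers of the
#'   activation peptide; \code{NULL} (default) means the first 8 residues of
#'   the modelled chain.
#' @param forbidHydroxyl replace hydroxyl-bearing homolog residues (S/T/Y) by
#'   PTM-safe fallbacks (default TRUE).
#' @param similarityThreshold Pearson threshold for calling the variant's
#'   potential pattern matched to the homolog (default 0.7).
#' @return A \linkS4class{DesignConstraints}.
#' @export
designConstraints <- function(minRelSASA = 0.20, minDistance = 10,
                              activationPeptide = NULL,
                              forbidHydroxyl = TRUE,
                              similarityThreshold = 0.7) {
  new("DesignConstraints", minRelSASA = minRelSASA, minDistance = minDistance,
      activationPeptide = as.integer(activationPeptide %||% integer(0)),
      forbidHydroxyl = forbidHydroxyl,
      similarityThreshold = similarityThreshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PTM-safe substitution rule
#'
#' Hydroxyl-bearing residues (Ser, Thr, Tyr) introduced from a homolog risk
#' post-translational modification of the OH group; the rule replaces them
#' with near-isosteric, hydroxyl-free fallbacks: T -> L, S -> A, Y -> N. Any
#' other residue passes through unchanged.
#'
#' @param residue one-letter code(s).
#' @return one-letter code(s) safe to introduce.
#' @examples
#' ptmSafeSubstitution(c("K", "T", "Y"))  # "K" "L" "N"
#' @export
ptmSafeSubstitution <- function(residue) {
  map <- c(S = "A", T = "L", Y = "N")
  out <- toupper(residue)
  hit <- out %in% names(map)
  out[hit] <- map[out[hit]]
  out
}

## aligned homolog residue (or NA) per target canonical position
.homologAtTargetPositions <- function(aln) {
  both <- !is.na(aln@alignedA)
  idxA <- aln@alignedA[both]
  resB <- rep(NA_character_, length(idxA))
  hasB <- !is.na(aln@alignedB[both])
  resB[hasB] <- residues(aln@seqB)[aln@alignedB[both][hasB]]
  stats::setNames(resB, aln@seqA@firstResidueNumber + idxA - 1L)
}

#' Propose a charge-transfer mutation set
#'
#' The rational design pipeline: align target and homolog, collect candidate
#' positions whose charge class differs, measure each candidate's surface
#' exposure (relative SASA) and distance from the activation peptide on the
#' structural model, reject candidates failing either filter, map surviving
#' homolog residues through the PTM-safe substitution rule, and assemble the
#' final mutation set with before/after charge accounting and a predicted
#' potential similarity to the homolog. Every candidate -- accepted or
#' rejected -- is reported with its measured values.
#'
#' In \code{paperReplication} mode two narrative heuristics are added on top
#' of the strict charge-difference rule: (i) aligned positions adjacent
#' (+/-1) to an accepted charge-difference site where the homolog residue
#' differs become "homolog-match" candidates, and (ii) charge-conserving
#' differences at charged positions (e.g. Lys for Arg) are also proposed.
#' Both are reconstructions of choices a designer made case by case, not
#' derivable rules, and are off by default.
#'
#' @param target,homolog \linkS4class{ProteinSequence} objects; structure
#'   residue numbers must match the target's canonical numbering.
#' @param model \linkS4class{PDBStructure} of the target (or a template with
#'   target numbering).
#' @param constraints a \linkS4class{DesignConstraints}.
#' @param paperReplication enable the heuristics above (default FALSE).
#' @param chain optional chain id of the modelled target chain.
#' @param ionicStrength mol/L for the potential-similarity maps (default 0.1).
#' @param matrix,gapOpen,gapExtend alignment parameters, see
#'   \code{\link{globalAlign}}.
#' @return A \linkS4class{DesignReport}.
#' @export
proposeChargeTransfer <- function(target, homolog, model,
                                  constraints = designConstraints(),
                                  paperReplication = FALSE, chain = NULL,
                                  ionicStrength = 0.1,
                                  matrix = "BLOSUM62", gapOpen = 10,
                                  gapExtend = 0.5) {
  aln <- globalAlign(target, homolog, matrix = matrix, gapOpen = gapOpen,
                     gapExtend = gapExtend)
  sites <- chargeDiffSites(aln)
  homAt <- .homologAtTargetPositions(aln)

  sasa <- relativeSASA(shrakeRupleySASA(model))
  res <- residueSASA(sasa)
  if (!is.null(chain)) res <- res[res$chain %in% chain, , drop = FALSE]
  ap <- constraints@activationPeptide
  if (!length(ap)) {
    rt <- residueTable(model)
    if (!is.null(chain)) rt <- rt[rt$chain %in% chain, , drop = FALSE]
    ap <- utils::head(rt$resno, 8L)
  }

  measure <- function(pos) {
    row <- which(res$resno == pos)
    if (!length(row))
      stop("candidate position ", pos,
           " not present in the structural model (numbering offset?)")
    c(relSASA = res$relSASA[row[1]],
      distance = minDistanceToRegion(model, pos, ap, chain = chain))
  }

  cand <- data.frame(position = integer(0), targetResidue = character(0),
                     homologResidue = character(0), origin = character(0),
                     stringsAsFactors = FALSE)
  if (nrow(sites))
    cand <- data.frame(position = sites$position,
                       targetResidue = sites$targetResidue,
                       homologResidue = sites$homologResidue,
                       origin = "charge-diff", stringsAsFactors = FALSE)

  evalCand <- function(cand) {
    n <- nrow(cand)
    cand$relSASA <- cand$distance <- rep(NA_real_, n)
    cand$passSASA <- cand$passDistance <- rep(NA, n)
    for (i in seq_len(n)) {
      m <- measure(cand$position[i])
      cand$relSASA[i] <- m[["relSASA"]]
      cand$distance[i] <- m[["distance"]]
      cand$passSASA[i] <- m[["relSASA"]] >= constraints@minRelSASA
      cand$passDistance[i] <- m[["distance"]] > constraints@minDistance
    }
    cand
  }
  cand <- evalCand(cand)
  cand$accepted <- cand$passSASA & cand$passDistance

  if (paperReplication) {
    extra <- list()
    tpos <- canonicalPositions(target)
    ## (i) neighbours of accepted charge-diff sites where the homolog differs
    for (p in cand$position[cand$accepted]) {
      for (q in c(p - 1L, p + 1L)) {
        if (!q %in% tpos || q %in% cand$position) next
        hb <- homAt[as.character(q)]
        if (is.na(hb) || hb == residueAt(target, q)) next
        extra[[length(extra) + 1L]] <- data.frame(
          position = q, targetResidue = residueAt(target, q),
          homologResidue = unname(hb), origin = "homolog-match",
          stringsAsFactors = FALSE)
      }
    }
    ## (ii) charge-conserving residue differences at charged positions
    for (p in tpos) {
      if (p %in% cand$position) next
      hb <- homAt[as.character(p)]
      ta <- residueAt(target, p)
      if (is.na(hb) || hb == ta) next
      if (.chargeClass(ta) != 0L && .chargeClass(hb) == .chargeClass(ta)) {
        extra[[length(extra) + 1L]] <- data.frame(
          position = p, targetResidue = ta, homologResidue = unname(hb),
          origin = "homolog-match", stringsAsFactors = FALSE)
      }
    }
    if (length(extra)) {
      extra <- unique(do.call(rbind, extra))
      extra <- evalCand(extra)
      extra$accepted <- extra$passSASA & extra$passDistance
      cand <- rbind(cand, extra)
    }
  }

  ## PTM-safe residue choice + rejection bookkeeping
  n <- nrow(cand)
  cand$toResidue <- rep(NA_character_, n)
  cand$fallback <- rep(NA_character_, n)
  cand$reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    to <- cand$homologResidue[i]
    if (constraints@forbidHydroxyl) {
      safe <- ptmSafeSubstitution(to)
      if (safe != to) {
        cand$fallback[i] <- paste0(to, "->", safe)
        to <- safe
      }
    }
    cand$toResidue[i] <- to
    if (!cand$accepted[i]) {
      rs <- character(0)
      if (!cand$passSASA[i])
        rs <- c(rs, sprintf("relSASA %.3f < %.2f", cand$relSASA[i],
                            constraints@minRelSASA))
      if (!cand$passDistance[i])
        rs <- c(rs, sprintf("distance %.2f A <= %.1f A", cand$distance[i],
                            constraints@minDistance))
      cand$reason[i] <- paste(rs, collapse = "; ")
    } else if (to == cand$targetResidue[i]) {
      cand$accepted[i] <- FALSE
      cand$reason[i] <- "PTM-safe fallback equals target residue"
    }
  }
  cand <- cand[order(cand$position), , drop = FALSE]
  rownames(cand) <- NULL

  acc <- cand[cand$accepted, , drop = FALSE]
  muts <- mutationSet(acc$position, acc$targetResidue, acc$toResidue)
  mutated <- applyMutations(target, muts, id = paste0(target@id, "_sc"))
  before <- chargeProfile(target)
  after <- chargeProfile(mutated)

  ## predicted potential pattern of the variant vs the homolog, on the model
  sim <- NA_real_
  pts <- surfaceSamplePoints(model, sasa = sasa,
                             minRelSASA = constraints@minRelSASA)
  if (nrow(pts) >= 3L) {
    homologOnModel <- proteinSequence(
      homolog@id,
      paste(vapply(canonicalPositions(target), function(p) {
        hb <- homAt[as.character(p)]
        if (is.na(hb)) residueAt(target, p) else unname(hb)
      }, ""), collapse = ""),
      target@firstResidueNumber)
    qMut <- assignPointCharges(model, seq = mutated, chain = chain)
    qHom <- assignPointCharges(model, seq = homologOnModel, chain = chain)
    sim <- tryCatch(
      potentialSimilarity(
        screenedCoulombPotential(qMut, pts, ionicStrength),
        screenedCoulombPotential(qHom, pts, ionicStrength)),
      error = function(e) NA_real_)
  }

  new("DesignReport", mutations = muts, candidates = cand,
      profileBefore = before, profileAfter = after, similarity = sim,
      constraints = constraints, mutatedSequence = mutated)
}

#' Accessors for DesignReport
#' @param report a \linkS4class{DesignReport}.
#' @export
designMutations <- function(report) report@mutations

#' @rdname designMutations
#' @export
designCandidates <- function(report) report@candidates

#' @rdname designMutations
#' @export
designSimilarity <- function(report) report@similarity

#' @rdname designMutations
#' @export
designProfiles <- function(report) {
  list(before = report@profileBefore, after = report@profileAfter)
}

setMethod("show", "DesignReport", function(object) {
  cat(sprintf("DesignReport: %d candidate(s), %d accepted\n",
              nrow(object@candidates), length(object@mutations)))
  if (length(object@mutations))
    cat("  mutations:", paste(formatMutations(object@mutations),
                              collapse = ", "), "\n")
  cat(sprintf("  charge: %d-/%d+ (net %+d) -> %d-/%d+ (net %+d)\n",
              object@profileBefore@nNegative, object@profileBefore@nPositive,
              object@profileBefore@netCharge, object@profileAfter@nNegative,
              object@profileAfter@nPositive, object@profileAfter@netCharge))
  cat(sprintf("  potential similarity vs homolog: %s (threshold %.2f)\n",
              ifelse(is.na(object@similarity), "NA",
                     sprintf("%.3f", object@similarity)),
              object@constraints@similarityThreshold))
})

#' Audit a design report
#'
#' Independent consistency gate before a report is trusted: re-applies the
#' mutation set to the target, recomputes the charge profile and checks it
#' against the reported one (and against the shift predicted by the
#' per-mutation charge deltas), and verifies that every accepted candidate
#' passed all filters and that every mutation traces back to a candidate.
#' Any inconsistency is a hard failure naming the offending site.
#'
#' @param report a \linkS4class{DesignReport}.
#' @param target the \linkS4class{ProteinSequence} the report was built from.
#' @return The validated report, invisibly.
#' @export
auditDesign <- function(report, target) {
  muts <- report@mutations
  mutated <- applyMutations(target, muts)
  prof <- chargeProfile(mutated)
  want <- report@profileAfter
  if (prof@nNegative != want@nNegative || prof@nPositive != want@nPositive)
    stop("charge-profile mismatch on re-application: recomputed ",
         prof@nNegative, "-/", prof@nPositive, "+ vs reported ",
         want@nNegative, "-/", want@nPositive, "+")
  shifted <- shiftChargeProfile(report@profileBefore, muts)
  if (shifted@netCharge != want@netCharge)
    stop("charge-delta accounting mismatch: shifted net ", shifted@netCharge,
         " vs reported net ", want@netCharge)
  cand <- report@candidates
  for (p in muts@position) {
    row <- which(cand$position == p)
    if (!length(row))
      stop("mutation at position ", p, " has no candidate record")
    if (!all(cand$passSASA[row[1]], cand$passDistance[row[1]],
             cand$accepted[row[1]]))
      stop("filter audit failure at position ", p,
           ": accepted mutation with failed filter flags")
  }
  bad <- cand$position[cand$accepted & !cand$position %in% muts@position]
  if (length(bad))
    stop("accepted candidate(s) missing from mutation set at position ",
         paste(bad, collapse = ", "))
  invisible(report)
}

#' Write a design report to JSON and TSV
#'
#' JSON carries the full report (mutations, per-candidate audit trail, charge
#' profiles, similarity, constraint echo); the TSV is the candidate table.
#' Requires the jsonlite package.
#'
#' @param report a \linkS4class{DesignReport}.
#' @param jsonFile,tsvFile output paths (either may be NULL to skip).
#' @export
writeDesignReport <- function(report, jsonFile = NULL, tsvFile = NULL) {
  if (!is.null(tsvFile))
    utils::write.table(report@candidates, tsvFile, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(jsonFile)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON export")
    obj <- list(
      mutations = formatMutations(report@mutations),
      candidates = report@candidates,
      chargeBefore = list(negative = report@profileBefore@nNegative,
                          positive = report@profileBefore@nPositive,
                          net = report@profileBefore@netCharge),
      chargeAfter = list(negative = report@profileAfter@nNegative,
                         positive = report@profileAfter@nPositive,
                         net = report@profileAfter@netCharge),
      similarity = report@similarity,
      constraints = list(minRelSASA = report@constraints@minRelSASA,
                         minDistance = report@constraints@minDistance,
                         activationPeptide = report@constraints@activationPeptide,
                         forbidHydroxyl = report@constraints@forbidHydroxyl,
                         similarityThreshold = report@constraints@similarityThreshold))
    jsonlite::write_json(obj, jsonFile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
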