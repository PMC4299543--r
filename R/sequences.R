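#' Create a ProteinSequence
#'
#' @param id character label.
#' @param residues one-letter amino-acid string (20 standard codes).
#' @param firstResidueNumber canonical number of the first residue. Mutation
#'   strings, charge-difference sites and design reports all use canonical
#'   numbering, so sequences that begin mid-construct (e.g. a zymogen chain
#'   numbered from 16 in the chymotrypsin convention) keep their literature
#'   numbering.
#' @return A \linkS4class{ProteinSequence}.
#' @examples
#' proteinSequence("toy", "APFDDDDKIVGG", firstResidueNumber = 16)
#' @export
proteinSequence <- function(id, residues, firstResidueNumber = 1L) {
  new("ProteinSequence", id = as.character(id),
      residues = toupper(as.character(residues)),
      firstResidueNumber = as.integer(firstResidueNumber))
}

#' @describeIn proteinSequence sequence length (number of residues)
#' @param x a ProteinSequence.
#' @export
setMethod("length", "ProteinSequence", function(x) nchar(x@residues))

#' @export
setMethod("as.character", "ProteinSequence", function(x) x@residues)

setMethod("show", "ProteinSequence", function(object) {
  n <- nchar(object@residues)
  cat(sprintf("ProteinSequence '%s': %d residues, canonical %d..%d\n",
              object@id, n, object@firstResidueNumber,
              object@firstResidueNumber + n - 1L))
  cat(" ", if (n > 60) paste0(substr(object@residues, 1, 57), "...")
      else object@residues, "\n")
})

#' Accessors for ProteinSequence
#'
#' \code{seqId}, \code{residues} and \code{firstResidueNumber} read the slots;
#' \code{residueAt} returns the one-letter code at a canonical position.
#'
#' @param x a \linkS4class{ProteinSequence}.
#' @return character / integer scalars or vectors.
#' @export
seqId <- function(x) x@id

#' @rdname seqId
#' @export
residues <- function(x) strsplit(x@residues, "")[[1]]

#' @rdname seqId
#' @export
firstResidueNumber <- function(x) x@firstResidueNumber

#' @rdname seqId
#' @param position canonical residue number(s).
#' @export
residueAt <- function(x, position) {
  i <- position - x@firstResidueNumber + 1L
  if (any(i < 1L | i > length(x)))
    stop("canonical position ", paste(position[i < 1L | i > length(x)],
         collapse = ", "), " outside sequence '", x@id, "'")
  substring(x@residues, i, i)
}

#' Canonical residue numbers of a sequence
#' @param x a \linkS4class{ProteinSequence}.
#' @export
canonicalPositions <- function(x) {
  x@firstResidueNumber + seq_len(length(x)) - 1L
}

## ---- FASTA I/O (Biostrings behind the interface) ----

#' Read protein sequences from FASTA
#'
#' Multi-record FASTA reader; the first whitespace-delimited token of each
#' description line becomes the id. All records are returned as a list of
#' \linkS4class{ProteinSequence} objects with the given numbering offset.
#'
#' @param file path to a FASTA file.
#' @param firstResidueNumber canonical number of the first residue, recycled
#'   across records.
#' @return list of \linkS4class{ProteinSequence}.
#' @export
readProteinFasta <- function(file, firstResidueNumber = 1L) {
  set <- Biostrings::readAAStringSet(file)
  if (length(set) == 0L) stop("no FASTA records in ", file)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  off <- rep_len(as.integer(firstResidueNumber), length(set))
  lapply(seq_along(set), function(i)
    proteinSequence(ids[i], as.character(set[[i]]), off[i]))
}

#' Write protein sequences to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param seqs a \linkS4class{ProteinSequence} or list of them.
#' @param file output path.
#' @export
writeProteinFasta <- function(seqs, file) {
  if (is(seqs, "ProteinSequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, function(s) s@residues, ""))
  names(set) <- vapply(seqs, function(s) s@id, "")
  Biostrings::writeXStringSet(set, file, width = 60L)
  invisible(file)
}

## ---- charge profiles from sequences ----

#' Charge profile of a sequence or composition
#'
#' Counts negatively charged residues (Asp, Glu), positively charged residues
#' (Lys, Arg) and the net charge (positives minus negatives). Histidine is
#' counted as neutral and terminal charges are ignored.
#'
#' @param x a \linkS4class{ProteinSequence}.
#' @return A \linkS4class{ChargeProfile}.
#' @examples
#' chargeProfile(proteinSequence("x", "DEKRH"))  # 2 neg, 2 pos, net 0
#' @export
chargeProfile <- function(x) {
  cls <- .chargeClass(residues(x))
  chargeProfileFromCounts(sum(cls == -1L), sum(cls == 1L))
}

#' @rdname chargeProfile
#' @param nNegative,nPositive charged-residue counts, for building a profile
#'   from a published composition rather than a sequence.
#' @export
chargeProfileFromCounts <- function(nNegative, nPositive) {
  new("ChargeProfile", nNegative = as.integer(nNegative),
      nPositive = as.integer(nPositive),
      netCharge = as.integer(nPositive) - as.integer(nNegative))
}

#' @rdname chargeProfile
#' @export
nNegative <- function(x) x@nNegative

#' @rdname chargeProfile
#' @export
nPositive <- function(x) x@nPositive

#' @rdname chargeProfile
#' @export
netCharge <- function(x) x@netCharge

setMethod("show", "ChargeProfile", function(object) {
  cat(sprintf("ChargeProfile: %d negative (D/E), %d positive (K/R), net %+d\n",
              object@nNegative, object@nPositive, object@netCharge))
})

#' Shift a charge profile by a mutation set
#'
#' Applies the per-mutation charge deltas of a \linkS4class{MutationSet} to a
#' \linkS4class{ChargeProfile} without touching a sequence. This is the
#' charge-accounting identity used by the design audit: the profile of a
#' mutated sequence must equal the shifted profile of the original.
#'
#' @param profile a \linkS4class{ChargeProfile}.
#' @param muts a \linkS4class{MutationSet}.
#' @return The shifted \linkS4class{ChargeProfile}.
#' @export
shiftChargeProfile <- function(profile, muts) {
  fromCls <- .chargeClass(muts@from)
  toCls <- .chargeClass(muts@to)
  dNeg <- sum(toCls == -1L) - sum(fromCls == -1L)
  dPos <- sum(toCls == 1L) - sum(fromCls == 1L)
  chargeProfileFromCounts(profile@nNegative + dNeg, profile@nPositive + dPos)
}
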