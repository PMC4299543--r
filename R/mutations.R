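#' Build, parse and format mutation sets
#'
#' A \linkS4class{MutationSet} holds point substitutions in canonical
#' numbering. \code{parseMutations} reads the usual text form ("E79K",
#' comma- or whitespace-separated); \code{formatMutations} writes it back.
#'
#' @param position integer canonical positions.
#' @param from,to one-letter residue codes.
#' @return A \linkS4class{MutationSet}.
#' @examples
#' parseMutations("E31A, E32A, N33H")
#' @export
mutationSet <- function(position = integer(0), from = character(0),
                        to = character(0)) {
  o <- order(position)
  new("MutationSet", position = as.integer(position)[o],
      from = toupper(from)[o], to = toupper(to)[o])
}

#' @rdname mutationSet
#' @param text mutation tokens like \code{"E79K"}, separated by commas and/or
#'   whitespace.
#' @export
parseMutations <- function(text) {
  tokens <- unlist(strsplit(text, "[,;[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(mutationSet())
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- tokens[vapply(m, length, 1L) != 4L]
  if (length(bad))
    stop("malformed mutation token(s): ", paste(bad, collapse = ", "))
  mutationSet(position = as.integer(vapply(m, `[`, "", 3L)),
              from = toupper(vapply(m, `[`, "", 2L)),
              to = toupper(vapply(m, `[`, "", 4L)))
}

#' @rdname mutationSet
#' @param muts a \linkS4class{MutationSet}.
#' @export
formatMutations <- function(muts) {
  paste0(muts@from, muts@position, muts@to)
}

#' @export
setMethod("length", "MutationSet", function(x) length(x@position))

setMethod("show", "MutationSet", function(object) {
  cat(sprintf("MutationSet with %d substitution(s)", length(object@position)))
  if (length(object@position))
    cat(": ", paste(formatMutations(object), collapse = ", "), sep = "")
  cat("\n")
})

#' Accessors for MutationSet
#' @param x a \linkS4class{MutationSet}.
#' @export
mutationPositions <- function(x) x@position

#' @rdname mutationPositions
#' @export
mutationFrom <- function(x) x@from

#' @rdname mutationPositions
#' @export
mutationTo <- function(x) x@to

#' Apply a mutation set to a sequence
#'
#' Returns a new sequence differing from \code{seq} exactly at the mutated
#' canonical positions. Each mutation's \code{from} residue must match the
#' sequence; a mismatch usually means a numbering-offset error and stops with
#' an informative message.
#'
#' @param seq a \linkS4class{ProteinSequence}.
#' @param muts a \linkS4class{MutationSet}.
#' @param id id for the mutated sequence (default: original id + "_mut").
#' @return The mutated \linkS4class{ProteinSequence}.
#' @export
applyMutations <- function(seq, muts, id = paste0(seq@id, "_mut")) {
  if (!length(muts)) return(proteinSequence(id, seq@residues,
                                            seq@firstResidueNumber))
  idx <- muts@position - seq@firstResidueNumber + 1L
  out <- idx < 1L | idx > length(seq)
  if (any(out))
    stop("mutation position(s) outside sequence: ",
         paste(muts@position[out], collapse = ", "))
  chars <- residues(seq)
  mism <- chars[idx] != muts@from
  if (any(mism))
    stop("from-residue mismatch (numbering offset?): expected ",
         paste(paste0(muts@from[mism], muts@position[mism]), collapse = ", "),
         " but sequence has ",
         paste(paste0(chars[idx][mism], muts@position[mism]), collapse = ", "))
  chars[idx] <- muts@to
  proteinSequence(id, paste(chars, collapse = ""), seq@firstResidueNumber)
}

#' Reverse a mutation set
#'
#' Swaps \code{from} and \code{to}; applying a set and then its reverse
#' restores the original sequence.
#'
#' @param muts a \linkS4class{MutationSet}.
#' @export
reverseMutations <- function(muts) {
  mutationSet(muts@position, from = muts@to, to = muts@from)
}
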