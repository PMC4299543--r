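## Global affine-gap alignment (Gotoh three-state dynamic programming).
##
## Gap model: a gap of length L costs gapOpen + (L - 1) * gapExtend, i.e. the
## opening position carries the full open penalty and each further position
## one extension. The brute-force oracle used in the tests scores alignments
## under the same model; Biostrings::pairwiseAlignment reproduces the scores
## with gapOpening = gapOpen - gapExtend.

.getSubMatrix <- function(name) {
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (is.matrix(name)) return(name)
  if (!name %in% known)
    stop("unknown substitution matrix '", name, "'")
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment of two protein sequences under an
#' affine gap model (a gap of length L costs \code{gapOpen + (L-1) *
#' gapExtend}). Among equally optimal alignments the traceback prefers the
#' substitution state over gaps (high-road convention), which makes the
#' result deterministic. Defaults (BLOSUM62, 10/0.5) approximate the ClustalW
#' protein defaults.
#'
#' @param a,b \linkS4class{ProteinSequence} objects (a = target, b = homolog
#'   in the design pipeline).
#' @param matrix substitution matrix name known to Biostrings (e.g.
#'   "BLOSUM62") or a numeric matrix with residue dimnames.
#' @param gapOpen,gapExtend non-negative gap penalties.
#' @return A \linkS4class{GlobalAlignment}.
#' @examples
#' a <- proteinSequence("a", "KR"); b <- proteinSequence("b", "KD")
#' alignmentScore(globalAlign(a, b))  # 5 + (-2) = 3 under BLOSUM62
#' @export
globalAlign <- function(a, b, matrix = "BLOSUM62", gapOpen = 10,
                        gapExtend = 0.5) {
  stopifnot(is(a, "ProteinSequence"), is(b, "ProteinSequence"))
  sm <- .getSubMatrix(matrix)
  ra <- residues(a); rb <- residues(b)
  if (!all(ra %in% rownames(sm)) || !all(rb %in% colnames(sm)))
    stop("residue not covered by substitution matrix")
  n <- length(ra); m <- length(rb)
  NEG <- -1e18
  ## three DP layers: M (substitution), X (gap in b, consumes a), Y (gap in a)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n) X[2:(n + 1L), 1L] <- -gapOpen - (seq_len(n) - 1L) * gapExtend
  if (m) Y[1L, 2:(m + 1L)] <- -gapOpen - (seq_len(m) - 1L) * gapExtend
  ## traceback: which predecessor layer (1=M, 2=X, 3=Y) was chosen
  tbM <- matrix(0L, n + 1L, m + 1L)
  tbX <- matrix(0L, n + 1L, m + 1L)
  tbY <- matrix(0L, n + 1L, m + 1L)
  subScore <- sm[ra, rb, drop = FALSE]
  for (i in seq_len(n)) {
    ii <- i + 1L
    for (j in seq_len(m)) {
      jj <- j + 1L
      ## M: diagonal from any layer (prefer M on ties)
      cand <- c(M[ii - 1L, jj - 1L], X[ii - 1L, jj - 1L], Y[ii - 1L, jj - 1L])
      k <- which.max(cand)
      M[ii, jj] <- cand[k] + subScore[i, j]
      tbM[ii, jj] <- k
      ## X: consume a_i against a gap; opening from M/Y, extension from X
      cand <- c(M[ii - 1L, jj] - gapOpen, X[ii - 1L, jj] - gapExtend,
                Y[ii - 1L, jj] - gapOpen)
      k <- which.max(cand)
      X[ii, jj] <- cand[k]
      tbX[ii, jj] <- k
      ## Y: consume b_j against a gap
      cand <- c(M[ii, jj - 1L] - gapOpen, X[ii, jj - 1L] - gapOpen,
                Y[ii, jj - 1L] - gapExtend)
      k <- which.max(cand)
      Y[ii, jj] <- cand[k]
      tbY[ii, jj] <- k
    }
  }
  fin <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  layer <- which.max(fin)
  score <- fin[layer]
  ## traceback
  ai <- integer(0); bi <- integer(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i == 0L) { ai <- c(NA_integer_, ai); bi <- c(j, bi); j <- j - 1L; next }
    if (j == 0L) { ai <- c(i, ai); bi <- c(NA_integer_, bi); i <- i - 1L; next }
    if (layer == 1L) {
      prev <- tbM[i + 1L, j + 1L]
      ai <- c(i, ai); bi <- c(j, bi); i <- i - 1L; j <- j - 1L
    } else if (layer == 2L) {
      prev <- tbX[i + 1L, j + 1L]
      ai <- c(i, ai); bi <- c(NA_integer_, bi); i <- i - 1L
    } else {
      prev <- tbY[i + 1L, j + 1L]
      ai <- c(NA_integer_, ai); bi <- c(j, bi); j <- j - 1L
    }
    layer <- prev
  }
  new("GlobalAlignment", seqA = a, seqB = b, alignedA = ai, alignedB = bi,
      score = score,
      matrixName = if (is.character(matrix)) matrix else "custom",
      gapOpen = gapOpen, gapExtend = gapExtend)
}

#' @rdname globalAlign
#' @param aln a \linkS4class{GlobalAlignment}.
#' @export
alignmentScore <- function(aln) aln@score

#' @rdname globalAlign
#' @export
nColumns <- function(aln) length(aln@alignedA)

setMethod("show", "GlobalAlignment", function(object) {
  cat(sprintf("GlobalAlignment %s vs %s: %d columns, score %.1f (%s, gap %g/%g)\n",
              object@seqA@id, object@seqB@id, length(object@alignedA),
              object@score, object@matrixName, object@gapOpen, object@gapExtend))
  cat(sprintf("  identity %.1f%% over aligned columns\n",
              100 * percentIdentity(object)))
})

## residue characters per column (NA index -> "-")
.alignedChars <- function(seq, idx) {
  r <- residues(seq)
  out <- rep("-", length(idx))
  out[!is.na(idx)] <- r[idx[!is.na(idx)]]
  out
}

#' Percent identity of a global alignment
#'
#' Identical-residue columns divided by a denominator that defaults to the
#' number of columns where both sequences have a residue (gap columns
#' excluded). Alternative conventions are selectable: \code{"shorter"}
#' divides by the shorter sequence length, \code{"alignment"} by the total
#' number of alignment columns.
#'
#' @param aln a \linkS4class{GlobalAlignment}.
#' @param denominator one of "aligned", "shorter", "alignment".
#' @return identity fraction in [0, 1].
#' @export
percentIdentity <- function(aln,
                            denominator = c("aligned", "shorter", "alignment")) {
  denominator <- match.arg(denominator)
  ca <- .alignedChars(aln@seqA, aln@alignedA)
  cb <- .alignedChars(aln@seqB, aln@alignedB)
  both <- !is.na(aln@alignedA) & !is.na(aln@alignedB)
  ident <- sum(both & ca == cb)
  den <- switch(denominator,
    aligned = sum(both),
    shorter = min(length(aln@seqA), length(aln@seqB)),
    alignment = length(ca))
  if (den == 0L) stop("alignment has no non-gap columns")
  ident / den
}

#' Charge-differing sites between two aligned sequences
#'
#' Scans the non-gap columns of a target/homolog alignment and reports every
#' position where the formal charge class differs (Asp/Glu = -1, Lys/Arg =
#' +1, all else 0). Positions are reported in the target's canonical
#' numbering, ascending. These are the raw candidates of the charge-transfer
#' design pipeline.
#'
#' @param aln a \linkS4class{GlobalAlignment} of target (A) vs homolog (B).
#' @return data.frame with columns \code{position} (target canonical),
#'   \code{targetResidue}, \code{homologResidue}, \code{targetCharge},
#'   \code{homologCharge}, \code{deltaCharge} (homolog - target).
#' @export
chargeDiffSites <- function(aln) {
  ca <- .alignedChars(aln@seqA, aln@alignedA)
  cb <- .alignedChars(aln@seqB, aln@alignedB)
  both <- which(!is.na(aln@alignedA) & !is.na(aln@alignedB))
  qa <- .chargeClass(ca[both]); qb <- .chargeClass(cb[both])
  keep <- qa != qb
  idxA <- aln@alignedA[both[keep]]
  out <- data.frame(
    position = aln@seqA@firstResidueNumber + idxA - 1L,
    targetResidue = ca[both[keep]],
    homologResidue = cb[both[keep]],
    targetCharge = qa[keep],
    homologCharge = qb[keep],
    deltaCharge = qb[keep] - qa[keep],
    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}
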