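test_that("ProteinSequence enforces the residue alphabet and canonical numbering", {
  s <- proteinSequence("tg", "APFDDDDKIVGG", firstResidueNumber = 16)
  expect_equal(length(s), 12L)
  expect_equal(canonicalPositions(s), 16:27)
  expect_equal(residueAt(s, 16), "A")
  expect_equal(residueAt(s, 23), "K")
  expect_error(residueAt(s, 15), "outside")
  expect_error(proteinSequence("bad", "ACDX"), "non-standard")
  expect_error(proteinSequence("bad", ""), "non-empty")
})

test_that("global alignment reproduces hand-scored examples", {
  ident <- globalAlign(proteinSequence("a", "ACD"), proteinSequence("b", "ACD"))
  expect_equal(nColumns(ident), 3L)
  expect_false(anyNA(ident@alignedA))
  expect_false(anyNA(ident@alignedB))
  expect_equal(percentIdentity(ident), 1)

  ## KR vs KD under BLOSUM62: ungapped, K-K 5 plus R-D -2
  kr <- globalAlign(proteinSequence("a", "KR"), proteinSequence("b", "KD"))
  expect_equal(alignmentScore(kr), 3)
  expect_false(anyNA(kr@alignedA))

  expect_error(globalAlign(proteinSequence("a", "KR"),
                           proteinSequence("b", "KD"), matrix = "NOSUCH"),
               "unknown substitution matrix")
})

test_that("alignment score equals the exhaustive-enumeration oracle on short pairs", {
  ## a modest sample here; the full 200-case sweep runs in the acceptance suite
  set.seed(421)
  for (case in 1:40) {
    a <- randomSeq(sample(1:6, 1)); b <- randomSeq(sample(1:6, 1))
    got <- alignmentScore(globalAlign(proteinSequence("a", a),
                                      proteinSequence("b", b)))
    want <- bruteAlignScore(a, b, blosum62, 10, 0.5)
    expect_equal(got, want, tolerance = 1e-9,
                 info = sprintf("pair %s / %s", a, b))
  }
})

test_that("alignment agrees with an independent aligner on longer pairs", {
  ## Biostrings costs a length-L gap gapOpening + L*gapExtension, ours
  ## gapOpen + (L-1)*gapExtend: equivalent when gapOpening = gapOpen - ext
  set.seed(77)
  for (case in 1:10) {
    a <- randomSeq(sample(15:40, 1)); b <- randomSeq(sample(15:40, 1))
    mine <- alignmentScore(globalAlign(proteinSequence("a", a),
                                       proteinSequence("b", b)))
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 9.5, gapExtension = 0.5))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("percent identity uses the both-residues denominator and is symmetric", {
  aln <- globalAlign(proteinSequence("a", "AA"), proteinSequence("b", "AG"))
  expect_equal(percentIdentity(aln), 0.5)
  ## the optimal score is exactly symmetric; identity is computed on the
  ## deterministic high-road traceback, so it can wobble between co-optimal
  ## alignments when the argument order swaps gap roles -- the identical-
  ## column count itself must agree
  set.seed(11)
  for (case in 1:10) {
    a <- proteinSequence("a", randomSeq(sample(5:15, 1)))
    b <- proteinSequence("b", randomSeq(sample(5:15, 1)))
    ab <- globalAlign(a, b); ba <- globalAlign(b, a)
    expect_equal(alignmentScore(ab), alignmentScore(ba))
    nIdent <- function(x) round(percentIdentity(x) *
                                  sum(!is.na(x@alignedA) & !is.na(x@alignedB)))
    expect_equal(nIdent(ab), nIdent(ba))
  }
  ## denominator conventions are selectable
  long <- globalAlign(proteinSequence("a", "ACDEF"), proteinSequence("b", "ACD"))
  expect_true(percentIdentity(long, "alignment") <=
                percentIdentity(long, "shorter"))
})

test_that("charge-diff sites flag exactly the charge-class differences", {
  x <- proteinSequence("x", "EKAARND")
  expect_equal(nrow(chargeDiffSites(globalAlign(x, x))), 0L)

  tgt <- proteinSequence("t", "EK"); hom <- proteinSequence("h", "KK")
  sites <- chargeDiffSites(globalAlign(tgt, hom))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 1L)
  expect_equal(sites$targetResidue, "E")
  expect_equal(sites$homologResidue, "K")
  expect_equal(sites$deltaCharge, 2L)

  ## canonical numbering offset is respected and output is ascending
  tgt2 <- proteinSequence("t", "EKAD", firstResidueNumber = 30)
  hom2 <- proteinSequence("h", "KKAK")
  s2 <- chargeDiffSites(globalAlign(tgt2, hom2))
  expect_equal(s2$position, c(30L, 33L))

  ## self-comparison is empty for any sequence
  set.seed(8)
  for (case in 1:10) {
    s <- proteinSequence("s", randomSeq(sample(4:20, 1)))
    expect_equal(nrow(chargeDiffSites(globalAlign(s, s))), 0L)
  }
})

test_that("mutation parsing, application and inversion are consistent", {
  ms <- parseMutations("E31A, E32A N33H")
  expect_equal(length(ms), 3L)
  expect_equal(formatMutations(ms), c("E31A", "E32A", "N33H"))
  expect_error(parseMutations("E31A, 31A"), "malformed")
  expect_error(mutationSet(c(5L, 5L), c("A", "A"), c("K", "R")), "duplicate")

  seq <- proteinSequence("t", "AEKDA", firstResidueNumber = 77)
  mut <- applyMutations(seq, parseMutations("E78K"))
  expect_equal(as.character(mut), "AKKDA")
  expect_equal(as.character(applyMutations(seq, mutationSet())),
               as.character(seq))
  expect_error(applyMutations(seq, parseMutations("E79K")), "mismatch")
  expect_error(applyMutations(seq, parseMutations("A99K")), "outside")

  ## applying the reverse set restores the original, for random sets
  set.seed(303)
  for (case in 1:15) {
    s <- proteinSequence("s", randomSeq(20), firstResidueNumber = 10)
    pos <- sample(10:29, sample(1:6, 1))
    to <- sample(AA20, length(pos), replace = TRUE)
    ms <- mutationSet(pos, from = residueAt(s, pos), to = to)
    back <- applyMutations(applyMutations(s, ms), reverseMutations(ms))
    expect_equal(as.character(back), as.character(s))
  }
})

test_that("FASTA writing and reading round-trips sequences", {
  f <- tempfile(fileext = ".fasta")
  seqs <- list(proteinSequence("alpha", randomSeq(150), 16),
               proteinSequence("beta", "ACDEFGHIKLMNPQRSTVWY"))
  writeProteinFasta(seqs, f)
  back <- readProteinFasta(f, firstResidueNumber = c(16L, 1L))
  expect_equal(vapply(back, seqId, ""), c("alpha", "beta"))
  expect_equal(as.character(back[[1]]), as.character(seqs[[1]]))
  expect_equal(firstResidueNumber(back[[1]]), 16L)
  unlink(f)
})
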