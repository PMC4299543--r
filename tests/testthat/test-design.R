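test_that("PTM-safe substitution passes non-hydroxyl residues and maps S/T/Y", {
  expect_equal(ptmSafeSubstitution("K"), "K")
  expect_equal(ptmSafeSubstitution("T"), "L")
  expect_equal(ptmSafeSubstitution("S"), "A")
  expect_equal(ptmSafeSubstitution("Y"), "N")
  expect_equal(ptmSafeSubstitution(c("D", "T", "Y")), c("D", "L", "N"))
})

test_that("identical target and homolog yield an empty design with similarity 1", {
  tr <- genHomologPair(60, 0, 0, seed = 2)
  rep <- proposeChargeTransfer(truthTarget(tr), truthHomolog(tr),
                               truthStructure(tr))
  expect_equal(length(designMutations(rep)), 0L)
  expect_equal(nrow(designCandidates(rep)), 0L)
  expect_equal(designSimilarity(rep), 1)
  prof <- designProfiles(rep)
  expect_equal(netCharge(prof$before), netCharge(prof$after))
})

test_that("planted surface sites are recovered and buried sites rejected with values", {
  tr <- genHomologPair(60, 3, 1, seed = 7)
  rep <- proposeChargeTransfer(truthTarget(tr), truthHomolog(tr),
                               truthStructure(tr))
  expect_setequal(mutationPositions(designMutations(rep)),
                  truthSurfaceSites(tr))
  cand <- designCandidates(rep)
  rej <- cand[cand$position %in% truthBuriedSites(tr), ]
  expect_equal(nrow(rej), 1L)
  expect_false(rej$accepted)
  expect_true(is.finite(rej$relSASA))
  expect_lt(rej$relSASA, 0.20)
  expect_match(rej$reason, "relSASA")
  ## audit passes untouched
  expect_silent(auditDesign(rep, truthTarget(tr)))
  ## variant profile is consistent with the charge deltas
  prof <- designProfiles(rep)
  shifted <- shiftChargeProfile(prof$before, designMutations(rep))
  expect_equal(netCharge(prof$after), netCharge(shifted))
})

test_that("audit detects tampered reports and names the site", {
  tr <- genHomologPair(60, 3, 1, seed = 13)
  rep <- proposeChargeTransfer(truthTarget(tr), truthHomolog(tr),
                               truthStructure(tr))
  ## drop one mutation: charge accounting no longer matches
  ms <- designMutations(rep)
  dropped <- mutationSet(ms@position[-1], ms@from[-1], ms@to[-1])
  broken <- rep
  broken@mutations <- dropped
  expect_error(auditDesign(broken, truthTarget(tr)), "mismatch|missing")
  ## flip a filter flag on an accepted candidate
  flipped <- rep
  i <- which(flipped@candidates$accepted)[1]
  flipped@candidates$passSASA[i] <- FALSE
  expect_error(auditDesign(flipped, truthTarget(tr)),
               as.character(flipped@candidates$position[i]))
})

test_that("design respects its structural invariants", {
  tr <- genHomologPair(60, 3, 1, seed = 17)
  rep <- proposeChargeTransfer(truthTarget(tr), truthHomolog(tr),
                               truthStructure(tr))
  cand <- designCandidates(rep)
  ## no position invented by the pipeline
  expect_true(all(mutationPositions(designMutations(rep)) %in% cand$position))
  ## tightening either threshold never adds a mutation
  for (cons in list(designConstraints(minRelSASA = 0.6),
                    designConstraints(minDistance = 14))) {
    tight <- proposeChargeTransfer(truthTarget(tr), truthHomolog(tr),
                                   truthStructure(tr), constraints = cons)
    expect_true(all(mutationPositions(designMutations(tight)) %in%
                      mutationPositions(designMutations(rep))))
  }
  ## hydroxyl-free guarantee over many seeds
  for (s in 31:40) {
    tri <- genHomologPair(60, 3, 1, seed = s)
    ri <- proposeChargeTransfer(truthTarget(tri), truthHomolog(tri),
                                truthStructure(tri))
    expect_false(any(mutationTo(designMutations(ri)) %in% c("S", "T", "Y")))
    expect_silent(auditDesign(ri, truthTarget(tri)))
  }
})

test_that("paper-replication mode adds neighbour and charge-conserving candidates", {
  tr <- genHomologPair(60, 3, 0, seed = 7)
  target <- truthTarget(tr)
  sites <- sort(truthSurfaceSites(tr))
  p <- sites[1]; q <- sites[2]

  ## homolog variant: also differs at the neutral neighbour p+1 and carries a
  ## charge-conserving K where the target has R at site q
  targetChars <- residues(target)
  homChars <- residues(truthHomolog(tr))
  off <- firstResidueNumber(target)
  targetChars[q - off + 1L] <- "R"
  homChars[q - off + 1L] <- "K"
  nb <- p + 1L
  stopifnot(!nb %in% sites)
  targetChars[nb - off + 1L] <- "A"
  homChars[nb - off + 1L] <- "Q"
  target2 <- proteinSequence("t2", paste(targetChars, collapse = ""), off)
  homolog2 <- proteinSequence("h2", paste(homChars, collapse = ""), off)

  plain <- proposeChargeTransfer(target2, homolog2, truthStructure(tr))
  expect_false(nb %in% designCandidates(plain)$position)
  expect_false(q %in% designCandidates(plain)$position)

  repl <- proposeChargeTransfer(target2, homolog2, truthStructure(tr),
                                paperReplication = TRUE)
  cand <- designCandidates(repl)
  expect_true(nb %in% cand$position)
  expect_equal(cand$origin[cand$position == nb], "homolog-match")
  ## the charge-conserving site is exposed and distant by construction
  expect_true(q %in% mutationPositions(designMutations(repl)))
  expect_equal(cand$origin[cand$position == q], "homolog-match")
  expect_silent(auditDesign(repl, target2))
})
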