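test_that("charge profiles count D/E and K/R with His neutral", {
  p <- chargeProfile(proteinSequence("x", "DEKRH"))
  expect_equal(nNegative(p), 2L)
  expect_equal(nPositive(p), 2L)
  expect_equal(netCharge(p), 0L)

  expect_error(chargeProfileFromCounts(-1, 2), "non-negative")

  ## profile after mutations is predictable from per-mutation charge deltas
  set.seed(51)
  for (case in 1:20) {
    s <- proteinSequence("s", randomSeq(30), firstResidueNumber = 16)
    pos <- sample(canonicalPositions(s), sample(1:8, 1))
    ms <- mutationSet(pos, from = residueAt(s, pos),
                      to = sample(AA20, length(pos), replace = TRUE))
    direct <- chargeProfile(applyMutations(s, ms))
    shifted <- shiftChargeProfile(chargeProfile(s), ms)
    expect_equal(nNegative(direct), nNegative(shifted))
    expect_equal(nPositive(direct), nPositive(shifted))
    expect_equal(netCharge(direct), nPositive(direct) - nNegative(direct))
  }
})

test_that("point charges land on representative side-chain atoms", {
  lys <- readPDBStructure(c(pdbLine(1, "CA", "LYS", "A", 1, 0, 0, 0, "C"),
                            pdbLine(2, "NZ", "LYS", "A", 1, 3, 0, 0, "N")))
  q <- assignPointCharges(lys)
  expect_equal(nrow(q), 1L)
  expect_equal(q$charge, 1)
  expect_equal(q$x, 3)  # NZ, not CA

  gly <- readPDBStructure(pdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"))
  expect_equal(nrow(assignPointCharges(gly)), 0L)

  trio <- readPDBStructure(c(
    pdbLine(1, "CA", "ASP", "A", 1, 0, 0, 0, "C"),
    pdbLine(2, "CG", "ASP", "A", 1, 2, 0, 0, "C"),
    pdbLine(3, "CA", "LYS", "A", 2, 8, 0, 0, "C"),
    pdbLine(4, "NZ", "LYS", "A", 2, 11, 0, 0, "N"),
    pdbLine(5, "CA", "ARG", "A", 3, 16, 0, 0, "C"),
    pdbLine(6, "CZ", "ARG", "A", 3, 19, 0, 0, "C")))
  q3 <- assignPointCharges(trio)
  expect_equal(q3$charge, c(-1, 1, 1))
  expect_equal(q3$x, c(2, 11, 19))

  ## a sequence override projects a mutant's charges onto the model
  seq <- proteinSequence("mut", "AAE", firstResidueNumber = 1)
  qm <- assignPointCharges(trio, seq = seq)
  expect_equal(qm$charge, -1)
  expect_equal(qm$resno, 3L)
})

test_that("screened-Coulomb potential matches its defining formula", {
  q1 <- data.frame(x = 0, y = 0, z = 0, charge = 1)
  ## Bjerrum-length distance, no salt: exactly 1 kT/e
  m <- screenedCoulombPotential(q1, matrix(c(7.1, 0, 0), 1), ionicStrength = 0)
  expect_equal(potentialValues(m), 1, tolerance = 1e-12)

  expect_equal(debyeKappa(0.1), 0.104, tolerance = 0.01)
  expect_error(
    screenedCoulombPotential(q1, matrix(c(0.2, 0, 0), 1), 0), "0.5 A")

  ## superposition and linear scaling in the charges
  set.seed(31)
  ch <- data.frame(x = rnorm(5, sd = 5), y = rnorm(5, sd = 5),
                   z = rnorm(5, sd = 5), charge = sample(c(-1, 1), 5, TRUE))
  pts <- matrix(rnorm(30, sd = 20), ncol = 3)
  tot <- potentialValues(screenedCoulombPotential(ch, pts, 0.1))
  parts <- sapply(seq_len(5), function(i)
    potentialValues(screenedCoulombPotential(ch[i, ], pts, 0.1)))
  expect_equal(tot, rowSums(parts), tolerance = 1e-12)
  ch2 <- ch; ch2$charge <- 2 * ch2$charge
  expect_equal(potentialValues(screenedCoulombPotential(ch2, pts, 0.1)),
               2 * tot, tolerance = 1e-12)

  ## term-by-term summation oracle, 1e-10 relative
  want <- directSumPotential(ch, pts, 0.1)
  expect_equal(max(abs(tot - want) / pmax(abs(want), 1e-30)), 0,
               tolerance = 1e-10)

  ## monotone screening: higher ionic strength shrinks |phi| of one charge
  d <- matrix(c(5, 0, 0), 1)
  phis <- sapply(c(0, 0.05, 0.1, 0.5), function(I)
    abs(potentialValues(screenedCoulombPotential(q1, d, I))))
  expect_true(all(diff(phis) < 0))
})

test_that("potential similarity is a Pearson correlation with guard rails", {
  mkMap <- function(v) new("PotentialMap",
    points = data.frame(x = seq_along(v), y = 0, z = 0, potential = v,
                        resno = NA_integer_),
    ionicStrength = 0.1, temperature = 298)
  set.seed(6)
  v <- rnorm(12); w <- rnorm(12)
  expect_equal(potentialSimilarity(mkMap(v), mkMap(v)), 1)
  expect_equal(potentialSimilarity(mkMap(v), mkMap(-v)), -1)
  expect_equal(potentialSimilarity(mkMap(v), mkMap(w)), pearsonByHand(v, w))
  expect_error(potentialSimilarity(mkMap(v[1:2]), mkMap(w[1:2])), "3")
  expect_error(potentialSimilarity(mkMap(rep(1, 5)), mkMap(w[1:5])),
               "zero variance")
})

test_that("surface sample points sit outside exposed residues only", {
  tr <- genHomologPair(60, 2, 1, seed = 4)
  s <- truthStructure(tr)
  sasa <- relativeSASA(shrakeRupleySASA(s))
  pts <- surfaceSamplePoints(s, sasa = sasa)
  expect_gt(nrow(pts), 3)
  exposed <- residueSASA(sasa)
  expect_true(all(pts$resno %in% exposed$resno[exposed$relSASA >= 0.2]))
  ## points are pushed outward from the centroid
  ctr <- colMeans(as.matrix(structureAtoms(s)[, c("x", "y", "z")]))
  rpts <- sqrt(rowSums(sweep(as.matrix(pts[, 1:3]), 2, ctr)^2))
  ratoms <- sqrt(rowSums(sweep(
    as.matrix(structureAtoms(s)[, c("x", "y", "z")]), 2, ctr)^2))
  expect_gt(min(rpts), 0.9 * max(ratoms) - 5)
})
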