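## Independent oracles used by the tests. These deliberately do NOT share
## code with the package implementations they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomSeq <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

## Exhaustive-recursion alignment oracle: walks every global alignment of the
## two residue vectors (tracking whether the previous column opened a gap in
## a or b) and returns the maximum score under the same affine gap model as
## the package (length-L gap costs open + (L-1) * ext). Exponential -- only
## for short sequences.
bruteAlignScore <- function(sa, sb, sm, open, ext) {
  ra <- strsplit(sa, "")[[1]]; rb <- strsplit(sb, "")[[1]]
  n <- length(ra); m <- length(rb)
  rec <- function(i, j, last) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      v <- sm[ra[i + 1], rb[j + 1]] + rec(i + 1, j + 1, "M")
      if (v > best) best <- v
    }
    if (i < n) {
      v <- -(if (last == "X") ext else open) + rec(i + 1, j, "X")
      if (v > best) best <- v
    }
    if (j < m) {
      v <- -(if (last == "Y") ext else open) + rec(i, j + 1, "Y")
      if (v > best) best <- v
    }
    best
  }
  rec(0L, 0L, "none")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

## Monte-Carlo SASA oracle: uniform random points on each atom's solvent
## sphere, accessible when outside every other atom's solvent sphere.
mcSASA <- function(xyz, vdw, probe = 1.4, nPts = 1e5, seed = 99) {
  set.seed(seed)
  r <- vdw + probe
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(rnorm(3 * nPts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPts)
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= r[j]^2
    }
    out[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  out
}

## Term-by-term screened-Coulomb summation (scalar double loop).
directSumPotential <- function(charges, pts, ionicStrength) {
  lB <- 7.1
  kap <- sqrt(8 * pi * lB * 6.02214076e23 * ionicStrength * 1e-27)
  phi <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    s <- 0
    for (i in seq_len(nrow(charges))) {
      d <- sqrt((pts[p, 1] - charges$x[i])^2 + (pts[p, 2] - charges$y[i])^2 +
                  (pts[p, 3] - charges$z[i])^2)
      s <- s + charges$charge[i] * exp(-kap * d) / d
    }
    phi[p] <- lB * s
  }
  phi
}

## Pearson correlation written out by hand.
pearsonByHand <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## Closed-form activating-protease-only course (kAuto = 0):
## Tr(t) = Tg0 * (1 - exp(-kEp * EP0 * t)) + Tr0, concentrations in nmol/L.
epClosedForm <- function(kEp, Tg0, Tr0, EP0, t) {
  Tg0 * 1e3 * (1 - exp(-kEp * EP0 * 1e-3 * t)) + Tr0
}

## Small PDB fixtures built in code.
pdbLine <- function(serial, name, resName, chain, resno, x, y, z,
                    element = substr(name, 1, 1), insert = " ") {
  sprintf("ATOM  %5d  %-3s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resName, chain, resno, insert, x, y, z, element)
}
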