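---
title: "Surface-charge transfer design and activation kinetics with zymoCharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-charge transfer design and activation kinetics with zymoCharge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zymoCharge)
```

## The problem

Zymogens are inactive enzyme precursors that become active when another
protease removes a short activation peptide. For trypsinogen-like serine
protease zymogens this creates a hazardous feedback: the activated enzyme can
itself cleave the activation peptide of its own precursor, so a trace of
active enzyme amplifies autocatalytically. Homologs differ strikingly in this
respect — some autoactivate within the hour while close relatives are
essentially inert — and one candidate explanation is the pattern of charged
residues on the protein surface, which steers the transient protein–protein
encounter between an active enzyme and a zymogen.

`zymoCharge` implements the two computational halves of testing that idea:

1. **Design**: given a target zymogen, an autoactivation-defective homolog
   and a structural model, propose the minimal set of surface substitutions
   that transplants the homolog's charge pattern onto the target without
   touching the active site, the activation peptide's neighbourhood, or
   introducing new post-translational-modification liabilities.
2. **Kinetics**: model the activation cascade, estimate activation rates from
   activity time courses, and fit Michaelis–Menten parameters, so designed
   variants can be compared quantitatively to the parent enzyme.

A synthetic-data module generates every input the pipeline needs, so the
full stack is testable offline.

## The design pipeline

`proposeChargeTransfer()` chains five steps, each exposed on its own:

1. **Alignment** — `globalAlign()` is a Needleman–Wunsch/Gotoh global
   aligner with affine gaps. A gap of length $L$ costs
   $g_\mathrm{open} + (L-1)\, g_\mathrm{ext}$; defaults (BLOSUM62, 10, 0.5)
   approximate the ClustalW protein defaults. Ties between co-optimal
   alignments are broken deterministically in favour of substitution columns
   (high-road). One consequence worth knowing: the optimal *score* is exactly
   symmetric in the two sequences, but the reported identity *fraction* can
   differ slightly between argument orders when co-optimal alignments place
   gaps differently, because the denominator (columns where both sequences
   have a residue) depends on which co-optimal traceback is chosen.
   `percentIdentity()` defaults to that both-residues denominator;
   shorter-sequence and full-alignment conventions are selectable.
2. **Candidate detection** — `chargeDiffSites()` reports every aligned
   position whose formal charge class differs (Asp/Glu $=-1$, Lys/Arg $=+1$,
   His and everything else $0$; terminal charges ignored). Positions are in
   the target's canonical numbering, carried by every `ProteinSequence` via
   `firstResidueNumber` (zymogen chains conventionally start at 16, putting
   the activation peptide at 16–23).
3. **Structural filters** — each candidate must be *on the surface*
   (relative SASA $\ge$ 0.20 by default) and *distant from the activation
   peptide* (minimum heavy-atom distance strictly $>$ 10 Å by default,
   against the first eight residues of the chain unless an explicit residue
   list is given). Both thresholds sit in `designConstraints()`. The 20%
   exposure cutoff is a common surface criterion; the pipeline records the
   measured value for every candidate, so a different cutoff can be audited
   after the fact.
4. **PTM-safe substitution** — `ptmSafeSubstitution()` prevents introducing
   hydroxyl-bearing residues (Ser/Thr/Tyr), which carry phosphorylation/
   glycosylation risk in expression hosts: T→L, S→A, Y→N; everything else
   passes through.
5. **Audit and prediction** — the mutation set is re-applied, charge
   accounting is verified two ways (direct recount vs per-mutation deltas),
   and the variant's predicted surface potential is correlated with the
   homolog's on shared sample points (`potentialSimilarity()`, Pearson; we
   call the patterns *matched* at $\ge$ 0.7, a documented convention — the
   correlation itself is always reported).

`auditDesign()` re-derives everything independently and fails hard, naming
the site, on any inconsistency. Rejected candidates stay in the report with
their measured values; the audit trail is part of the contract.

A `paperReplication` flag adds two narrative heuristics that a designer
applied case by case and that no charge-class rule can derive: aligned
neighbours (±1) of accepted sites where the homolog differs, and
charge-conserving substitutions at charged positions (e.g. Lys for Arg).
They are off by default and clearly labelled a reconstruction.

## Electrostatics

The potential model is a screened Coulomb (Debye–Hückel) superposition,

$$\phi(\mathbf{p}) = \ell_B \sum_i q_i \frac{e^{-\kappa d_i}}{d_i}
\quad [kT/e],$$

with unit integer charges on one representative side-chain atom per charged
residue (Asp C$\gamma$, Glu C$\delta$, Lys N$\zeta$, Arg C$\zeta$; C$\beta$/
C$\alpha$ fallback), the Bjerrum length fixed at $\ell_B = 7.1$ Å (water,
298 K, $\varepsilon \approx 78.5$) and
$\kappa = \sqrt{8\pi \ell_B N_A I \cdot 10^{-27}}$ per Å with the ionic
strength $I$ in mol/L ($\kappa \approx 0.104$/Å at 0.1 mol/L). This is a
deliberate approximation to a Poisson–Boltzmann solve: no dielectric
boundary, no partial charges, no protonation-state assignment. What it
preserves — superposition, sign pattern, distance decay and monotone salt
screening — is exactly what the design pipeline compares between a variant
and its homolog, and each of those properties is verified against
independent oracles in the test suite. Sample points are the heavy-atom
centres of exposed residues pushed 1.4 Å outward from the structure
centroid, which keeps the two maps being compared on identical supports.

## Structure: SASA and distances

`shrakeRupleySASA()` counts accessible test points on each atom's solvent
sphere (van der Waals radius + 1.4 Å probe; Bondi/Chothia-style radii
C 1.70, N 1.55, O 1.52, S 1.80 Å). The point set is a golden-spiral sphere —
quasi-uniform and RNG-free, so results are bit-reproducible for a fixed
point count. The default 960 points give $\le$ 1% error on isolated spheres
and $\le$ 2% against a $10^5$-point oracle for overlapping atoms; rotational
invariance holds to the sampling tolerance. Relative exposure divides by
Gly-X-Gly extended-tripeptide maxima (`maxSASATable()`), so fractions can
slightly exceed 1 for highly exposed residues. Distances to the activation
peptide are heavy-atom minima; with backbone-only models this degrades
gracefully to a C$\alpha$ criterion since those are the only atoms present.

## The kinetics model

The cascade is irreversible mass action with a constant activating-protease
pool ($EP$):

$$\frac{d[\mathrm{Tg}]}{dt} = -(k_\mathrm{auto}[\mathrm{Tr}] +
k_\mathrm{ep}[EP])\,[\mathrm{Tg}], \qquad
\frac{d[\mathrm{Tr}]}{dt} = +(\cdots)[\mathrm{Tg}],$$

integrated adaptively (rtol $10^{-8}$, atol $10^{-12}$, µmol/L and minutes
internally). $[\mathrm{Tg}]+[\mathrm{Tr}]$ is conserved; with
$k_\mathrm{auto}=0$ the model reduces to the closed-form exponential
approach, checked to $10^{-6}$. No Michaelian saturation is included in the
activation step and no degradation term by default (a first-order decay of
the active enzyme is available behind an explicit argument, for exploration
beyond the default stable-enzyme assumption).

Two rate-like quantities must not be confused. The **bimolecular constant**
$k_\mathrm{auto}$ (L/µmol/min) parameterises the ODE and is recovered by
`fitCascade()`. The **activation rate** reported from experiments
(nmol/L/min) is the initial linear slope of the active-enzyme concentration,
related by $\mathrm{rate} = (k_\mathrm{auto} \mathrm{Tr}_0 +
k_\mathrm{ep} EP_0)\,\mathrm{Tg}_0$ (`initialActivationRate()`).
`estimateActivationRate()` implements the slope with an explicit window
convention: grow the window greedily from the first three points while the
converted signal has risen by at most 10% of the total zymogen and the
linear fit keeps $R^2 \ge 0.99$. Because an autocatalytic course e-folds on
the $1/(k_\mathrm{auto}\mathrm{Tg}_0)$ timescale (about 0.3 min at the fast
defaults), the initial slope of a fast course is only visible on an early,
densely sampled window; slow courses are near-linear for tens of minutes,
but even there we estimate on a window short relative to the acceleration
timescale (30 min keeps the upward bias below 1%, against ~8% over 300 min).
The worked analyses in the acceptance script state their grids explicitly.

At the study's standard conditions — 2 µmol/L zymogen seeded with 10 nmol/L
active enzyme — a fast variant (initial rate ≈ 31 nmol/L/min) completes
activation well within 80 simulated minutes, while a slow variant (initial
rate ≈ 0.005 nmol/L/min) converts under 1% of its zymogen in 300 min; the
two slopes differ by more than 5000-fold. Note a tension inside the
published numbers themselves: an initial rate of 30.9 nmol/L/min under pure
bimolecular mass action implies completion within minutes, not ~80 min, so
the package treats the 80-min figure as an upper-bound ordering property
rather than a point value. Salt effects enter as different $k_\mathrm{auto}$
values per condition (screening of the encounter is qualitative here, and
the monotone-screening property of the potential is tested in its own
right); they are not predicted from the electrostatics module.

`fitMM()` fits $v = k_\mathrm{cat} E_0 S / (K_m + S)$ by positive-constrained
nonlinear least squares started from a Hanes–Woolf linearisation; at least
four distinct substrate levels are required. `activityToConcentration()`
converts U/mL through specific activity (U/mg) and molar mass. For the
plateau worked example the package uses a nominal 25 kDa zymogen molar mass
(the exact construct mass depends on sequence and tags): 2 µmol/L at
69 U/mg gives 3.46 U/mL.

## What the synthetic data emulate — and what they do not

`genHomologPair()` builds a planted-truth design case: a compact FCC-lattice
ball of pseudo-residues (3.8 Å nearest-neighbour spacing, deterministic
geometry), one C$\alpha$ per residue plus a two-atom outward pseudo side
chain on surface residues, the first eight residues forming a compact
surface patch that carries the activation-peptide motif. An early design
sketch used two thin concentric shells, but under Shrake–Rupley occlusion a
sparse inner shell far from an outer shell is *not* buried (no test point of
a central atom falls inside any shell atom's solvent sphere), so a filled
lattice is used instead. Planted surface sites are chosen among positions
whose *measured* relative SASA is $\ge 0.30$ for any plantable residue type
and whose measured distance to the activation-peptide patch exceeds 10.5 Å;
planted buried sites have measured relative SASA $\le 0.05$. Selecting by
measurement (rather than hoping a geometric band behaves) is what makes the
planted truth satisfy the design filters for every seed, which the test
suite asserts across seeds 0–99. Charge-class differences are planted by
drawing the target and homolog residues from distinct classes.

These fixtures exercise the full pipeline — alignment, charge detection,
exposure, distance, PTM fallback, audit — but they are not proteins: no
secondary structure, no realistic packing, ungapped alignments, and exposure
values cleanly separated by construction. Passing the planted-recovery test
therefore demonstrates that the pipeline's logic is correct, not that its
thresholds are well-calibrated for real structures, where exposure values
crowd the cutoff and homology models add coordinate noise.

`genTimeCourse()` and `genMMData()` add seeded Gaussian noise
(multiplicative, $\sigma = 0.05$ by default — a typical activity-assay CV,
our choice) to the deterministic models. Every generator saves and restores
the caller's RNG state and is a pure function of its arguments including the
seed.

## Numerical choices and degenerate inputs

* Alignment ties: high-road, deterministic; unknown matrices and residues
  outside the matrix alphabet are errors.
* SASA: $R^2$-free, RNG-free; unknown elements are errors, never defaulted.
* Potential: sample points closer than 0.5 Å to a charge are an error
  (the $1/d$ kernel is meaningless there); zero-variance potential vectors
  make the similarity undefined (error), except that two *identical* maps
  compare as 1.
* Rate estimation: a constant course has slope 0 with $R^2$ defined as 1
  (the line fits perfectly); a course whose first three points already
  violate the conversion cap is a hard error rather than a silent
  extrapolation.
* `fitCascade()` optimises on the log scale (positivity) and, when both
  constants are fitted, tries three attributions of the initial slope and
  keeps the best least-squares solution, because the two rate terms trade
  off near $t = 0$.
* Charge accounting is checked after every design via two independent
  routes; any mismatch is a hard failure.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run entirely on synthetic inputs:
60-residue planted-truth fixtures (50 for recovery scoring, 100 seeds for
the exposure-separation contract), 200 short random pairs against the
exhaustive alignment oracle, 100 noisy replicates for cascade-constant
recovery, and six-point velocity datasets for the Michaelis–Menten fits.
Checks that need the real accession sequences (overall identity of the
homolog pair, total charged-residue counts) activate only when the
corresponding FASTA files are placed under `inst/extdata`; they are not
redistributed with the package.

## Known limitations

* The screened-Coulomb map is not a Poisson–Boltzmann potential; absolute
  values and dielectric-boundary effects are out of scope by design.
* The design heuristics behind `paperReplication` are a labelled
  reconstruction of case-by-case choices, not a derivable rule.
* The cascade model has no saturation and no degradation by default;
  variants that degrade during activation need the optional decay term and
  care in interpreting plateaus.
* Identity fractions depend on the chosen co-optimal alignment under ties
  (see above); scores do not.
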