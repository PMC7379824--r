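---
title: "Screening cysteine-rich repeat proteins for horizontal gene transfer: models and methods"
author: "CRRscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cysteine-rich repeat proteins for horizontal gene transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Some eukaryotic proteins carry short cysteine-rich repeat modules of
about 33 residues with an absolutely conserved cysteine pattern. These
modules tend to flank conserved enzymatic domains — lysozymes,
peptidoglycan amidases, M15-type peptidases — that are otherwise typical
of bacteria and bacteriophages. That architecture makes the repeats a
useful *anchor* for a horizontal gene transfer (HGT) screen: find every
protein carrying the repeat, annotate the domains travelling with it,
ask whether each domain family is taxonomically biased toward
prokaryotes and phages, and trace each suspicious domain to its nearest
cross-superkingdom homolog. A protein whose two domains trace to donors
in *different* prokaryotic phyla is evidence of two independent transfer
events fused into one chimeric gene.

`CRRscreen` implements that screen end to end, together with a
synthetic-proteome generator that provides ground truth, so every stage
is testable offline with no sequence database.

# The profile hidden Markov model

The search engine is a local-alignment profile HMM over match (`M`),
insert (`I`) and delete (`D`) states:

* **Entry/exit.** The begin state enters any match state with uniform
  probability $1/L$; every match state carries an exit probability
  $\tau$ to the end state (default $\tau = 0.1$; the last match state
  exits with probability 1). Flanking residues are emitted by the
  background (null) model and so contribute zero log-odds. This lets
  the model find a repeat module embedded anywhere in a protein, and
  find partial modules.
* **Scores.** All scores are bits: $\log_2$ of the model-vs-background
  odds of a path (Viterbi, the maximum) or of all paths (forward, the
  log-sum). Insert emissions default to the background, so inserts cost
  only their transitions.
* **Estimation.** Alignment columns with occupancy $\ge$ 0.5 (the
  conventional choice; gap-majority columns become inserts) become
  match states. Emissions are background-weighted pseudocount mixtures
  $(c_a + w\,b_a)/(n + w)$ with weight $w = 1$ by default — a simple
  closed form whose behaviour is easy to verify (raising $w$ moves every
  emission monotonically toward the background). Transitions are
  counted from per-row gap patterns with the same rule (uniform prior
  over each state's legal transitions). Insert runs flanked by a
  deletion have no legal path in this topology and are counted as the
  direct transition.

The unknown residue codes (X, B, Z, U, O, J) score zero bits in every
state: a neutral treatment that neither rewards nor penalises
ambiguity.

# E-values: why the Gumbel is fitted to Viterbi scores

Significance is calibrated empirically: `n_decoys` i.i.d. background
sequences, lengths resampled from the real database's length
distribution, are scored and fitted to a Gumbel law by the method of
moments ($\lambda = \pi/(s\sqrt 6)$, $\mu = \bar x - \gamma/\lambda$).
The E-value of a hit in a database of $N$ sequences is
$N\,(1 - \exp(-\exp(-\lambda (S - \mu))))$.

The statistic fitted is the **Viterbi** bit score. This is a deliberate
choice: the null distribution of a *maximum* alignment score is Gumbel
by extreme-value theory, so a bulk fit (which is all a moment fit is)
extrapolates faithfully into the significance tail — we measure
$\lambda \approx 0.65$ per bit, close to the theoretical $\ln 2$ for
well-scaled log-odds scores, and the fitted tail is mildly conservative.
The null *forward* score, by contrast, has a narrow, nearly Gaussian
bulk (sd $\approx$ 0.8 bits) sitting under an exponential upper tail;
a moment fit to it underestimates tail P-values by orders of magnitude
and admits spurious short partial matches at any fixed E-value
threshold. `calibrateEvalues()` therefore defaults to
`statistic = "viterbi"`; the forward algorithm remains available (and
`forwardScore() >= viterbiScore()` is enforced by the property suite).

# Iterative search

`iterativeSearch()` performs a jackhmmer-style refinement, 3 iterations
by default (the point at which the published screen found hit gains to
saturate) at inclusion E-value 0.01 (the reported significant matches
top out just below that). Included hits contribute only their
match-state-aligned residues to the re-estimated profile — insertions
are dropped and uncovered match states become gaps — which keeps the
model length fixed across iterations and avoids column drift. The
E-value model is recalibrated for each refined profile. Tandem copies
are counted by envelope masking: the best hit's envelope is masked
(match emission forbidden), the target rescanned, until the score falls
below the inclusion threshold. On the bundled benchmark this count
equals the implanted copy number exactly.

# Domain annotation and the HGT rules

Domain families are scored with the same engine (per protein and
family, database size 1, so `report_e` behaves like a per-test
P-value ceiling; default 1e-3). Overlaps are resolved greedily by
ascending E-value (ties: higher bit score, then smaller start), which
an exhaustive-subset oracle in the test suite confirms to be
order-independent and dominance-respecting. Externally produced scans
can be ingested through the annotation TSV (1-based inclusive
coordinates in files; 0-based half-open everywhere internally — the
round trip is lossless).

The classification rules are deliberately literal:

* A family is **prokaryote/phage-typical** iff *strictly more than*
  three quarters of its unique carrier species are in Bacteria, Archaea
  or Viruses. Exactly 3/4 is unbiased; carriers are species labels, not
  sequence counts.
* A protein is an HGT **candidate** iff it carries at least one typical
  domain; **chimeric** iff it carries two or more from distinct
  families; flagged **independent events** iff, additionally, the best
  foreign hits of two such domains fall in distinct donor phyla —
  "distant phylogenetic position" operationalised as a phylum-level
  contrast, which is the contrast the motivating case
  (Firmicutes vs Bacteroidetes) exhibits.
* Percentages in summaries are integers, rounded half away from zero.
  On the published restricted-dataset counts this reproduces 79%
  (98/124), 51% (63/124), 14% (17/124) and 5% (6/124), and reports the
  complement 26/124 as 21%.

Nearest foreign hits use Smith–Waterman local alignment
(BLOSUM62, gap open 11, extend 1 — standard defaults) through the
`Biostrings` aligner, with identity counted over aligned residue pairs
excluding gap columns; co-optimal tracebacks are canonicalised so
identity is symmetric in its arguments. Foreign-hit E-values are
Gumbel-calibrated on residue-shuffled donor decoys, and a hit is
accepted below `max_e = 1e-5` with no identity floor: the evidence
standard in the motivating case was an E-value around 1e-28 at 35%
identity, so 1e-5 is conservative plumbing, and configurable.

# What the synthetic generator emulates

The generator's defaults are the bundled study conditions, fixed once:

| parameter | default | meaning |
|---|---|---|
| `n_background / n_repeat_proteins / n_chimeric` | 445 / 50 / 5 | a 500-protein proteome |
| `module_consensus` | 33 residues | 6 invariant cysteines (positions 3, 8, 14, 19, 24, 32), glycines at 10, 21, 26, 30, prolines at 29, 31 |
| `substitution_rate` | 0.1 | per mutable position; substitutions draw uniformly from 20 residues, so 1/20 are silent |
| `repeat_copies_range` | 2–6 | modules per repeat protein, arranged in pairs |
| `domain_substitution_rate` | 0.05 | divergence of implanted domains and donors |
| `background_length_range` | 80–400 | i.i.d. background residues (fixed 20-value table) |

Repeat proteins carry module pairs at recorded intervals; every fifth
one also carries a library domain. Chimeric proteins carry two domains
from families whose donors sit in Firmicutes and Bacteroidetes, each
preceded by a pair of modules. The emitted donor database contains the
named donor of each family plus eukaryotic decoys. Every protein draws
from its own substream of the master seed, so appending proteins to a
configuration never perturbs the ones already generated, and the truth
table records every implant verbatim — the suite re-locates each by
exact substring match.

The module consensus is a stand-in: the published logo is described
only qualitatively (the cysteine pattern is absolutely conserved;
glycines and prolines at the named positions are strongly conserved),
so the exact residues elsewhere are an invention, and only the
cysteines are generated as unconditionally invariant.

**What passing does and does not show.** The generator produces
substitution-only modules (an optional indel rate exists to exercise
insert states), i.i.d. background composition, and families that are
cleanly biased or cleanly unbiased. Real proteomes have compositional
bias, low-complexity regions, genuinely ambiguous families and
partially degraded repeats; perfect recovery on the benchmark therefore
validates the machinery and its statistics, not database-scale
performance. The published UniProtKB/Pfam-scale numbers (382 hits, the
E-value range, the Fungi/Metazoa split, the 35%/50% alignment
identities) depend on 2017 database snapshots and are out of reach
offline; the package checks only that its aggregation reproduces the
printed marginal counts when given tables of that composition.

# Numerical and degenerate-input choices

* Log-space throughout, base 2; `log2(0) = -Inf` is legal everywhere in
  the DP, and a fully masked sequence yields `-Inf` (reported as
  no hit).
* Viterbi ties break deterministically: match over delete over insert,
  continuation over fresh entry, earliest end position.
* Profile JSON serialisation keeps full precision; the
  write-read round trip reproduces every probability to 1e-12.
* Zero decoy-score variance (e.g. a single-state point-mass model)
  raises a calibration error rather than returning a degenerate fit.
* Repeat-region border splitting takes 0-based half-open borders
  strictly inside the sequence; unsorted or out-of-range borders are
  validation errors. De novo module proposal (iterated off-diagonal
  self-alignment, Waterman–Eggert masking) decomposes overlapping
  tandem self-alignments into period-length modules and reports
  disjoint copies as-is.

# Problem sizes

The bundled benchmark is 500 proteins scanned with a 33-state profile
over 3 iterations, 200 decoys per calibration; the whole pipeline runs
in well under a minute on one CPU, and the test suite's property checks
(path-enumeration oracles at up to 4 match states and 6 residues,
exhaustive alignment oracles at up to 8 residues, exhaustive
overlap-resolution subsets at up to 5 annotations) complete in a few
seconds each.

# Known limitations

* E-values are calibrated per profile against a homogeneous background;
  compositionally biased targets are not corrected for (no analogue of
  the HMMER bias filter or null2 correction).
* Multiple module copies are counted by envelope masking, not by a
  multi-domain dynamic program; abutting copies are counted correctly
  on the benchmark but posterior-decoded envelopes would be more
  robust on degraded repeats.
* The carrier-species rule inherits whatever strain/species
  deduplication the supplied library uses; carriers are deduplicated by
  exact species label only.
* The foreign-hit step ranks a supplied donor database; it is not a
  database-scale homology search and inherits the donor set's
  completeness.
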