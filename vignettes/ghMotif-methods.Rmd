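---
title: "Signature motifs in the lysozyme superfamily: models and methods"
author: "ghMotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature motifs in the lysozyme superfamily: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghMotif)
```

# The scientific problem

The lysozyme superfamily groups glycoside hydrolase (GH) families and
subfamilies — GH19 plant chitinases, GH22 C- and I-type lysozymes, GH23
goose-type lysozymes, GH24 viral and lambda-type lysozymes and GH46
chitosanases — that share essentially no sequence similarity yet fold into
the same bilobal architecture around a substrate-binding cleft.  Two
structural elements recur in every member: the C-terminal part of the
central helix, carrying the invariant general-acid glutamate, and a
β-hairpin pointing into the cleft.  Within each family, the hairpin region
is also the most conserved stretch of the sequence alignment, so it
defines a family-specific *signature motif* that can be used to search
sequence databases, and it concentrates catalytically important residues:
the general-base Glu/Asp (role B), the Ser/Thr that positions the
catalytic water of inverting enzymes (role C), and a conserved
left-handed glutamine of unknown function (role D).

`ghMotif` re-implements this analysis as a reusable, fully tested
pipeline with four stages:

1. **Structure clustering** — transform a matrix of pairwise structural
   similarity Z-scores into distances, build a UPGMA tree, and assess
   every internal node by the Lanyon leave-one-out jackknife.
2. **Conservation profiling** — entropy-based per-column conservation of
   a family alignment, smoothed and normalized, mapped onto the
   representative structure's author numbering, with extraction of the
   signature motif around the configured hairpin.
3. **Signature search** — position-specific log-odds profile built from
   the motif block, glocal affine-gap scoring of candidate sequences, and
   TPR/FPR evaluation against labelled sets at a null-calibrated
   threshold.
4. **Structural characterization** — backbone torsions, left-handed
   conformation classes, β-turn typing, hairpin classing and the
   active-site role-distance table.

A synthetic-data module generates inputs with the statistical and
geometric structure each stage assumes, so the whole pipeline is testable
offline.

# Structure clustering

## From similarity to distance

The input is a labelled symmetric matrix of structure-pair similarity
scores $S_{ij}$ (DaliLite-style Z-scores in the original study) with
self-scores $S_{ii}$ on the diagonal.  The default transform is

$$D_{ij} = 100\left(1 - \frac{2\,S_{ij}}{S_{ii}+S_{jj}}\right),$$

which is exactly 0 for a structure against itself, strictly decreasing in
$S_{ij}$ at fixed self-scores, and maps complete dissimilarity
($S_{ij}=0$) to 100.  The transform is pluggable (`transform` argument
accepts any function of the similarity matrix): the exact algebraic form
used to produce the published inter-family distances is not recoverable
from the source material, so the package treats it as a configuration
point and never asserts those printed values.  Similarities exceeding the
self-score mean would give negative distances; they are clamped to 0 and
reported.

## UPGMA and its tie rule

`upgmaTree()` implements unweighted pair-group averaging directly: join
the closest pair, replace it by a cluster whose distance to any other
cluster is the size-weighted mean of its parts, repeat.  Node height is
half the merge distance, so the tree is ultrametric by construction.  Two
numerical choices matter:

* **Ties** are broken deterministically towards the pair whose smallest
  member labels sort lexicographically first, so results are identical
  across platforms and across jackknife replicates.
* Distances within a relative $10^{-9}$ of the current minimum count as
  tied.  Size-weighted averaging of *exactly equal* distances drifts by
  one ulp depending on cluster sizes; without the epsilon, the
  deterministic tie rule would be bypassed by floating-point noise and
  noise-free replicate trees could differ spuriously from the full tree.

The suite cross-checks the implementation against
`stats::hclust(method = "average")` on general matrices and against a
cophenetic-identity oracle on generated ultrametric matrices: whenever
the input is ultrametric, the tree's induced cophenetic matrix equals the
input exactly.

## Lanyon jackknife

Each structure is removed in turn and the tree is rebuilt from the
reduced similarity matrix (the transform is re-applied, then UPGMA).  An
internal node of the full tree is **reliable** only if, in every
replicate, its clade restricted to the surviving structures is either
smaller than two leaves (vacuously present) or appears as a clade of the
replicate tree.  This restriction rule is the package's concretization of
"found in all possible trees"; clades reduced below two leaves cannot be
meaningfully tested and are counted present.  At least four structures
are required — below that no internal node is testable.

## Family distances

`familyDistances()` reports the mean over unordered within-family pairs
(singletons report no value, printed `-`) and the mean over all cross
pairs for every family pair.  The mean (rather than min or max) matches
the "mean distance between families" reading of the summary statistics
the analysis reports.

# Conservation profiling

## Weights, entropy, smoothing, normalization

Sequence redundancy is corrected with Henikoff position-based weights: at
each column a residue type shared by $s$ of $r$ distinct types
contributes $1/(rs)$ to each carrying sequence; row sums are rescaled to
$\sum w = n$.  This is a documented stand-in for AL2CO's
independent-count estimator with the same qualitative behaviour (exact
duplicates share weight; a duplicate-free alignment keeps near-equal
weights).  Gap (`-`) and unknown (`X`) symbols never contribute to
frequencies.  A BLOSUM62 matrix, listed among the original AL2CO
parameters, is irrelevant to the entropy estimator (it affects only
sum-of-pairs scoring) and is accepted but unused.

The raw per-column index is the negative Shannon entropy in nats,
$C = \sum_a f_a \ln f_a \in [-\ln 20, 0]$, computed from the weighted
frequencies: 0 for an invariant column, $-\ln 20$ for a uniform one.
Columns with gap fraction above 0.5 are flagged and excluded from
smoothing input and normalization statistics.  Smoothing is a centred
moving average of window 3 (shrinking at edges and across flagged
columns); normalization is a population z-score over unflagged columns.
A single-sequence family cannot be normalized; the pipeline falls back to
the raw profile with a warning.

## Motif extraction

The signature motif is the contiguous window, of length 8–18 columns
(bracketing the 9–17-residue signatures of the superfamily), that
contains the configured β-hairpin range and maximizes the **sum of
z-scored raw conservation** over its columns; ties go to the shortest,
then leftmost window.  Two design points deserve explanation:

* A windowed *mean* systematically shrinks to the most conserved interior
  columns and drops genuine boundary columns of a conserved block.  The
  summed z-score rewards every above-average column and penalizes every
  background column, so the optimum extends exactly across a contiguous
  conserved block — which is what the planted-block recovery tests (and
  the original qualitative criterion, "the region of strongest
  conservation containing the hairpin") demand.
* The z-scores are computed from the **raw**, not the smoothed, index:
  window-3 smoothing bleeds one column of elevated signal past each
  block boundary and would drag background columns into the motif.

A hairpin longer than the maximal window length is returned as-is with a
warning.  The extractor is verified against a brute-force scan over all
admissible windows.

# Signature models and search

## Logo and profile

`buildLogo()` reports weighted relative frequencies and per-position
information content $IC = \log_2 20 - H_2(f)$ bits (no small-sample
correction); an invariant position scores $\log_2 20 \approx 4.32$ bits,
a uniform one 0.  `buildProfile()` turns the motif block into
position-specific emission probabilities with background pseudocounts,

$$e(p, a) = \frac{w_{p,a} + \alpha\,bg_a}{W_p + \alpha},\qquad
  \text{log-odds} = \ln \frac{e(p,a)}{bg_a},$$

with $\alpha = 1$ and a uniform background by default (overridable, e.g.
by the negative-set composition).  With $\alpha = 0$, unseen residues
score $-\infty$, which is permitted and documented.

## Glocal scoring

A full profile HMM is deliberately out of scope: the scientific claim
being tested is signature discriminability, not HMM internals.  Instead,
`scoreSequence()` aligns the **entire motif** against **any window of the
sequence** (glocal semantics: free sequence flanks) by three-state
dynamic programming with affine gap penalties — 4.0 nats to open and 0.5
nats to extend a gap, on either the motif side (deletions) or the
sequence side (internal insertions).  The DP is proven equivalent to an
exhaustive enumeration of all gapped alignments on small instances (every
motif length up to 4 against every sequence length up to 8 over a reduced
alphabet) in the test suite.

## Threshold and evaluation

The hit threshold is calibrated on a simulated null: scores of random
background-composition sequences drawn at the *median length of the
target set* (under glocal semantics the null score grows with sequence
length, so length matching matters), thresholded at the $1-\mathrm{FPR}$
empirical quantile with FPR 0.01 by default.  `evaluateSearch()` then
reports TPR and FPR over labelled member/non-member sets, with `NA` for
empty classes.  Published search performances against a 2010 database
release depend on that corpus and on family-membership corrections
against an external database; they are reproduced only qualitatively, on
synthetic benchmarks with known ground truth.

# Structural characterization

## Torsions and conformational classes

Backbone φ/ψ/ω follow the IUPAC sign convention (verified against
`bio3d::torsion` as an independent oracle) and are undefined at termini,
at missing backbone atoms, and across chain breaks (peptide-bond C–N
distance above 2.5 Å — avoids spurious angles at crystallographic gaps).
The Ramachandran plane is partitioned into explicit boxes: left-handed
helical $\phi \in (20°, 125°], \psi \in [-45°, 90°)$; left-handed
extended $\phi \in (20°, 180°], \psi \in [90°, 240°)$ (mod 360); their
right-handed mirror images; everything else unclassified.  The bounds are
this package's formalization of the usual $\alpha_L$/ε regions — the
source analysis states only "positive φ" and "left-handed" — and both
left-handed classes require $\phi > 0$ by construction.

## Turns and hairpins

β-turns are typed over windows $i..i{+}3$ gated by
$C_\alpha(i)$–$C_\alpha(i{+}3) < 7$ Å and by the central residues not
lying inside a helix (proxy: a run of ≥ 4 consecutive right-handed
helical residues, since no hydrogen-bond-based secondary structure
assignment is attempted).  Types I, I′, II and II′ are matched against
canonical central dihedrals (type I: $-60,-30/-90,0$) within ±30°, one
angle allowed ±45°; candidates matching no named type are type IV.
Negating all dihedrals maps I↔I′ and II↔II′ by construction.

Hairpins are classified `X:Y` from two bracketing conventions: X counts
loop residues between the supplied strand boundaries, Y those between the
innermost geometrically paired residues ($C_\alpha$ distance < 5.5 Å).
The original Promotif conventions bracket by hydrogen-bond ladders; with
a purely geometric criterion the two definitions above coincide on ideal
hairpins (4:4 for a four-residue loop) and differ exactly when strand
annotation and geometry disagree.  Strand ranges from the family
configuration always override the simplified geometric strand detection
(runs of ≥ 3 extended residues) — the fallback the original study itself
needed when DSSP mis-assigned strands in two families.  Anti-parallelism
is checked by requiring the nearest-partner mapping across the strands to
be order-reversing.

## Active-site geometry

Role distances follow the atom-selection rule of the published
active-site table: the shortest separation between side-chain oxygen sets
— Glu {OE1, OE2}, Asp {OD1, OD2}, Ser {OG}, Thr {OG1} — and, for the
accessory Gln, the Cβ atom only.  Roles missing from a configuration, or
whose residue is absent or mutated in the structure, yield `NA`, printed
`/`; structures lacking a role are skipped (with a log message) in family
summaries, whose parentheses report the **population** standard deviation
(the printed table does not state its convention) and `-` for singletons.
All residue references use author numbering with insertion codes as part
of the residue key — every catalytic label in the literature (Glu67,
Ser120, …) is an author number.

# Synthetic data: what it emulates, what it does not

`generateMsa()` plants a contiguous high-conservation block (per-column
consensus emitted with probability `pCons = 0.95`, default block of 13
columns in a 120-column, 50-sequence alignment, uniform background, 5%
gaps outside the block).  This emulates the *statistical* signature of a
family alignment around its motif — a conserved block on a variable
background — not evolutionary structure: there is no phylogeny, no
substitution-matrix correlation between residues, and no alignment error.
Passing tests therefore demonstrate that the profile machinery recovers
planted signal at realistic conservation contrast, not that it tolerates
phylogenetic autocorrelation.

`generateSimilarityMatrix()` draws within-family similarities at
$35 \pm 2$, between-family at $5 \pm 2$ and self-scores at $45 \pm 1$
(clamped at 0), matching the regime of the published Z-scores (1.2–47.3,
with definite homology above 20).  `generateSequenceDb()` embeds mutated
motif instances (divergence 0.1 by default) in random flanks of 10–30
residues against pure-background negatives.

`generatePeptide()` builds backbones from prescribed torsions by
natural-extension-of-reference-frame construction with fixed standard
geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; angles 111.2°, 116.2°,
121.7°; C=O 1.231 Å), so recomputed torsions reproduce the prescription
to well below 0.5°.  The hairpin presets fix the loop centre at the
canonical type I turn (four-residue loop) or type I′ turn (two-residue
loop — tight 2:2 hairpins require the mirror-image turn to close, as in
real structures) and set the four strand/loop junction torsions by a
deterministic Nelder–Mead refinement, run once per session from a fixed
starting geometry, that targets 4.9 Å cross-strand $C_\alpha$ pairing
with a steric penalty below 4.2 Å.  Every generator is a pure function of
its arguments and seed, and restores the caller's RNG state.

# Problem sizes and numerical conventions

The shipped tests and the acceptance script run at the following scales,
chosen to exercise each property well past its asymptotic regime while
staying desk-sized: 100 random ultrametric matrices ($n \le 12$) for the
cophenetic oracle; 50 seeded alignments for peak localization; 20 for
exact motif recovery; every (motif length ≤ 4) × (sequence length ≤ 8)
combination, several random instances each, for the DP-vs-enumeration
equivalence; 5 seeds × (50 positives + 500 negatives) with 1000-sequence
null calibration for the search benchmark; 500 random 10-residue chains
for the torsion round trip.

Other conventions: natural log (nats) for conservation and log-odds,
bits for logo information; population SD throughout; angles in degrees in
$(-180°, 180°]$; distances in Å reported to 0.01; PHYLIP square matrices
are the only matrix dialect (asymmetries averaged, warned above 0.5);
`-` and `.` both read as gaps; Newick branch lengths written with 15
significant digits so write/read round trips are exact to $10^{-9}$.
Pipeline outputs are written atomically (temp file + rename) so a failed
stage never leaves partial results, and reruns are byte-identical.

# Known limitations

* The similarity-to-distance transform is a documented default, not the
  unpublished original; absolute tree heights and printed inter-family
  distances are therefore not comparable, only tree *topology* behaviour
  is tested.
* Conservation weighting is Henikoff position-based, not AL2CO's
  independent count; absolute index values differ from AL2CO output even
  though peak locations and block boundaries agree.
* The profile model is a glocal affine-gap PSSM, not a plan-7 profile
  HMM; scores are not comparable to HMMER bit scores and no E-value
  calibration is attempted.
* Secondary structure is inferred from backbone geometry alone (no
  hydrogen-bond energies); configured strand ranges should be preferred
  whenever available.
* Verification against real crystallographic active sites requires the
  user to supply the PDB files; the packaged tests otherwise validate
  geometry on generated coordinates only.

# A minimal session

```{r example, eval = FALSE}
dir <- tempfile()
cfg <- simulateInputs(dir, seed = 4)        # writes matrix, MSAs, PDB, config
runAll(readRunConfig(cfg))                  # cluster + motifs + search + structures
list.files(file.path(dir, "out"), recursive = TRUE)
```
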