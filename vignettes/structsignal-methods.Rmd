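---
title: "Assessing phylogenetic signal in structure-partitioned rDNA alignments"
author: "structsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing phylogenetic signal in structure-partitioned rDNA alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structsignal)
```

## The problem

Ribosomal RNA genes are the workhorse markers of deep arthropod and
chelicerate phylogenetics, but they are not a homogeneous source of signal.
The molecule's secondary structure divides an alignment into three very
different column classes:

* **stems** — paired helix positions whose homology is anchored by
  compensatory substitutions (a change in one partner matched by the
  complementary change in the other);
* **loops** — unpaired positions, typically adenine-rich and evolving
  under a different composition than stems;
* **regions of ambiguous alignment (RAAs)** — expansion segments whose
  length varies so much among taxa that positional homology cannot be
  asserted by a structure consensus; these account for most of the
  alignment's length variation.

`structsignal` implements the full desk-side workflow for such matrices:
reading the dot-bracket structure mask, partitioning, per-partition
diagnostics (composition, stationarity, saturation), a rescue path for the
RAAs (independent per-block alignment under posterior guide trees followed
by random-similarity masking), and tree-side signal assessment (likelihood
mapping, consensus-network split systems, internode certainty, a Bayesian
relative-rates test, and trace-based model comparison). A seeded
synthetic-data generator produces data with known ground truth so that
every stage is testable without any external download.

## Structure-annotated alignments

The input convention is an aligned FASTA in which one record (id
`#structure`, or a trailing record of mask characters) carries matching
parentheses for stems and dots for loops. Brackets are paired by a stack in
nesting order. Unmatched brackets are *not* an error: a helix partner may
simply not have been sequenced, so such columns are recorded as *orphans*,
classified and counted as paired columns but excluded from the pairing map.
RAA spans come either from a BED-like sidecar (block id, 0-based half-open
start/end) or from lowercase runs inside the mask; the reader auto-detects
the convention. A column belongs to exactly one class; RAA spans override
the mask class.

Internally all coordinates are 1-based inclusive (the natural R
convention); every file format that carries coordinates keeps its own
convention (BED-like sidecar: 0-based half-open; partition definition
files: 1-based inclusive ranges). `U` is folded to `T` on input.

Site-pattern counting follows the parsimony conventions: a column is
*parsimony-informative* when at least two states are each present in at
least two taxa, with gaps and ambiguity codes never counting as states. The
constant-site convention is lenient by default (gaps and ambiguities are
ignored, so one real state plus gaps is constant); `strict_constant = TRUE`
requires a clean column. The lenient default is a deliberate choice — the
strict rule reclassifies gap-bearing monomorphic columns as uninformative
variable, which distorts comparisons across gappy partitions.

## Composition diagnostics

Per-taxon base counts are taken over ungapped positions, excluding
ambiguity codes from the counts (but not from the ungapped length). Three
diagnostics sit on top:

* **Tetrahedral coordinates.** The 4-base frequency simplex embeds affinely
  into 3-space with the pure compositions at the vertices of a regular
  tetrahedron centered at the origin; the uniform composition maps to the
  origin. Affinity is the property that matters (midpoints map to
  midpoints), and it is property-tested.
* **GC–length correlation.** Spearman's rank correlation (ties
  mid-ranked, two-sided p from the t approximation) between per-taxon GC
  fraction and ungapped length.
* **Stationarity.** For each taxon, a chi-squared statistic against the
  pooled ("average") composition with df = 3, flagged at the 5% level.
  Whether the external tool that inspired this test pools over all taxa or
  leaves the focal taxon out is not documented anywhere we could verify,
  so pooled is the default and `leave_one_out = TRUE` is available. With
  leave-one-out pooling a base can have zero expected frequency while
  being present in the focal taxon; a 0.5 pseudocount option covers that
  case (it is an error otherwise, with the remedy named in the message).

## Substitution saturation

The index of substitution saturation compares the alignment's mean
per-site entropy to the entropy expected under *full* saturation:

$$ I_{ss} = \frac{\bar H}{E[H_{\text{full}}]}, \qquad
   H_i = -\sum_b p_{ib} \log_2 p_{ib} $$

where the full-saturation expectation draws each column i.i.d. from the
alignment's global base frequencies at the observed taxon count. Because
the finite-sample closed form of that expectation exists in several
published variants, we estimate it by seeded Monte Carlo (default 10,000
columns; tests and the bundled analyses use 2,000–5,000, which changes the
normalizer by well under 1%).

The critical value Iss.c — the Iss at which tree reconstruction starts to
fail — is estimated by simulation: alignments evolve under Jukes–Cantor on
a four-clade topology (balanced for `sym`, ladderized for `asym`; tips
diverge within their group at 30% of tree depth so that group monophyly is
informative) over a divergence ladder; at each rung we record mean Iss and
the fraction of replicates whose neighbor-joining tree recovers all group
splits plus the backbone split. The critical Iss interpolates the ladder at
95% recovery, after anchoring with the exact noiseless limit (zero
divergence: Iss 0, recovery 1) and enforcing monotonicity. When the
empirical ladder never reaches the threshold at *any* divergence the
alignment is simply too short for the recovery criterion; the returned
value is then an extrapolation, flagged `identified = FALSE` with a
warning, and verdicts should be treated as inconclusive. Short partitions
are exactly the regime where reference implementations also print
degenerate critical values, so we report as-is rather than clamp.

The saturation test itself compares Iss against each critical value with a
two-sided t statistic using the among-site variance of normalized entropy.

## RAA rescue

Ambiguous regions are not discarded: each block is re-aligned
independently, then filtered.

* **Cost regime.** Gap opening costs 4; gap extension and substitution
  cost 1 each (`alignment_costs()`), i.e. a four-fold opening penalty
  relative to equally weighted extension and substitution — the regime
  reported to give the best homology estimates for dynamically aligned
  rDNA. A gap run of length $k$ costs $4 + (k-1)$.
* **Progressive alignment.** Profiles merge postorder along the guide
  tree (most similar first); each merge is solved exactly by affine-gap
  (Gotoh) dynamic programming over profile columns, where the
  column–column substitution cost is the mean pairwise cost (match 0,
  mismatch 1, residue–gap = extension, gap–gap 0). Tie-breaking is
  deterministic: prefer the match state, then a gap in the first profile,
  with leftmost placement following from the traceback order. Taxa with
  empty subsequences join as all-gap rows after alignment.
* **Multiple guide trees.** Because a posterior sample of guide trees is
  used rather than a single topology, each block is aligned under every
  guide and the minimum-total-cost alignment wins (ties: first tree in
  input order). All candidate costs are retained for sensitivity checks.
  Minimum cost was chosen because it is objective, deterministic, and
  uses the whole sample; averaging alignments is not well defined.
* **Random-similarity masking.** After concatenation, a sliding window
  (default width 7) scores every taxon pair: +1 per matching base pair,
  −1 per mismatch or any gap position. The null distribution pools window
  scores from composition-preserving shuffles of both rows (default 200
  per pair, minimum 100); a window is non-random when its observed score
  exceeds the null's 0.95 quantile. A site's pair profile is +1 when most
  covering windows are non-random; the consensus profile averages pairs,
  and columns with positive consensus are kept. The exact numerical output
  of the external masking tool is not reproduced — the published scoring
  scheme and window default are.

On synthetic data the mask behaves as designed: conserved cores flanked by
shuffled tails are kept/dropped cleanly, and on concatenated RAA blocks the
dropped columns are precisely the gap-riddled indel stretches. Low
retention on RAA material is expected, not a failure mode.

## Likelihood mapping

For every sampled quartet the three unrooted topologies are scored by
maximum likelihood under a fixed GTR+Γ model (parameters are inputs,
typically taken from an external ML run; Γ uses 4 equal-probability
categories at their conditional means). Branch lengths (five per quartet)
are optimized by coordinate descent with Brent-style bounded line searches
(floor 1e-8, convergence 1e-6 on the log-likelihood). Gap/ambiguity columns
marginalize over the permitted states. The implementation agrees with an
independent pruning implementation to 1e-8 at fixed branch lengths (a
dual-route test in the suite).

The three posterior weights $w_i \propto e^{\ell_i - \max \ell}$ place each
quartet on the barycentric simplex, partitioned into seven regions: corner
basins ($w_i > 1/2$, fully resolved), edge regions (the omitted topology's
weight ≤ 1/4, partly resolved), and the central star-like region (all
weights in (1/4, 1/2)) — the mid-line geometry whose edge/center boundary
is the medial triangle of the central triangle. Boundary points go to the
lowest region id deterministically. The exact boundary constants of the
original tool are not restated in the literature we can verify offline;
this variant honors all the defining anchor cases ((1,0,0) → corner,
(⅓,⅓,⅓) → center, (½,½,0) → edge) and places ≥95% of quartets in corners
on strongly resolved synthetic data.

In cluster mode one taxon is drawn per cluster and corners are labeled by
cluster pairings, so corner fractions answer "which grouping do the
quartets support". All quartets are evaluated when their number is at most
50,000, otherwise a seeded uniform sample (default 10,000).

## Split systems and internode certainty

Bipartition frequencies are collected over a tree set (bootstrap
replicates or a posterior sample), canonicalized by the side not containing
the alphabetically first taxon, with topology-string deduplication so
large tree sets with few distinct topologies are cheap. Consensus-network
input is the split system filtered at a frequency threshold (0.1 by
convention for 1000 bootstrap trees), exported as a NEXUS SPLITS block for
splits-graph viewers; drawing is delegated to those viewers.

Internode certainty for a reference edge with observed frequency $f_1$ and
most frequent incompatible split $f_2$:

$$ IC = 1 + p_1 \log_2 p_1 + p_2 \log_2 p_2, \qquad p_i = f_i/(f_1+f_2) $$

signed negative when $f_2 > f_1$; $f_2 = 0$ gives IC = 1. ICA generalizes
to all incompatible splits above a threshold (default 0.05, exposed as an
argument because the reference implementation's default is not printed),
using $\log_k$ over the $k$ splits considered. TC/TCA sum the edges;
relative versions divide by $n-3$. Two splits are compatible iff one of
the four side-intersections is empty — property-tested against brute-force
coexistence-in-one-tree on all 6-taxon pairs.

## Relative rates and model comparison

The Bayesian relative-rates test profiles, for every sampled tree, the
path length from the reference clade's MRCA (recomputed per tree, so
non-monophyly is handled) to each terminal. Per terminal we report the
mean, the equal-tailed credible interval (default 95%; equal-tailed rather
than HPD because the plain reading of "credible interval" carries no
further qualification, and HPD adds estimator variance at these sample
sizes), and the range. A terminal is flagged fast-evolving when its
credible interval overlaps *no other terminal's* interval (leave-one-out,
union rule). The union rule — rather than the others' convex hull — is
deliberate: with two separated outliers the hull of "the others" swallows
the inner outlier, while the union rule flags both. The hull variant
remains available as `mode = "hull"`.

Trace-based model comparison uses two estimators on post-burn-in sampled
log-likelihoods (burn-in default 10%):

* the log harmonic mean, computed stably in log space;
* AICM, pinned here as $\mathrm{AICM} = 2\,\widehat{\mathrm{var}}(\ell) -
  2\bar\ell$ (smaller is better), the variance-penalized analogue of AIC
  computed from the posterior sample; its SD comes from a seeded bootstrap
  over trace samples. This convention is forced by two exact identities the
  suite checks: a zero-variance trace at $c$ gives $-2c$, and shifting a
  trace by $s$ shifts AICM by $-2s$ (so the difference between two traces
  differing by a constant shift $s$ is $2s$).

`compare_partition_models()` reports both deltas with the sign convention
that positive favors the second model.

## The synthetic-data generator

The generator emulates the salient statistical features of
structure-annotated rDNA matrices, not their biology:

* **Stems** evolve as paired doublets: substitution events arrive as a
  Poisson process on each pair (rate 2 per unit branch length); with
  probability `q` (default 0.9) the partner immediately co-substitutes to
  the complement. Compensation is implemented as an event-coupled process
  rather than a 16-state doublet rate matrix because the pipeline's
  consumers need realized compensatory frequencies, not a normalized
  doublet likelihood; the truth record tallies events and compensations so
  the planted `q` is independently checkable.
* **Loops** are i.i.d. GTR+Γ with adenine-rich stationary frequencies
  (default $\pi_A = 0.4$, shape 0.5).
* **RAA blocks** evolve substitutions plus an indel process (rate 0.2
  events per substitution-unit per site, geometric lengths with mean 2.5)
  confined to the blocks, honoring the observation that RAAs carry most of
  the length variation; blocks are laid out left-justified with gap
  padding, i.e. deliberately *not* aligned, since that is what the rescue
  pipeline consumes. An optional per-lineage GC enrichment
  (`gc_rich_lineages`) biases terminal-branch substitutions toward G/C
  while scaling the deletion probability down, planting a positive
  GC–length correlation across taxa for testing the composition
  diagnostics.
* **Tree sets**: bootstrap sets with a planted conflict plant the chosen
  internode at frequency $f_1$ against a nearest-neighbor alternative at
  $f_2$ (multinomial per tree; backbone splits incompatible with the drawn
  resolution collapse, as they would in a real replicate). Posterior
  samples keep the topology fixed and jitter branch lengths lognormally
  (mean-one), with per-lineage rate multipliers on terminal branches.
* **Traces** are i.i.d. normal.

Everything is deterministic under a fixed seed, restoring the caller's RNG
state.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: thermodynamically consistent helix structure,
among-site rate autocorrelation, alignment error in the non-RAA backbone,
compositional heterogeneity beyond the optional terminal-branch GC
enrichment (so the stationarity test's power against realistic drift is
untested), and model misspecification of the inference step (which this
package deliberately does not perform).

## Problem sizes and numerical choices

The bundled analyses and the reproduction script use an 8-taxon balanced
tree (60 stem pairs, 120 loop columns, three 30-nt RAA blocks), 1000-tree
bootstrap sets, 500-tree posterior samples, 1000-sample traces, exhaustive
likelihood mapping (70 quartets), and 40–60 replicates per rung of the
saturation ladder — sizes chosen so the full suite and the end-to-end
study each complete in minutes on a single core while keeping Monte-Carlo
error well inside the tolerances asserted. Branch-length optimization is
bounded to [1e-8, 10]; transition matrices come from the eigendecomposition
of the symmetrized GTR generator; degenerate inputs (all-gap columns,
empty partitions, zero-variance traces, star references) take defined
paths rather than errors wherever a defined value exists, and errors name
the offending record or the remedial argument otherwise.

## Known limitations

* The affine progressive aligner is a stand-in for whatever automatic
  aligner a user prefers per block; it honors the stated cost regime
  exactly but makes no claim of being the best heuristic for long blocks
  (it is exact only per merge, not jointly).
* Iss.c is simulation-based and honest about identifiability; it does not
  reproduce any external tool's lookup tables digit-for-digit.
* ICA ignores conflicting splits below its threshold; with very diffuse
  conflict the index depends on that choice, which is why it is an
  argument rather than a constant.
* Masking reproduces the published scoring scheme, not the reference
  tool's exact output.
* Tree inference itself (Bayesian or ML), model selection, and
  statistical alignment are out of scope; the package assesses signal
  around those steps.
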