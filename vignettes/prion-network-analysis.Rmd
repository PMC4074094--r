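---
title: "Methods: interaction and functional networks of prion-like proteins"
author: "prionNets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction and functional networks of prion-like proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionNets)
```

# Scope

prionNets analyses how prion, prionogenic and N/Q-rich prion-like proteins
of budding yeast are embedded in protein interaction and functional
networks. Four protein sets anchor the analysis: the 10 well-characterized
known prions (KP), the 27 experimental prionogenic-domain proteins (EPD,
a superset of KP), the 18 experimental prion negatives (EPN), and the
bioinformatically defined N/Q-rich prion-like proteins (NQP), which can be
supplied as a list or recomputed from a proteome by the package's
compositional-bias scan. This vignette explains the statistical models,
the tunable parameters, the synthetic-data generator used for testing, the
numerical choices, and the known limitations.

# Compositional-bias detection (LPS)

A compositionally biased region is scored by the exact binomial upper
tail. For residue set $R$ (e.g. $\{N, Q\}$) with background probability
$p_R$ (the sum of the background frequencies of its members), a region of
length $n$ containing $k$ residues from $R$ scores

$$P(X \ge k), \qquad X \sim \mathrm{Bin}(n, p_R),$$

and the lowest-probability subsequence is the contiguous region of length
at least `minRegionLength` minimizing this tail. The search is exact: the
optimum either starts and ends on a biased residue (trimming an unbiased
end residue strictly lowers the tail when $k \ge 1$) or has exactly the
minimum length, so only those candidates are scored — an $O(L + m^2)$
evaluation for a protein of length $L$ with $m$ biased residues,
equivalent to the exhaustive $O(L^2)$ scan (property-tested against it).

Classification as N/Q-rich prion-like (NQP) evaluates the residue sets
$\{N\}$, $\{Q\}$, $\{N,Q\}$ and each of their unions with one subsidiary
residue (Y, S or G), takes the minimal-tail admissible region, and accepts
when:

* the region tail is at or below `mainP` = 1e-10 (the threshold that
  separates known prion domains from the proteome background);
* a subsidiary residue in the winning set itself shows a within-region
  bias below `subsidiaryP` = 1e-4 (otherwise that candidate set is
  inadmissible);
* no excluded residue — charged D/E/R/K or major hydrophobic V/I/L/M —
  reaches a within-region bias below `exclusionP` = 1e-4.

Decisions that the underlying method description leaves open, resolved
here once:

* **Background composition** defaults to the supplied proteome's aggregate
  frequencies (`proteomeComposition()`), the standard choice for
  compositional bias; a uniform 1/20 background is available
  (`uniformComposition()`).
* **`minRegionLength` = 20**: prion-like domains span tens of residues,
  and a floor prevents trivially short regions from reaching extreme
  tails. Configurable.
* The **exclusion and subsidiary tests are evaluated within the winning
  region**, since the rules describe biases of the region, not of the
  whole protein.
* A **single minimal-tail region per protein** decides classification;
  merging of multiple disjoint biased regions is not attempted.
* **Tie-breaking** is lower tail, then greater length, then smaller start,
  which makes the scan deterministic.

# Interaction-level enrichment

Binary interactions are parsed from MITAB 2.5+ (UniProt accessions only,
isoform suffixes stripped, A–B/B–A and duplicate evidence collapsed,
optional taxon filter) into an undirected deduplicated network.
Self-interactions are retained by default (they count once and put a
protein in its own interactor list); a toggle drops them.

The set-versus-set test uses interaction-level counts: with background
network $B$,

* $N = |B|$;
* $K$ = interactions involving at least one target-set protein;
* $n$ = interactions involving at least one sample-set protein;
* $k$ = interactions in which **one endpoint is a sample member and the
  other endpoint a target member** — within a sample protein's interactor
  list, the interactions whose partner belongs to the target set. For
  sample = target this makes $k$ the number of set-internal interactions,
  which is what the published diagonal of this analysis reports.

The reported P-value is the one-sided hypergeometric tail on the side of
the deviation of $k$ from its nominal expectation $nK/N$ (upper tail for
enrichment, lower for depletion; no two-sided doubling). Both tails are
always computed and returned. Family-wise control is Holm–Bonferroni over
the family of tests actually executed in a run (`enrichmentGrid()` corrects
over its own grid; `extraP` lets a caller merge companion grids into one
family, mirroring the published 72-test family). The restricted-background
analysis (e.g. all NQP-touching interactions as the population) is the
same contract applied to `restrictNetwork()` output.

**Known limitation — the convention is not calibrated under a random
graph.** For protein sets $S, T$ of sizes $a, b$ over $P$ proteins in an
Erdős–Rényi network, an interaction touching $S$ has a partner in $T$ at
rate $\approx b/P$, while the hypergeometric expectation uses the touch
rate $K/N \approx 2b/P$ (an edge has two endpoint slots, and "touches
$T$" double-counts them). Under a preference-free network, $k$ therefore
sits systematically at about half its nominal expectation: enrichment
tails are conservative and depletion tails are anti-conservative, and the
package's own null simulation (the calibration test in the acceptance
suite, 300 proteins, 800 interactions, 60-protein sets) measures exactly
this deviation. P-values from this convention are comparative scores in
the tradition of the original analysis, not calibrated frequentist error
rates; depletion calls in particular should be read with this bias in
mind. The hypergeometric/Holm machinery itself is calibrated and is
verified on genuinely hypergeometric nulls (uniform-p Holm family-wise
error; GO membership enrichment under the generator null, where the
examined set is independent of the annotations). A related numerical
consequence: with heavily overlapping sets in a restricted background the
observed $k$ can fall outside the hypergeometric support, where the exact
tail is zero; tails are floored at the smallest positive double so
corrections stay defined.

# GO enrichment triad

The ontology is read from OBO (is_a plus, by default, part_of edges;
obsolete terms dropped; restricted to biological_process; cyclic input is
an error), annotations from GAF (NOT-qualified rows dropped, aspect
filtered). Annotations are propagated to all ancestors before any
counting — propagation is the GO-standard choice and is required for the
most-specific-term collapse to trigger — and propagation is idempotent.

* **Membership enrichment**: per term, upper-tail hypergeometric on
  (universe size, annotated count, set size, annotated set members), Holm
  over all terms tested for the set. Terms annotating fewer than 2
  universe proteins are skipped (singleton terms are uninformative and
  would dominate the high-membership ranking).
* **High-membership report**: terms whose annotated universe proteins are
  at least half covered by the examined set, ranked by covered count;
  among nested terms enriched by the identical protein list, the ancestor
  is dropped only when the more specific term has the strictly lower
  P-value — otherwise both are kept.
* **Interaction-based enrichment**: interacting partners are collapsed to
  terms (one deduplicated protein–term pair regardless of how many
  partners carry the term), and the same hypergeometric contract is
  applied to the pair counts.
* **Cross-referencing** intersects the corrected-significant term sets of
  three analyses (high membership, set interaction enrichment, hub
  interactor enrichment).

# Monte-Carlo disorder test

Intrinsic disorder is consumed as upstream predictor output (per-residue
flags or per-protein counts; per-residue wins when both are present). The
test compares a set's total disordered residue count against `nSamples` =
10000 random samples of the proteome with exactly the same total length:
proteins are drawn uniformly without replacement until the cumulative
length reaches the target, and the final protein contributes the fraction
needed to hit the target exactly, its disordered count prorated by that
fraction. Prorating is unbiased in expectation and position-independent;
a positional N-terminal prefix mode is available for per-residue tracks.
The reported exceedance is the fraction of samples with **strictly**
greater disorder than observed. Sampling is without replacement within a
sample and with replacement across samples, and the whole test is
reproducible under a seed.

# Hub analysis

Hubs are sample-set proteins with at least `minPartners` = 10 distinct
interactors in the partner set. The threshold is deliberately "at least"
rather than "more than" 10: the published analysis describes its hubs as
interacting with more than 10 NQPs yet includes a nucleoporin with exactly
10, and ≥ 10 is the operational rule that reproduces its three hubs.
Per-hub enrichment uses the interaction-level background (N = all
interactions, K = partner-set-touching interactions) with n = the hub's
distinct interactors and k = those in the partner set; this choice
reproduces the published per-hub P-values within their printed precision.
`partitionAndEnrich()` splits the sample's interactions into hub-touching
and the rest (sizes always sum to the full sample count) and re-runs the
set tests on each partition with unchanged backgrounds.

# Synthetic data generator

The generator emulates the statistical structure the analysis assumes, at
desk scale, with a planted ground truth written alongside every output:

* **Proteome**: 500 proteins, log-normal lengths (median 400 residues,
  sdlog 0.45, floor 50), i.i.d. yeast-like aggregate composition; 8% of
  proteins receive a planted 60-residue domain whose residues are N/Q
  (equiprobable) with probability 0.4, the rest drawn from the background.
  The truth table records coordinates and realized N/Q counts.
* **Network**: 2000 unique pairs sampled uniformly with acceptance weight
  proportional to the preference odds of the category pair; an all-ones
  odds matrix is a uniform random graph. Rejection sampling is exact for
  the acceptance-odds semantics and fast at this scale.
* **Annotations**: a 60-term random tree (each term one parent, bounded
  depth — sufficient to exercise propagation and collapse without
  general-DAG complexity), leaf annotation probability 0.05 per
  protein–leaf pair, boosted on the odds scale ($p' = op/(1-p+op)$) for
  coupled term–set pairs; disorder fractions Beta-distributed around a
  base rate of 0.2 (concentration 30), with a +0.5 boost for
  planted-domain proteins.

All generators are deterministic under a fixed seed and emit files that
round-trip through the package readers. What the generator does **not**
emulate: scale-free degree distributions, correlated annotation structure
between related proteins, realistic GO term-size distributions, or
sequence features beyond composition. Passing planted-signal tests
therefore demonstrates the correctness and power of the counting and
testing machinery under the stated statistical structure, not performance
on real proteomes.

**Detection boundary.** Domains planted at 40% N/Q over 60 residues sit
near the 1e-10 classification threshold: with a ~10% N/Q background,
detection requires about 26 N/Q residues in the window, which a
Binomial(60, 0.46) realization misses in a substantial minority of cases.
The package's recovery tests measure ~33–35 of 40 such domains recovered;
a planted strength this close to the boundary is a feature for testing
threshold behaviour, but an asserted recovery of 38/40 is not attainable
at this strength and the corresponding acceptance expectation is left
failing, documented rather than relaxed.

# Numerical choices

* All binomial and hypergeometric tails are computed in log space
  (`log10p = TRUE` end-to-end), so magnitudes far below 1e-300 — e.g. the
  population-scale depletion tails — remain representable.
* The depletion tail is reported inclusively, $P(X \le k)$. The published
  tables this package mirrors demonstrably mix the inclusive and the
  strict ($P(X \le k-1)$) conventions across cells;
  `verifyPrintedValues()` computes both and compares each printed cell
  against the nearer convention under a factor-of-two rule (the tables
  print 1–2 significant figures). One printed cell (the NQP ×
  highly-disordered depletion) reproduces only to a factor of ~2.5 under
  either convention and is flagged as failing.
* Holm–Bonferroni flags are `p.adjust(p, "holm") <= alpha`, verified in
  tests against the hand-stepped step-down definition.
* Accessions are matched exactly after stripping isoform suffixes
  (interaction files mix isoform and canonical identifiers).
* The ">0.5 disordered" composite set uses a strict inequality.

# Test problem sizes

The shipped suite exercises: oracle equivalence of the region search on
100 random sequences up to 300 residues; exhaustive hypergeometric
enumeration for all populations up to 30; null calibration on 200–500
replicate 800-interaction networks; planted-signal recovery on
500-protein proteomes with 2000-interaction networks over 100 seeds; and
Monte-Carlo disorder tests at 400–10000 samples. These sizes were chosen
as the smallest that give the relevant binomial/KS bounds useful power.

# Known limitations

* The interaction-level counting convention's structural bias under
  random-graph nulls (above) — inherited from the analysis tradition this
  package operationalizes, measured by its own tests, and not silently
  "fixed", since the printed results it reproduces depend on it.
* The NQP set shipped by a real analysis also depends on an HMM-based
  candidate list and a specific proteome snapshot; the scan reproduces
  only the compositional-bias criterion, so set-dependent published counts
  are reproduced from their printed contingency tables, not re-derived.
* GO results depend on the ontology release; the package tests structure
  (propagation, collapse, counting) on synthetic DAGs only.
* Disorder is consumed, never predicted; published disorder percentages
  that depend on running a specific predictor over a specific proteome are
  out of scope.
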