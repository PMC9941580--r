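---
title: "Methods: kinome identification, duplication, TE proximity and coexpression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinome identification, duplication, TE proximity and coexpression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kinomer` implements a desk-scale version of a plant kinome analysis: identify
protein kinase (PK) genes from domain-model hits, classify them into groups and
subfamilies, merge calls from two genome assemblies, detect tandem and
segmental duplications, measure transposable-element (TE) proximity, aggregate
expression to subfamily level, and compare control-versus-stress subfamily
coexpression networks. Because genome-scale inputs (assemblies, read sets)
are out of scope, a seeded synthetic-data module generates every input with
planted ground truth, and the package's claims are validated against that
truth. This vignette documents the model behind each stage, the parameters and
their defaults, what the generator does and does not emulate, and the
numerical choices.

## 1. Kinome identification

**Model.** A protein is a *typical PK* when it carries at least one hit from a
kinase domain model (`Pkinase`, `Pkinase_Tyr`) with E-value at most
`evalue_max` and *model coverage* at least `coverage_min`, where coverage is
measured on the domain model:

\[
\mathrm{coverage} = \frac{\mathrm{hmm\_to} - \mathrm{hmm\_from} + 1}{\mathrm{model\ length}}.
\]

Proteins failing coverage are treated as atypical/probable pseudogenes and
excluded. One protein per gene is kept — the longest isoform, with
lexicographic tie-breaking so the choice is deterministic.

**Parameters.** `evalue_max = 1e-10` and `coverage_min = 0.5` are the
conventional thresholds for this kind of survey; both are arguments of
`filter_kinases()`. Multiple kinase domains on one protein are counted
greedily by ascending E-value with overlapping envelopes suppressed, so a
single biological domain reported twice is not double-counted.

**Input format.** `parse_domain_hits()` reads a 22-column whitespace-separated
per-domain table (the common profile-HMM search "domain table" shape); the
dialect is documented in the function and malformed lines are reported with
their line numbers.

**Classification.** Subfamily assignment scores each candidate against
per-subfamily log-odds position-specific scoring matrices (natural log,
pseudocount-smoothed, uniform background) at every ungapped placement, taking
the best placement per profile. A sequence is assigned the best-scoring
subfamily only if the best score reaches `threshold` (default 30 nats) *and*
beats the runner-up by at least `margin` (default 5 nats); otherwise it is
`Unknown`. The margin rule prevents arbitrary assignment between near-tied
subfamilies; the defaults separate the planted subfamilies from random
sequences by a wide gap in the synthetic tests.

## 2. Assembly merging

Two protein sets are pooled and clustered greedily in decreasing length order
(CD-HIT style): each sequence joins the first cluster whose representative
(its founding, hence longest, member) it matches, else founds a new cluster.
The join criterion uses

* *global identity* — aligned matches divided by the **shorter sequence's
  full length** (`identity_shorter`, the CD-HIT convention), at least
  `id_min = 0.95`, and
* whole-sequence length ratio (shorter/longer) at least
  `len_ratio_min = 0.75`.

Global identity rather than per-column local identity drives the join because
any two unrelated sequences share some short perfect local match, which would
score a per-column identity of 1.0.

Retention rules per cluster: a single copy from each source keeps only the
longest member; a cluster where either source contributed more than one member
keeps *all* members of the larger-contributing source (tie: the source holding
the longest member); singletons are kept as-is. The merged set is therefore
never larger than the union, and the per-source composition is reported with
percentages rounded half-up to two decimals.

## 3. Duplication detection

**Similarity search.** CDS pairs are pre-screened with an exact 11-mer shared
word (a BLAST-like seed), locally aligned (match +1, mismatch −2, gap open 4,
extend 1), and scored with a Karlin–Altschul E-value
\(E = K m n e^{-\lambda S}\) using the standard ungapped nucleotide constants
\(\lambda = 1.28\), \(K = 0.46\). These constants are an approximation for
gapped scores; E-values here rank candidate pairs rather than claim database
significance, and the acceptance thresholds operate on identity and coverage.

**Tandem clusters.** A pair is a tandem edge when both genes lie on the same
chromosome with boundary gap \( \mathrm{start}_2 - \mathrm{end}_1 - 1 \le
25\,\mathrm{kb}\) (1-based inclusive coordinates), identity ≥ 0.95, coverage
≥ 0.75 and E ≤ 1e-10. Connected components of ≥ 2 genes under single linkage
(union–find) form clusters; qualifying pairs at 25–100 kb are reported
separately as proximal-unclassified rather than silently dropped.

**Segmental tiers.** Pairs with identity above 0.90/0.75/0.50 that lie on
different chromosomes or more than 100 kb apart form three *nested* tiers;
tandem and segmental calls are disjoint by construction because their distance
conditions cannot overlap.

## 4. TE association

A gene is TE-associated when a TE lies within `window = 100 kb` (interval
distance: 0 when overlapping, otherwise the gap between nearest boundaries).
The query runs on a `GenomicRanges` interval index, and the unit tests check
it against a brute-force scan. The summary reports the associated fraction of
the kinome, the overlap with tandem clusters, and the TE class composition.

## 5. Expression and networks

**TPM.** Per sample, \( \mathrm{rate}_i = \mathrm{count}_i / \ell_i \) and
\( \mathrm{TPM}_i = 10^6 \mathrm{rate}_i / \sum_j \mathrm{rate}_j \); columns
sum to \(10^6\) (relative tolerance 1e-6), all-zero samples are flagged rather
than producing NaN. Samples whose detected-transcript fraction falls below
`min_detected_fraction = 0.1` are excluded — a quantitative stand-in for
dropping "abnormally low" quantifications; the cutoff is configurable because
no principled universal value exists. Replicates are collapsed by arithmetic
mean, and subfamily expression is the arithmetic mean TPM over member
transcripts (so aggregation and replicate averaging commute).

**Networks.** Nodes are subfamilies; an undirected edge joins two subfamilies
when the Pearson correlation of their profiles is at least `pcc_min = 0.7` —
*positive* correlations only, matching the moderate-to-strong positive scale
the analysis is built on. Zero-variance profiles are dropped and flagged
before correlation. At least 3 samples are required.

**Hub scores.** On an undirected graph, HITS hub and authority scores coincide
with the principal eigenvector of the adjacency matrix. Scores are computed
per connected component by power iteration on \(A + I\): the diagonal shift
leaves eigenvectors unchanged but makes the principal eigenvalue strictly
dominant, so the iteration converges even on bipartite components, where
iterating \(A\) or \(A^2\) stalls in the two-dimensional eigenspace of the
\(\pm\lambda\) pair. Iteration stops when the L2 change falls below 1e-12
(cap 10,000 iterations). Each component with at least one edge is scaled to a
maximum of 1 — so the global maximum is 1 *and* every component's top hub
scores 1, which keeps disconnected satellite components comparable. This
differs from implementations that normalize globally (they zero out
non-dominant components); the tests compare against a dense per-component
eigendecomposition and, on non-bipartite components, against `igraph`.

**Edge betweenness.** Brandes' algorithm on the unweighted graph; each
unordered node pair counts once and ties split fractionally across
co-shortest paths. The tests check closed forms (paths, cycles, trees) and a
brute-force geodesic enumeration.

**Comparison.** `compare_networks()` reports per-condition edge counts,
shared/unique edges, isolated nodes, percent edge loss
\(100(1 - |E_s|/|E_c|)\) and per-node hub rank shifts.

## 6. Characterization

Molecular weight sums ExPASy-style average residue masses plus one water
(18.01524 Da); it is additive up to water, and `MW("G") = 75.07` Da serves as
the worked reference. The isoelectric point solves the Henderson–Hasselbalch
net-charge equation (termini plus K, R, H, D, E, C, Y side chains with an
EMBOSS-style pKa table) by bisection on [0, 14], stopping at |charge| < 1e-4
or bracket < 1e-4 pH. The charge function is strictly decreasing, so the root
is unique; the tests agree with an independent pH-grid scan to 1e-3. The pKa
table is an argument because published tables shift pI by up to ~0.5 pH.
Intron count is exon count − 1 on the selected isoform. All reported
percentages use half-up rounding (`percent_half_up()`): base R `round()`
rounds half-to-even, which fails to reproduce conventionally reported ratios
(e.g. 1,636/2,842 → 57.57 at two decimals).

## 7. The synthetic generator: what it emulates, and what it does not

`generate_genome()` plants, per chromosome, singleton kinase genes and the
requested tandem arrays. Array members are derived from one ancestral CDS by
mutating *disjoint* position sets — `m = floor(L(1 - p)/2)` positions per copy
— so every pair of members has identity exactly \(1 - 2m/L \ge p\) by
construction, with stop codons avoided. Genes get multi-exon structures and,
for a fraction of genes, extra shorter isoforms (exercising longest-isoform
selection). TEs are placed uniformly with an LTR-dominated class mix.
`generate_domain_hits()` emits passing hits for every planted kinase and, when
requested, decoy proteins whose hits violate at least one threshold (half by
coverage, half by E-value). `generate_expression()` draws per-sample latent
subfamily profiles \( \eta_s = \sqrt{r}\, f_{\mathrm{block}} +
\sqrt{1-r}\, u_s \), so the within-block latent correlation equals the target
`block_correlation` exactly in expectation; gene log-means add noise of
standard deviation `noise_sd`, and counts are Poisson (or exact expected
values when `noise_sd = 0`, making within-subfamily profiles exactly
proportional).

The generator *does not* emulate: sequencing-read simulation or mapping
error, assembly artifacts, real codon usage or GC bias, TE nesting and
fragmentation, isoform-level differential splicing, batch effects, or
library-size variation beyond what Poisson sampling induces. Realized
subfamily-level TPM correlations sit *below* the latent `block_correlation`
because of three attenuation layers — the lognormal transform, Poisson
sampling, and TPM's compositional closure (each column shares one divisor).
The recovery suites therefore use gentle-noise settings (many genes, small
`signal_sd`, high baseline counts) where the planted structure demonstrably
survives to the network stage; this is a property of the generator
configuration, not a tuning of the detection thresholds, which stay at their
defaults everywhere.

## 8. Determinism

Every generator takes a seed and scopes its RNG use (`.Random.seed` is saved
and restored), stage seeds are derived reproducibly, and all outputs are
plain text written deterministically — the test suite checks that two
pipeline runs with one seed are byte-identical. Problem sizes in the tests
(tens of genes, dozens of samples, graphs ≤ 30 nodes) are chosen so the full
suite runs in well under a minute per module; all algorithms are pure R and
scale as documented rather than being micro-optimized.

## 9. Worked example

```{r example}
library(kinomer)
run <- run_kinome_pipeline(seed = 1, out_dir = tempfile("kinome_run"))
run$report          # kinase counts, tandem and TE percentages, edge counts
run$networks$comparison
```

`scripts/acceptance.R --seed <int> --out <path>` runs the same pipeline plus
the oracle and recovery suites against the installed package and writes the
main quantities as JSON.

## 10. Limitations

* Subfamily classification uses ungapped PSSM placement, not profile HMMs
  with insert states; highly gapped homologs would score poorly.
* Karlin–Altschul constants are fixed ungapped approximations.
* Segmental-tier calls are similarity/distance heuristics; no synteny or
  collinearity evidence is used.
* Hub scores on bipartite components are well-defined here only because of
  the per-component eigenvector convention; plain HITS is not unique there.
* The expression model is a single-factor-per-block latent structure; it
  cannot represent overlapping blocks or condition-specific rewiring beyond
  what the condition labels induce.
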