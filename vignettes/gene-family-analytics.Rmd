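---
title: "Gene-family analytics with orthokit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family analytics with orthokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthokit)
```

# Overview

orthokit implements the analytic core of a modular gene-family analysis
workflow for comparative plant (and general eukaryote) genomics. The
organizing object is the *gene-family scaffold*: a pre-computed
circumscription of genes from a set of reference genomes into orthogroups
(clusters of orthologs and paralogs descending from one ancestral gene).
Around that object the package provides:

* classification of new coding sequences into scaffold orthogroups from
  similarity- and profile-search hit tables, with classifier merging and
  single/low-copy family selection;
* transcript post-processing: open-reading-frame extraction, removal of
  duplicates and exact subsequences, orthogroup-targeted meta-assembly of
  overlapping contigs, and alignment-coverage filtering;
* alignment post-processing: gap-threshold column trimming, low-coverage
  row removal, and back-translation of protein alignments to codon
  alignments;
* phylogeny plumbing: a deterministic neighbor-joining builder and the
  outgroup / most-distant-taxon rooting rule;
* pairwise Ka/Ks estimation by Nei–Gojobori (1986) codon counting with
  Jukes–Cantor correction, and Gaussian mixture modelling of Ks
  distributions to flag genome-duplication components;
* core-orthogroup (CROG) analytics for cohorts of related genomes;
* a leave-one-taxon-out harness for benchmarking classifiers;
* seeded synthetic-data generators that make every stage testable with no
  external program or download.

This vignette records the models, the tunable parameters, and the design
decisions made where the behavior was genuinely open.

# The scaffold model

A `Scaffold` carries the membership table (`gene_id`, `taxon`, `og_id`),
optional per-orthogroup sequences, free-text annotations, and
super-orthogroup labels at multiple clustering stringencies (carried as
opaque labels: re-clustering is out of scope). The membership table is the
single source of truth; the orthogroup-by-taxon count matrix is always
recomputed from it and never read from disk, which prevents silent
inconsistency between artifacts. Taxon order is first-appearance order in
the membership table and every derived matrix uses it, so all outputs are
deterministic. Gene and orthogroup ids are opaque strings; ids containing
the TSV field delimiter are rejected rather than escaped.

One deliberate relaxation: a scaffold may carry all-zero count rows for
orthogroups whose members were removed (see the hold-out harness below);
such orthogroups remain assignable targets.

# Classification

`assignOrthogroups()` implements best-hit classification: each query goes
to the orthogroup of its best passing hit (bit score ≥ `min_bits`, e-value
≤ `max_e`; defaults 50 and 1e-5, a conventional stringent operating point —
both configurable). Ties are resolved bit score → e-value → lexicographic
orthogroup id, making assignment a pure function of the hit set and
invariant under row permutation. Queries with no passing hit are
first-class output (`unclassified`), because the evaluation harness needs
them for its recall denominator.

`mergeClassifications()` combines a similarity-based and a profile-based
table. A gene seen by one classifier keeps that assignment; agreement is
recorded as `both`; on disagreement the profile assignment wins — profile
(HMM) searches are the more sensitive classifier at long evolutionary
distances — and the record keeps `conflict = TRUE` plus the similarity
candidate in `similarity_og`, so the merge is fully auditable and
reversible.

`selectLowCopy()` returns the families conventionally used for species-tree
inference, controlled by three thresholds: maximum copies in any taxon,
minimum taxa present, maximum taxa missing.

# Transcript post-processing

`findOrfs()` is an exhaustive six-frame ORF finder under the standard
genetic code (external gene predictors can replace it at the pipeline
level; the built-in finder is what the tests exercise). Within each frame
the sequence splits into stop-free regions and each region reports at most
one *maximal* ORF: from its first ATG to the terminating stop, or from the
region boundary when `allow_partial` and the region is truncated by a
transcript end. A reported ORF must carry an anchor — a start codon or a
terminating stop; a run truncated at both ends with neither is not a gene
model (hence homopolymer sequences yield nothing). Coordinates are 0-based
half-open on the forward strand; negative frames encode
reverse-complement origin, and the reported CDS is the coding-strand
sequence, so the mapping round-trips unambiguously. The CDS includes the
terminal stop codon when present; the protein never does.

`dedupSequences()` removes exact duplicates and exact subsequences (the
lexicographically smallest id survives among identical sequences); it is
idempotent and partitions its input.

`metaAssemble()` is a deliberately small greedy overlap-layout-consensus
assembler for *orthogroup-targeted* re-assembly: contigs binned to one
orthogroup are repeatedly merged by the longest suffix–prefix overlap
≥ `min_overlap` (default 40 nt) with overlap identity ≥ `min_identity`
(default 0.99); containment counts as a full-length overlap. Overlap
scoring is exact-match seeded Hamming identity — no banded alignment — so
assembly is deterministic and fast at the per-orthogroup scale it is meant
for; fidelity to production assemblers is a non-goal. Consensus within an
overlap is by majority, ties taking the base of the contig with the
lexicographically earlier id. Each output contig records every source
contig id.

`coverageFilter()` (shared with the aligner as
`removeLowCoverageRows()`) drops alignment rows whose global non-gap
fraction is below `min_cov` (default 0.3, our documented choice — at this
scale a transcript covering less than a third of its orthogroup alignment
is more likely mis-binned than informative).

# Alignment processing

`trimAlignment()` keeps exactly the columns whose non-gap fraction is at
least `gt` (default 0.1, mirroring the gap-threshold convention of common
trimming tools); all-gap columns always go, even at `gt = 0`. The fixed
processing order is trim → remove low-coverage rows → optional single
realignment: trimming first means row coverage is judged against the
informative columns, and realignment is bounded to one iteration so the
pipeline always terminates. `backtranslate()` maps each protein gap to
`---` and each residue to its source codon, verifying that the CDS
translates exactly to the ungapped row (a trailing stop is permitted and
dropped). The built-in `"padded"` alignment backend right-pads to the
longest sequence — a stand-in that satisfies every alignment invariant so
downstream stages are testable; real aligners plug in through a
`list(cmd, args)` spec.

# Trees

`njTree()` is standard neighbor joining with two deterministic choices:
ties in the Q-criterion resolve to the smallest (row, column) index pair,
and negative branch lengths clamp to zero. On additive matrices it
reproduces the generating path metric exactly, which the tests verify
against the independent reference implementation in ape. `rerootTree()`
implements the rooting rule applied to orthogroup trees: root on the first
present taxon of a ranked outgroup list, else on the *most distant taxon*
— defined here, since the notion is otherwise informal, as the tip with
maximal mean path length to all other tips (ties lexicographic). The root
is placed at the midpoint of the chosen pendant edge, so unrooted pairwise
path lengths are preserved to machine precision.

# Ka/Ks and Ks mixtures

`ng86()` implements Nei–Gojobori (1986) counting. Per codon, each
position's synonymous-site fraction is the fraction of its three
single-base neighbors that are synonymous, excluding neighbors that are
stop codons from the denominator; nonsynonymous sites are the complement,
so S + N = 3 per compared codon exactly. Site totals are averaged between
the two sequences. Differences in multi-substitution codons average over
all orderings of single-base steps with equal weights, excluding entirely
any path that passes through a stop codon; in the marginal case where
*every* path is blocked the codon pair is skipped altogether (not counted
as compared). Codons containing gaps, ambiguity codes or stops are skipped
the same way. Proportions are corrected with Jukes–Cantor,
d = −(3/4)·ln(1 − (4/3)p), reported as `NA` (saturated) when p ≥ 3/4.
Maximum-likelihood estimators remain a pluggable backend at the pipeline
level; the built-in estimator is fully specified and oracle-checkable,
which is why it is the one under test.

`detectPairs()` derives paralog pairs (best non-self same-species hit per
gene, deduplicated as unordered pairs) or ortholog pairs (reciprocal best
hits between exactly two species) from a hit table, with an alignment
length floor.

`fitKsMixture()` models the Ks distribution as a univariate normal
mixture fitted by EM. The Ks window defaults to [0.02, 4.0], excluding
allelic/assembly noise near zero and the saturated tail. For each
candidate k = 1..`k_max`, `n_starts` seeded runs are initialized by
quantile spread (component means at data quantiles, positions jittered
across starts, common sigma = sd/k); a run converges when the relative
log-likelihood change is below 1e-6 or at 1000 iterations, with a small
variance floor guarding spike collapse. Although the cited clustering
machinery in this field is multivariate, the quantity actually modelled
and plotted is one-dimensional, so the model here is univariate — a
documented simplification. Component count is selected by BIC (an
information criterion is reproducible where a likelihood-ratio bootstrap
would add a simulation layer), and components with weight ≥ 0.05 are
flagged significant; both thresholds are configurable since "significant
component" has no canonical definition. `ksPlotData()` returns the
histogram plus per-component densities scaled to count space, so the
component curves sum exactly to the mixture curve.

# CROG analytics

For a cohort of genomes grouped into genera: each genus's *master set* is
the union of orthogroups with ≥ 1 assigned gene over its genomes;
the *CROGs* are the intersection of all master sets; a genome's *capture
percentage* is the share of CROGs in which it has at least one gene
(presence means count ≥ 1 — no minimum-copy threshold). Gene-count
matrices (CROG × genome, with a cohort parameter so subsets like
polyploid-lineage splits can be analyzed separately) are row-standardized
to z-scores with sample standard deviation (ddof = 1, the convention of
the common plotting stacks; configurable); rows with zero standard
deviation carry no comparative signal and are removed and reported.
`topZ()` ranks a genome's highest-z CROGs (default 150) for inspection,
`captureCorrelation()` reports the squared Pearson correlation of capture
percentages against an external per-genome quality score, and
`clusterOrdering()` emits average-linkage Euclidean leaf orders for
clustermap-style display — the ordering is the tested contract, rendering
is left to the caller.

# Leave-one-taxon-out evaluation

`holdOut()` removes a taxon's genes, returning the reduced scaffold, the
truth map, and the orthogroups emptied by the removal — which are
*retained* as assignable (zero-count) targets and flagged, so the recall
denominator stays honest. `scoreClassification()` counts a true positive
only when a gene is reassigned to its original orthogroup; recall divides
by all held-out genes (assigned or not), precision by the genes the
classifier assigned anywhere, and F-score is their harmonic mean — the
recall/precision decomposition is our documented reading of the
true-positive rule. `evaluateClassifier()` chains hold-out → synthetic
hit generation → assignment → scoring per taxon, and `also_remove` lets a
sister taxon be removed alongside the scored one, expressing
double-removal designs (score a species after also deleting its closest
relative) on synthetic scaffolds.

Label noise (`noise_rate = q`) corrupts an exact `round(q·n)` subset of
the predictions rather than flipping each with probability q: the nominal
rate is then the realized rate, so the degradation property
(recall drops by ≈ q) is checkable at a fixed seed without Monte-Carlo
slack.

# Synthetic data: what it emulates, and what it does not

`simConfig()` defaults define the study conditions used throughout the
tests: 5 taxa, 50 orthogroups, 100-codon genes (desk-scale but long enough
that fragment overlaps exceed the assembler minimum), per-site
substitution probability 0.05, gene birth 0.1 (Poisson extra copies) and
loss 0.1 per taxon, 3-fragment shredding with ≥ 20% pairwise overlaps, and
a two-component Ks mixture 0.6·N(0.2, 0.05²) + 0.4·N(1.5, 0.3²) emulating
a recent small-scale-duplication background plus an older whole-genome
duplication peak. Per orthogroup a random ATG-initiated, internally
stop-free root CDS evolves independently into each taxon's copies;
substitutions are uniform over the three alternative bases, codons
mutating into stops are redrawn, and start/stop codons are conserved, so
every simulated gene stays a valid gene model for the ORF finder and the
Ka/Ks estimator. Everything is seeded and byte-reproducible.

Synthetic classification hits score each query by positional identity to
each orthogroup's majority consensus; by construction the generative truth
is the argmax, so noiseless runs are an exact oracle for the classifier.
Two consequences worth stating. First, noiseless-recovery experiments
generate their scaffold with `death_rate = 0`: an orthogroup present only
in the held-out taxon leaves nothing to classify against, so perfect
recall would be structurally impossible rather than a classifier property.
Second, passing these tests demonstrates the *bookkeeping* is exact — it
says nothing about classification hardness on real diverged sequences,
where hit scores are noisy, domains shuffle, and orthogroups overlap. The
generators likewise omit indels, alternative splicing, codon-usage bias
and sequencing error; fragments are exact substrings. These are
deliberate non-goals: the package tests its own algorithms, not the
biology.

# Numerical and degenerate-input choices

* NJ tie-breaks and the rooting tip choice are lexicographic; clamped
  branch lengths are exactly 0.
* EM guards: responsibilities renormalized per iteration; component
  collapse (vanishing weight or non-finite density) discards the run; the
  variance floor is max(1e-4, sd·1e-3).
* `ng86` returns `NA` (never an extrapolation) for saturated proportions;
  Ka/Ks is `NA` when Ks is 0 or undefined.
* Empty alignments, sub-20-point mixture inputs, constant z-score inputs,
  single-genus CROG cohorts and infeasible low-copy rules are all fatal
  with specific messages rather than silently degenerate output.
* Pipeline artifacts are staged and moved into place only on success, and
  every run writes a manifest (subcommand, inputs, resolved configuration,
  package version) so reruns are verifiably identical.

# Problem sizes used in the checks

The bundled tests run at desk scale, chosen so the full suite and the
acceptance script each finish in a few minutes on one CPU: 1000 random
codon pairs (≤ 30 codons) against the Ka/Ks counting oracle; 10 seeds ×
3000 draws for mixture recovery; 100 random 5–7 taxon additive matrices
for NJ; 5-taxon scaffolds with 50–100 orthogroups (≈ 250–550 genes) for
the classification benchmarks; 100 fragmented genes for assembly
restoration; and a 3-genus / 6-genome planted cohort for the CROG
analytics.

# Known limitations

The built-in assembler and aligner stand-ins are not production tools and
are not meant to be; NG86 underestimates rates relative to ML estimators
at high divergence (the Jukes–Cantor correction assumes equal base
frequencies and rates); the univariate mixture cannot represent
covariation between Ks and other pair statistics; and CROG analytics
presume the classification step upstream was itself sound — garbage
classifications produce confident-looking z-scores.
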