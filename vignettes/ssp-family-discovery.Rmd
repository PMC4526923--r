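---
title: "De novo discovery of small secretory peptide families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo discovery of small secretory peptide families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sspfam)
```

## The problem

Small secretory peptides (SSPs) — CLE, GLV/RGF/CLEL, IDA and their many
relatives in plants — are translated as short preproproteins: an
N-terminal signal peptide targets the precursor to the secretory pathway,
a variable middle region is discarded during maturation, and a short,
conserved stretch at or near the C-terminus carries the biological
activity. Because the conserved part is 10–20 residues long and family
members are otherwise free to diverge, whole-protein homology search finds
few of them, and genome annotation pipelines tend to miss or mis-annotate
the genes entirely. `sspfam` implements a de novo strategy that exploits
the architecture itself: restrict attention to short secreted proteins,
compare only their C-terminal ends, and let weak but consistent local
similarities accumulate into clusters, profile models, and finally
families.

## The pipeline

1. **Candidate selection.** Keep proteins strictly shorter than 200
   residues (`filter_by_length()`), then require a predicted cleavable
   signal peptide (`predict_signal()`).
2. **C-terminal comparison.** Extract the last 50 residues
   (`extract_cterm()`) and score every unordered pair with exact affine-gap
   Smith–Waterman under BLOSUM50 (`all_vs_all()`), a matrix chosen for
   mildly related sequences. Scores become E-values through a Gumbel null
   fitted to shuffled-sequence decoys, and pairs with `E <= 1e-3` become
   edges of weight `-log10(E)` (capped at 200) in a similarity graph.
3. **Sequence-level clustering.** The Markov Cluster Algorithm
   (`mcl_cluster()`, inflation 1.5) partitions the graph into clusters and
   singletons.
4. **Cluster models.** Each cluster is aligned progressively along a UPGMA
   guide tree (`progressive_align()`), gappy and non-conserved columns are
   masked using BLOSUM62 (`prune_columns()`), and the retained columns
   become a calibrated profile HMM (`build_profile_hmm()`,
   `calibrate_hmm()`).
5. **Singleton recruitment.** Remaining singletons are searched against
   all cluster models (`hmm_search()`); each singleton joining at
   `E <= 0.01` triggers realignment, re-pruning, rebuilding and
   recalibration of its cluster, and rounds repeat until no sequence can
   be added (`recruit_singletons()`).
6. **Family assembly.** Cluster models are compared all-against-all with a
   profile–profile co-emission score; significant links (`E <= 0.05`)
   feed a second Markov clustering whose groups are the families
   (`assemble_families()`), each summarised by a consensus motif with
   per-position information content (`consensus_motif()`).
7. **Screening.** Arbitrary proteomes, filtered with the same criteria,
   are scored against each family's representative model and tallied into
   a species-by-family count matrix (`screen_proteomes()`).

`ssp_pipeline()` chains steps 1–6 deterministically given a configuration
(`ssp_config()`) and a seed.

## Models and statistics

### Local alignment and E-values

The aligner is exact Gotoh dynamic programming: a gap of length $L$ costs
$\mathrm{open} + (L-1)\,\mathrm{ext}$ (defaults 10/2), scores are floored
at 0, and traceback ties prefer diagonal over up over left, making results
byte-reproducible. Heuristic seeding (as used by fast database-search
programs) is a speed device, not part of the method's logic, and is
deliberately omitted — at the scale of short-protein C-termini exactness
is affordable.

Raw scores are converted to E-values by fitting a type-I extreme-value
(Gumbel) distribution to Smith–Waterman scores of residue-shuffled decoy
pairs drawn from the segments themselves (`fit_score_background()`). The
fit is a 1-D profile maximum likelihood: the scale solves
$\beta = \bar x - \sum_i x_i e^{-x_i/\beta} / \sum_i e^{-x_i/\beta}$ by
root bracketing, and the location follows in closed form. Empirical
calibration is preferred over published Karlin–Altschul-style constants
because it is correct for any matrix/gap combination the configuration
selects. All segments share the same 50-residue window, so a single
pooled length class is fitted. With $n$ comparisons,
$E(S) = n\,(1 - \exp(-e^{-\lambda (S - \mu)}))$, floored at $10^{-200}$
so that $-\log_{10} E$ edge weights stay finite.

### Markov clustering

MCL alternates expansion (matrix squaring) and inflation (entrywise power
1.5 followed by column renormalisation) on the column-stochastic transition
matrix of the similarity graph, pruning entries below $10^{-5}$, until the
largest entry change falls below $10^{-8}$. Self-loops take the maximum
incident edge weight (1 for isolated nodes), the convention of the
reference MCL implementation. Clusters are read off as connected components
of the attractor structure; nodes attracted by several systems join the
cluster containing the smallest member id, making the partition
deterministic. Inflation is the granularity dial: the bundled
bridged-cliques fixture splits at inflation 1.5 and never coarsens as
inflation grows.

### Profile HMMs

Cluster models use a single-hit local architecture: uniform begin-entry
over match states, a small fixed exit probability (0.05) from every
internal match state plus certain exit from the last one, and N/C flanking
states that self-loop on background emissions so the motif may sit
anywhere in the precursor. There is no multi-hit state — a bioactive motif
occurs once per preproprotein. Match emissions are Henikoff
position-weighted counts mixed with one background-distribution
pseudocount; transitions come from the observed match/insert/delete paths
with add-one smoothing; inserts emit background. Scores are log-odds bits
against a geometric-length background null, reported from the Viterbi
path (the forward sum is available behind a flag); `X` residues emit
background in both numerator and denominator and so contribute zero.
Null calibration scores 1000 i.i.d. background sequences of length 350
and fits the same Gumbel by maximum likelihood, seeded and reproducible.

### Profile–profile comparison

Two profiles are compared by local dynamic programming over their
match-state pairs with the co-emission column score
$s(i,j) = \log_2 \sum_a p_i(a)\,q_j(a)/f(a)$ and affine profile-level
gaps (5/1 bits). The score is exactly symmetric. Its null distribution
comes from re-scoring against column-shuffled copies of the second
profile; a Gumbel is fitted to the 200 decoy scores when they vary, and
when they are degenerate (typical for unrelated profiles, whose local
scores floor at 0) an empirical rank p-value
$(1 + \#\{d \ge S\})/(n+1)$ is used instead. Both routes are
deterministic given the seed. Full five-state profile–profile forward
algorithms exist; the match–match simplification retains what the family
step needs — detecting that two cluster models describe the same motif —
with a recurrence that is directly testable.

### Signal-peptide heuristic

Neural-network predictors are not reproduced. A transparent von
Heijne-style rule stands in, with an import path
(`import_signal_predictions()`) for externally computed tables that
override it. A protein is signal-positive when (i) some 8-residue window
in the first 40 has mean Kyte–Doolittle hydropathy at or above the
threshold, (ii) the region before that window has non-negative net charge
(K/R vs D/E), and (iii) small residues (A, G, S, C, T) occupy the −1 and
−3 positions of some cleavage site whose mature region starts at position
15–45 after the hydrophobic core. The hydropathy threshold defaults to
2.2: on synthetic benchmarks this keeps sensitivity at 1.0 for designed
signal peptides while holding the false-positive rate on
background-composition proteins below 10%. The threshold is a tunable
with no literature anchor; lowering it toward 1.6 admits markedly more
false h-regions in random sequence (observed false-positive rate 22%).
All three rules and their constants are configuration keys.

## The synthetic benchmark

`generate_dataset()` plants families into an otherwise random proteome:
each record is signal peptide + background-composition linker + mutated
motif copy + 0–5 tail residues, with the motif ending within 5 residues of
the C-terminus, mirroring the canonical SSP architecture. Default study
conditions: 5 families × 8 members, motif length 14, per-residue motif
divergence 0.10, 40 decoy records sharing the architecture but lacking a
motif, mature length ~ N(70, 15²), seed 42.

Three generator choices deserve comment.

* **Substitutions resample uniformly** over the 20 residues and may
  silently restore the ancestor, so expected within-family identity is
  analytic: $1 - d \cdot 19/20$.
* **Ancestor motifs are drawn uniformly but rejected** if they exceed 25%
  identity to an earlier ancestor in any ungapped register (overlap ≥ 7).
  Distinct planted families are *defined* as unrelated; without the
  rejection step, chance collisions between random 14-mers occasionally
  produce two "different" families sharing a statistically significant
  sub-motif, and the ground-truth labels — not the method — would be
  wrong about them.
* **Decoys share the linker composition**, so they stress the E-value
  machinery rather than trivial composition filters.

Two scenario generators probe the two-level logic. The *split* scenario
(`generate_split_scenario()`) plants two unrelated motifs at low
divergence; the pipeline should keep them as two families. The *unified*
scenario (`generate_unified_scenario()`) derives two sub-lineages from one
ancestor, each lineage replacing an exact, disjoint 20% of motif
positions with guaranteed-different residues (so the sub-ancestors differ
at exactly 40% of positions — the divergence is part of the scenario's
definition rather than a noisy realisation) and mutating members at only
0.04 within lineages. Sequence-level clustering separates the lineages;
profile–profile comparison should reunite them into a single family, the
behaviour that distinguishes family-level from cluster-level relatedness.

What passing these benchmarks does *not* show: the generator has no
indels inside motifs, no compositional bias, no shared domains outside
the motif, and no phylogenetic correlation between members. Real
proteomes contain all four, so synthetic recovery rates are upper bounds
on real-data behaviour, and screening of real genomes should always use
externally validated signal-peptide calls where available.

## Numerical choices and degenerate inputs

* Column-stochasticity is tracked through every MCL normalisation; the
  maximum observed deviation is reported on the clustering object
  (`max_colsum_dev`, at machine precision on the bundled fixtures).
* Pruning that removes every column raises `"no conserved region"`; such
  clusters are flagged, skipped by the HMM stages, and reported.
* A degenerate decoy-score distribution (all scores equal) is an error in
  Gumbel fitting — the advice is to raise the number of decoys.
* Guide-tree ties join the lexicographically smallest label pair;
  alignment traceback ties prefer diagonal, then up, then left; singleton
  recruitment ties join the lower cluster id. Every tie-break is
  deterministic by construction.
* Profiles shorter than the window keep their whole sequence as the
  "C-terminal" segment: discarding them would drop exactly the tiny SSPs
  the method exists to find.
* E-values in the final screen use the total number of comparisons
  (proteins × profiles), so the 0.05 cutoff bounds the expected number of
  false assignments per screen; `hmm_search()` during recruitment scales
  by the number of target sequences, the usual sequence-database
  convention.

## Problem sizes

The bundled analyses run at desk scale by design: 80-protein benchmark
proteomes, 50-residue segments, ~3,200 alignment pairs, calibration with
1,000 null sequences per model and 200 shuffled profiles per comparison.
The full benchmark (generation, pipeline, screening and both scenarios)
completes in well under a minute on one core; genome-scale inputs
(tens of thousands of proteins) would want the all-vs-all step chunked or
distributed, which the per-module API supports but the package does not
automate.

## A worked example

```{r example, eval = FALSE}
ds <- generate_dataset(synthetic_spec(seed = 42L))
res <- ssp_pipeline(ds$proteins, seed = 42L)
res
#> SSP pipeline result: 80 proteins -> 5 clusters ( 40 singletons ) -> 5 families

evaluate_clustering(family_assignment(res), truth_labels(ds$truth))$ari
#> [1] 1

scr <- screen_proteomes(res$families, ds$proteins)
scr$family_matrix
#>            f1 f2 f3 f4 f5
#> synthetica  8  8  8  8  8
```

## Known limitations

* The signal-peptide heuristic is deliberately simple; on real proteomes
  it should be treated as a pre-filter and replaced by imported
  predictions from a dedicated tool whenever possible.
* The progressive aligner has no iterative refinement, so early guide-tree
  errors persist; clusters here are small sets of short segments, where
  the effect is minor.
* Profile–profile comparison uses match–match co-emission only; profiles
  whose relatedness is carried mainly by shared gap structure would be
  under-linked.
* E-value calibrations are seeded Monte Carlo; E-values are reproducible
  but carry sampling error of order $1/\sqrt{n_{\mathrm{decoys}}}$ on the
  p-value scale.
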