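---
title: "Methods and design choices in phaseomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in phaseomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phaseomics` analyses growth-phase resolved multi-omics time courses of
bacteria — the setting of batch fermentations of filamentous actinomycetes
such as *Actinoplanes* sp. SE50/110, sampled at seven times across lag,
growth, transition and stationary phase in three biological replicates. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, what the synthetic data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Growth and specific product formation

Cell dry weight (CDW, g/L) in `simulate_growth()` follows a logistic curve
with rate `mu` (default 0.06 per hour), inoculum `X0` (0.4 g/L) and capacity
`Xmax` (20 g/L). Product formation is growth-associated: the specific
production rate is modelled as a single-peak pulse
`q(t) = q_max (t/t_peak) exp(1 - t/t_peak)` (default peak 2 mg/g/h at 36 h),
and the product concentration is the integral of `q(t) X(t)` — hence
non-decreasing and flat in stationary phase.

`specific_product_formation()` computes, for each pair of consecutive
sampling times, the product increment normalized to the arithmetic mean of
the two endpoint CDW values and to the interval length:

    q_i = (P_i - P_{i-1}) / (((X_i + X_{i-1})/2) (t_i - t_{i-1}))

in g(product) g(CDW)^-1 h^-1. The endpoint mean is our reading of "mean cell
dry weight over the interval"; replicates are averaged per time point before
the rate is formed (a per-replicate mode is exposed). The rates telescope:
`sum_i q_i meanX_i dt_i` equals the total product increment exactly, which
the tests verify to machine precision. `annotate_phases()` labels times with
lag/growth/transition/stationary using half-open boundary conventions chosen
so that a boundary sample (e.g. 120.0 h) belongs to the later phase.

## Pooled-reference M-values and significance

Count tables are depth-normalized by median-of-ratios size factors
(`size_factor_normalize()`), rescaled to geometric mean one. The
pooled-reference M-value of feature f at time t is

    M[f,t] = log2( mean_reps(x[f,t]) / reference[f] ),
    reference[f] = mean over time of mean_reps(x[f,t])

i.e. the in-silico analogue of hybridising each sample against an equimolar
pool of all time points. By construction `mean_t 2^M = 1` exactly for every
feature — an identity the acceptance tests check at machine precision.

Per-time-point significance (`test_significance()`) is a Welch two-sample
t-test of a time point's replicate values against the pooled replicates of
all other time points, on the log2 scale, followed by Benjamini-Hochberg
adjustment across all tests of a layer and a strict `p_adj < 0.05` call.
Design notes:

* The "time point versus pooled rest" contrast mirrors the fold-change
  definition against the all-time-point mean; it is our reading of the
  two-sample design, stated as such.
* Welch's unequal-variance form is the robust default with three replicates.
* Exactly `p_adj = 0.05` is *not* significant (strict less-than), so a
  feature at the boundary everywhere is ruled out by `filter_dynamic()`.
* Reported percentages round half away from zero to one decimal
  (`summarize_significance()`), so 98% prints as 98.0 and 6.25% as 6.3.

The proteome filter cascade drops proteins identified by fewer than two
unique peptides, blanks every (protein, time) cell not quantified in all
three replicates, and z-normalizes each protein's log2 intensities over its
retained cells. The two filter rules commute (tested). Protein M-values are
computed from the positive LFQ intensities; the z-scores feed the t-tests.
Fraction reconciliation keeps a protein detected in both the cellular and
extracellular fraction only in the extracellular set when its localization
prediction (signal peptide) is extracellular.

## Operons, TSS and promoters

`call_primary_operons()` joins consecutive same-strand genes when the
intergenic distance is at most `d_max` (default 500 nt) and the minimum
combined coverage across the gap is at least `f_min` (default 0.5) of the
weaker flanking gene's mean coverage. Coverage is combined (summed) over all
time points before calling, which lifts weakly covered regions above the
threshold. Both thresholds are exposed; the defaults were chosen once as
plausible spanning-transcript evidence and are exercised against planted
ground truth (gene-pair co-membership Jaccard >= 0.95 required by the
acceptance suite).

`detect_tss()` calls a candidate where the 5'-read-start count is at least
`min_starts` (10) and at least `fold_bg` (5) times the mean start count in
the preceding `bg_window` (50 nt, upstream in transcription direction).
These thresholds replace a manual curation step and are deliberately
deterministic. `assign_primary_tss()` first sends each candidate to its
nearest downstream translation start within 500 nt (resolving overlapping
claims), then picks per gene the candidate with the highest count, breaking
ties towards the TLS-proximal one (determinism). The 5'-UTR is the TSS-TLS
distance; at most 3 nt means leaderless.

Promoter elements are discovered by a ZOOPS (zero-or-one occurrence per
sequence) EM over the 50 nt upstream of each TSS. The E-step computes a
posterior over motif start offsets plus a no-site option under a fixed
0-order background; the M-step re-estimates the 4 x 6 frequency matrix with
a 0.25 pseudocount per cell. The pseudocount makes the procedure MAP-EM
under a Dirichlet(1.25) column prior, so the monotone objective reported as
`loglik` is the penalized log-likelihood; the tests assert monotonicity per
iteration. Twenty seeded restarts (each initialised from a random window
subsequence) guard against local optima; a window is a hit at site posterior
>= 0.5. The -10 search uses a mild geometric proximity prior
(`offset_decay = 0.9`) anchored at the TSS-proximal end — the -10 element
sits a few nt upstream of the TSS, and location-weighted motif samplers use
the same device; the -35 is then searched uniformly in the sub-window
upstream of each -10 hit. Spacers are exclusive gaps: -10 3' end to TSS, and
-35 3' end to -10 5' start; the -35/-10 statistic uses only windows with
both hits. The ribosome-binding-site search runs the same EM on the final
20 nt (a Shine-Dalgarno positional range) of leadered 5'-UTRs longer than
10 nt.

## Ward clustering and the Krzanowski-Lai index

Profiles are M-value vectors over the seven time points. Features observed
at fewer than two thirds of the time points (ceiling: 5 of 7) are dropped;
remaining gaps are imputed with the mean of the nearest *originally
observed* earlier and later values, and boundary gaps copy the single
available neighbour (the neighbour-mean rule only covers interior points;
the boundary policy is ours).

Clustering is agglomerative Ward on Euclidean distances — the convention in
which each merge minimizes the increase in total within-cluster sum of
squares (`stats::hclust(method = "ward.D2")`). "Ward + Euclidean" is
ambiguous between two common conventions; we chose the variance-minimizing
one and verify it against an exhaustive greedy SSE oracle on small inputs
(100 seeds in the acceptance suite). The within-cluster dispersion trace
`W_k` for dendrogram cuts k = 1..51 (`k_max = 50`) feeds the Krzanowski-Lai
index

    DIFF(k) = (k-1)^(2/p) W_{k-1} - k^(2/p) W_k
    KL(k)   = |DIFF(k)| / |DIFF(k+1)|

whose maximizer over k in [2, k_max] estimates the cluster number; p is the
profile dimension. Numerical choices: ties break towards smaller k
(parsimony); k with `DIFF(k+1) = 0` are skipped; and candidates whose
numerator `|DIFF(k)|` is below `1e-3 x max|DIFF|` are excluded from the
argmax. The last rule matters in practice: in the structureless tail of the
trace DIFF fluctuates around zero, and a chance near-zero denominator under
an equally tiny numerator otherwise produces an arbitrarily large, spurious
KL maximum at a meaningless k. A genuine optimum has a large numerator and
is never excluded. When the selected maximum barely exceeds the trace median
(contrast < 2) the result carries a low-contrast warning. Cluster-category
enrichment is a hypergeometric upper-tail test per (cluster, category) with
BH adjustment — the test is our choice; no specific test was prescribed.

## Cross-omics comparison

Only features with both a transcript and a protein profile are paired
(`pair_features()`); each layer is then clustered independently with the
same Ward/KL machinery (`combined_clustering()`, `k_max = 50`). The
co-occurrence matrix gives, per transcriptome cluster, the percentage of its
members in each proteome cluster — rows sum to 100 exactly before rounding.
`lagged_pearson()` correlates, across paired features, transcript M at time
t with protein M at time t + lag; lag 1 captures a one-sampling-interval
transcription-to-translation offset. Correlations are computed on M-values
(replicate means), features with missing values are excluded pairwise, and a
per-feature across-time mode is exposed because the per-time-across-features
reading of a global transcript-protein correlation is not the only possible
one.

## The synthetic data generator

`simulate_genome()` plants, on a GC-rich (0.71) genome, transcription units
whose sizes follow a configurable distribution, a primary TSS with -10/-35
promoter for 70% of units (the rest emulate predicted, non-validated
operons), internal TSS on posterior genes at rate 0.4 (the source of
sub-operons), 14% leaderless TSS, leadered UTR lengths geometric with mean
80 within 4-494 nt, -10-to-TSS spacers uniform on 5-7 nt, -35-to--10 gaps
normal (17.6 +/- 2.5 nt), an 93.2% GGAGG ribosome-binding-site rate and a
75.4% purine TSS base rate (24.2% A, 51.2% G). Internal-TSS UTRs are capped
at 250 nt so an internal TSS always sits closer to its own gene's start than
to any upstream gene's. `simulate_tracks()` reports coverage as expected
depth (the combined evidence of 21 libraries, where counting noise is
negligible) with Poisson 5'-read starts — planted TSS at mean 100 over a
0.05/nt background. `simulate_expression()` draws negative-binomial counts
(shared dispersion 0.05 — the gamma-Poisson model standard for RNA-seq)
around archetype mean profiles x log-normal library factors (CV 0.1, a knob
because between-replicate depth variation is otherwise unspecified), and
log-normal LFQ intensities (sigma 0.2 log2 units) with 10% missingness for
50% of genes; 30% of detected proteins follow their transcript archetype
delayed by one time point, the first protein point copying the first
transcript point. Growth emulation uses the canonical sampling grid 24.0,
47.8, 72.3, 96.5, 120.0, 144.3, 168.0 h.

What the generator does **not** emulate: read-level sequencing artefacts,
codon usage and sequence-driven expression biases, correlated (non-MCAR)
proteome missingness at low intensities, antisense transcription, condition-
dependent operon structure, and batch effects. Passing the recovery tests
therefore shows the algorithms are correct under the stated statistical
model, not that their thresholds are optimal on any particular real data
set.

## Problem sizes and determinism

All randomness flows from one integer seed per simulation (`sim_config()`'s
`seed`); identical seeds give bit-identical genomes, tracks, matrices and
pipeline output files. Test and acceptance runs use deliberately compact
problem sizes — 100-600 genes, 500 features for cluster-number recovery,
220 windows for motif recovery, 20 seeded repetitions where rates are
asserted — chosen so the full validation remains quick on a laptop while
keeping binomial tolerances (3 sigma) meaningful. The KL k-recovery test
plants centers at a minimum pairwise separation of 8x the noise sd, the
regime the generator's own archetypes occupy (their minimum profile distance
is 1.41 against replicate-mean M-value noise of about 0.2); recovery
degrades, as expected for any cluster-number index, when separations
approach the noise vector magnitude.

## Known limitations

* The operon joining rule is a coverage-continuity heuristic; paired-end
  spanning evidence, where available, is stronger.
* The transcript significance test is the same t-test-versus-rest used for
  proteins, not a negative-binomial count model; with three replicates it is
  conservative for low counts. The NB count model is deliberately out of
  scope — the simulator uses it, the tests do not re-implement it.
* EM motif alignment is identifiable only up to small offsets when motif
  flanks are uninformative; consensus strings are stable but -35 spacer
  means can shift by about one nt between runs with few windows.
* KL-selected k on real data depends on `k_max` and the dispersion trace
  shape; the low-contrast warning should be heeded.
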