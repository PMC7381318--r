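---
title: "Core collection selection: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core collection selection: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `coreselect`, the conventions it
adopts where the underlying methodology leaves room, and what its synthetic
benchmarks do and do not demonstrate about real data.

## The problem

A germplasm collection of N accessions, genotyped at m biallelic SNP
markers, is to be reduced to a core of k accessions. Two goals compete:

* **CC-I (representation)**: every accession should have a similar entry
  nearby — minimize the average accession-to-nearest-entry distance
  (A-NE).
* **CC-X (spread)**: entries should be as dissimilar as possible —
  maximize the average entry-to-nearest-entry distance (E-NE).

Allele-pool criteria (Shannon diversity, expected heterozygosity, allele
coverage) judge the core by its pooled allele counts instead of by
pairwise distances.

Genotypes are stored as reference-allele dosages in {0, ½, 1}; a
heterozygote is an individual whose two alleles differ, and its
within-individual allele frequency of ½ enters the distance and diversity
formulas directly. Phase is ignored.

## Distances

For individuals i, j with per-locus allele frequencies `p_ila`:

* MRD: `sqrt( (1/2m) Σ_l Σ_a (p_ila − p_jla)² )`. For biallelic loci the
  inner sum is twice the squared dosage difference, so MRD equals the
  Euclidean distance between dosage vectors divided by `sqrt(m)`. This
  makes MRD a true metric (triangle inequality holds) and makes the MRD
  matrix exactly embeddable by classical scaling.
* CSE: `sqrt( (1/m) Σ_l (1 − Σ_a sqrt(p_ila p_jla)) )`, the chord-type
  distance on square-root frequencies, likewise normalized to [0, 1].

The forms above are the normalized variants standard in core-selection
software, with the biallelic specialization documented in `?mrd_dist`.
Both default to requiring complete data (distances are meant to be
computed after imputation); a pairwise-complete-loci mode exists for
pre-imputation exploration and errors when a pair shares no loci.

**PCoA.** `pcoa_classic()` double-centers the squared distances and
eigendecomposes (via `stats::cmdscale`). Negative eigenvalues — absent
for MRD up to rounding — are excluded from both the coordinates and the
variance-explained denominator, and no additive correction is applied:
for near-Euclidean inputs a correction would only perturb the variance
shares that the analysis reports.

## Marker placement

Array probes come as context sequences `LEFT[X/Y]RIGHT`. They are split
at the polymorphic site into pseudo paired-end reads (the right flank
reverse-complemented) and aligned externally; the package consumes the
resulting SAM/BED-level records. The consistency filter then requires,
per marker: a single surviving primary alignment per mate with
MAPQ ≥ 20 (inclusive), full-length-match CIGARs, both mates on one
chromosome in convergent orientation, an inner gap of exactly one
reference base (that base is the SNP), and a non-`N` reference base at
the gap. Markers failing any step carry exactly one machine-readable
reason (`mate`, `ambiguous`, `cigar`, `orientation`, `gap`, `N-site`,
`lookup`), assigned in that order, so the reasons partition the rejected
set. Positional duplicates keep the first marker in manifest order.

Three conventions are declared here because the procedure as commonly
described leaves them open: (1) a marker whose pair aligns in the reverse orientation
(left read on the minus strand) is accepted with complemented alleles
and the strand recorded, mirroring standard proper-pair semantics;
(2) mates with several equal-quality surviving alignments are rejected
as `ambiguous`, since only uniquely placed markers are wanted;
(3) gapped flank alignments are rejected (`cigar`) because an indel in a
flank shifts the SNP coordinate unpredictably.

## Marker QC

The cascade order is fixed: (a) remove markers with ≥ 30 % missing
calls, monomorphic markers (all non-missing calls equal — an all-
heterozygote marker still segregates and is kept) and duplicate call
vectors (first kept); (b) impute; (c) keep markers with MAF ≥ 5 % and
heterozygous-call fraction ≤ 12.5 %. All boundary semantics are
inclusive on the side just stated. The heterozygosity filter is
interpreted as the *observed* heterozygous-call fraction; an
expected-heterozygosity reading would also be defensible, but the
observed fraction is what an array QC pipeline sees directly.

Imputation is a deliberately naive, seeded stand-in: each missing call
is drawn from the marker's observed genotype frequencies. It preserves
marginal frequency spectra but ignores linkage, which is acceptable here
because every downstream statistic in this package is a function of
single-locus frequencies. Haplotype-aware imputed matrices can be
supplied instead, and a `no_impute` path keeps missing data through
pairwise-complete distances.

`collapse_perfect_ld()` implements the array-design step of collapsing
haplotype blocks: markers whose call vectors are identical *or exactly
complementary* (the same marker under flipped allele coding) form one
block, from which one or two representatives are retained.

## Selection algorithms

**PAM k-medoids** works on the distance matrix. BUILD starts from the
accession minimizing total distance and greedily adds the accession with
the largest cost reduction; SWAP applies the best-improving
(medoid, non-medoid) exchange until none improves. Ties are broken by
lowest accession index, so PAM is fully deterministic given its inputs;
stability experiments therefore feed it freshly sampled random initial
medoids per replicate (which skips BUILD), as a replicated
comparison requires. Swap deltas are computed from nearest/second-
nearest caches, which reproduces the classic best-improvement choice at
a fraction of the cost. Note that PAM is a local search: on adversarial
geometries it can settle in a non-global single-swap optimum (the
reference implementation in the `cluster` package does too, on the same
instances); on clustered data of the kind it is meant for it recovers
the exhaustive optimum.

**Local search** replaces the original multi-start metaheuristic engine
with seeded random descent: from a random k-subset, random
selected-for-unselected swaps are accepted when strictly improving,
with incremental objective updates (O(N) for A-NE, O(k) for E-NE, O(m)
for the allele-pool criteria per proposal). The claims this package
evaluates — objective values reached and run-to-run variability — only
need a well-mixing stochastic improver, not the exact annealing
schedule; equivalence with any particular external optimizer is not
claimed. Determinism comes from a self-contained splitmix64 generator,
so results are identical across platforms and unaffected by R's RNG
state. Defaults are 50 000 evaluations with patience 5 000 and a single
restart; restarts are the main lever for near-exhaustive quality on
small instances (10 restarts recover the exhaustive optimum on
8-choose-3 instances in ≥ 95 % of seeded runs, measured in the test
suite).

**Random baseline**: a uniform k-subset, the no-information reference
for both stability and quality.

## Evaluation harness

`run_stability()` runs one method R times (seeds `base_seed + 1 … + R`)
and records each accession's selection frequency `f_i`; `Σ f_i = k`
always. The ecdf of `f` is the visual diagnostic; as a scalar summary
the package defines the stability index `S = 1 − mean(4 f (1 − f))`,
which is 1 exactly when every accession is always or never selected and
0 when all frequencies are ½. The index is this package's own
quantification; the ecdf, the classical diagnostic, is still emitted.

`quality_table()` evaluates every produced core under one common metric
(MRD by default, regardless of the metric used during selection, so
that methods are compared on one scale). `compare_methods()` runs the
full grid — by default the seven optimizer settings (E-NE and A-NE
each under MRD and CSE, plus Shannon, expected heterozygosity and
allele coverage), the k-medoids baseline and the random baseline — and
reports stability and quality per method and core size. The
seven-setting enumeration (2 distance objectives × 2 metrics + 3
allele-pool objectives) is the only combination consistent with the
described design and is declared as such.

## Synthetic data

`sim_genotypes()` draws, per marker, an ancestral frequency uniform on
`ancestral_freq_range` (default 0.1–0.9); per collection, a
Balding–Nichols Beta frequency with shapes `p(1−F)/F` and
`(1−p)(1−F)/F` (point mass at `p` when `F = 0`); and per accession a
genotype with heterozygote probability `2pq(1 − f)` under inbreeding
coefficient `f` (default 0.9, a selfing crop, which keeps per-marker
heterozygosity comfortably below the 12.5 % QC bound). Defaults mirror
a realistic winter wheat panel: five collections of 92/284/40/220/254
accessions; 1 000 markers for routine tests. Missingness is MCAR (no
mechanism is reported for the real data; defaults are declared, not
inferred). All draws flow from one master seed in documented order, so
identical configurations are bit-identical. A Weir–Cockerham multilocus
F_ST estimator, implemented independently in the test suite, recovers
the configured F within ±0.02 at the stated benchmark size.

What the generator does **not** emulate: linkage maps and LD decay
(markers are independent), realistic wheat allele-frequency spectra,
genotyping error, and structured (non-MCAR) missingness. Passing the
package's ordering benchmarks therefore shows that the *methods* behave
as described under clean population structure — not that any particular
real collection will reproduce the same numeric ranges.

## Benchmark configurations

The test suite works at deliberately reduced sizes chosen so each check
still exercises the property it targets: grid accounting on 60
accessions × 100 markers with two core sizes and 1 000 replicates
(minimal search budgets — the check is about bookkeeping); exhaustive
oracles at N ≤ 10; and the ordering benchmark on 200 accessions × 500
markers, F = 0.1, core sizes 40 and 72 (20 % and 36 %
sampling fractions), R = 100 replicates, aggregated over 10 data seeds,
with a search budget of 10 000 evaluations (≈ 1.5 × the swap
neighborhood, enough for approximate convergence of the descent). On
this benchmark the expected qualitative pattern emerges: random and
allele-coverage selections are unstable and alike; the distance-based
objectives and k-medoids occupy a middle stability band; Shannon and
expected heterozygosity are most stable; k-medoids or the A-NE
objective attain the lowest mean A-NE; the E-NE objective attains the
highest mean E-NE; and MRD- versus CSE-based selection changes the
quality means by well under 10 %.

## Known limitations

* The local search is not a re-implementation of any external
  optimizer's schedule; absolute objective values at fixed budgets are
  implementation-specific even though orderings are robust.
* Allele-pool statistics assume complete data over the evaluated
  entries; impute (or filter) first.
* Only biallelic, diploid markers are supported; polyploid dosages,
  phased haplotypes and multi-allelic loci are out of scope.
* The placement stage consumes alignments; it does not run an aligner.
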