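---
title: "Quality-aware meta-calling of structural variants: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-aware meta-calling of structural variants: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmeld)
library(data.table)
```

## The problem

Structural variants (SVs) — deletions, insertions, duplications and other
rearrangements of at least 50 bp — are hard to call from short-read
whole-genome data. Individual callers (read-pair, split-read, read-depth or
assembly based) each miss substantial fractions of true SVs and emit
caller-specific artifacts, so practice has converged on *meta-calling*:
merging several callers' outputs into one consensus set. Most consensus
tools score a merged call only by *which* callers support it. That discards
the per-call evidence every caller already reports in its VCF: supporting
read-pair and split-read counts, local depth, genotype and mapping
qualities, microhomology lengths, breakpoint precision flags.

`svmeld` keeps that evidence. Calls of the same type are clustered by
breakpoint proximity into consensus calls; each consensus call is described
by a vector of harmonized per-caller quality metrics; a gradient-boosted
tree classifier, trained against a truth set, maps the vector to the
probability that the call is a true positive. The probability is written as
the QUAL value of the consensus VCF, giving a continuous ranking that can
be thresholded to any sensitivity/precision trade-off. A call seen by a
single caller with excellent support metrics can outrank a call seen by
three callers at their noise floor — the failure mode of count-based
consensus scoring.

## Pipeline

1. **Parse and filter** (`parse_caller_vcf`, `filter_sv_calls`). Each
   caller's VCF is read under a *dialect* describing its SVTYPE codes and
   metric fields. Duplications fold into `INS` permanently at parse time
   (the two classes are modeled together). Negative deletion SVLENs are
   absolute-valued; `chr` contig prefixes are stripped; records below
   50 bp, and optionally off-autosome or genotype-missing records, are
   dropped. A metric value a caller does not report, or reports
   unparseably, is *missing* (`NA`), never 0.
2. **Merge** (`merge_calls`). Same-type calls on the same contig are
   linked when *both* breakpoints agree within `max_dist` (default
   1000 bp); clusters are the connected components of this relation.
   Representative `pos`/`end`/`svlen` are member-wise lower medians.
   Single-caller clusters are kept (`min_support = 1`): scoring them is
   the point of the method.
3. **Featurize** (`build_feature_matrix`). One row per consensus call,
   one column per registered (caller, metric) pair, named
   `caller.metric`, plus the SV length. Coverage-referring metrics are
   divided by mean coverage, read-length-scale metrics (e.g. the average
   edit distance of insertion-supporting stable reads) by read length, so
   features are dimensionless and portable across sequencing depths.
   Absent callers contribute `NA` throughout.
4. **Classify** (`grid_search_train`, `predict_probabilities`). A gbtree
   booster with exact greedy splits and binary-logistic objective;
   hyperparameters chosen by stratified cross-validated AUC; features
   with zero gain importance iteratively discarded and training repeated.
   The *basic model* (BM: SV length + per-caller 0/1 presence) is the
   baseline that quantifies what the quality metrics add over caller
   agreement alone; the *full model* (FM) is what ships.
5. **Rank and write** (`write_consensus_vcf`). QUAL = TP probability
   (4 decimal digits); INFO records SUPP, CALLERS and MEMBER_IDS so every
   consensus entry traces back to the standalone VCFs. Calls with
   probability ≥ 0.5 (inclusive) are classified positive; the full ranked
   set is always written.

Benchmarking (`match_to_truth`, `compute_metrics`) matches calls to truth
records one-to-one when same chrom and type, both breakpoints within
`ref_dist` (default 500 bp), and size similarity
$\min(\ell_c,\ell_t)/\max(\ell_c,\ell_t) \ge 0.7$; assignment is greedy by
ascending breakpoint distance $|\Delta pos| + |\Delta end|$ with
deterministic tie-breaks (smaller truth, then call, position). Sequence
comparison is not performed. Reported are
$\mathrm{precision} = \frac{TP}{TP+FP}$,
$\mathrm{recall} = \frac{TP}{TP+FN}$ and
$$F_1 = \frac{2\,TP}{2\,TP + FP + FN},$$
with FN counting *all* unmatched truth records, including SVs no caller
reported at all. Empty denominators yield 0 by convention; printed tables
round half-up to 2 decimals only at report time.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_svlen` | 50 | bp | the conventional SV size floor; the bound is inclusive |
| `max_dist` (merge) | 1000 | bp | breakpoint tolerance between callers; both ends must agree, preventing a short deletion chaining onto a long one via a shared breakpoint |
| `min_support` | 1 | callers | keep single-caller calls and let the classifier judge them |
| `ref_dist` (bench) | 500 | bp | truth-matching breakpoint tolerance |
| `size_similarity_min` | 0.7 | ratio | truth-matching length agreement |
| `mean_coverage`, `read_length` | required | x, bp | normalization scales; cannot be inferred from VCFs, hence required arguments |
| `decision_threshold` | 0.5 | prob. | positive iff probability ≥ threshold (inclusive) |
| `r_threshold` (pre-selection) | 0.90 | \|r\| | prunes near-duplicate features before the learner's own importance-based pruning; Pearson, pairwise-complete |

The hyperparameter grid defaults to max depth {3, 5, 7}, learning rate
{0.05, 0.1, 0.3}, rounds {100, 300}, min child weight {1, 5}, selected by
mean 5-fold stratified CV AUC under a fixed seed; the chosen point, the
full CV table and the gain importances are stored in the model artifact
(JSON sidecar next to the serialized booster). Tests and the acceptance
script pass a reduced grid (depth {3, 5}, learning rate 0.3, 100 rounds) —
the package's desk-scale protocol; the grid is configuration, not part of
the method.

## Dialects and feature registries

The exact VCF fields each caller emits vary by caller version, so the
dialect registry is data-driven configuration (`caller_dialect`), not
hard-coded truth. The shipped defaults register the evidence classes a
practitioner would harvest: read-pair/split-read support counts and local
depth (coverage-normalized), qualities (QUAL, GQ, mapping qualities, the
CNV-likelihood score of read-depth callers), allele fractions,
microhomology lengths, consensus-sequence entropy, PRECISE/IMPRECISE
flags, and — for the insertion specialist — stable-read metrics including
the average edit distance normalized by read length. Strand-bias metrics
are registrable but excluded from the default insertion registry.

Deletion features draw on BreakDancer, Delly, LUMPY, Manta, Pindel and
TARDIS; insertion features on Delly, INSurVeyor, Manta, Pindel and TARDIS
(callers whose accuracy for the type warrants inclusion). With defaults the
deletion matrix has 34 caller metrics + svlen = 35 columns and the
insertion matrix 35 + svlen = 36. Delly and INSurVeyor dialects keep only
`FILTER == PASS` records (their high-confidence marker); this is togglable
per caller.

Missingness is a first-class value: the tree learner consumes `NA`
natively (its sparsity-aware split handling), so no imputation is applied
and "caller silent" stays distinct from "caller reports zero".

## The simulator

`simulate_truth_set` / `simulate_caller_outputs` generate, from a single
seed, a truth set (log-uniform lengths on [50, 10000] bp, uniform
placement over 2 × 60 Mb contigs, non-overlapping deletions) and one VCF
per emulated caller. Each caller has a type-specific sensitivity,
breakpoint jitter SD, and false-positive rate per Mb; defaults mirror the
heterogeneity of real short-read callers — a balanced high-F1 profile
(manta-like), high-precision/low-recall (tardis-like), insertion-weak
read-pair callers, an insertion specialist, and insertion-noisy callers
with FP-heavy output (pindel/tardis-like). Metric values are drawn from
TP- or FP-conditional distributions: Poisson for counts (rates 0.45× vs
0.15× mean coverage, so coverage-kind metrics scale linearly with depth
and the normalization's scale invariance is exercised end-to-end),
clipped Gaussians for qualities (55 ± 10 vs 25 ± 10) and allele fractions
(0.5 vs 0.15, SD 0.1), and deliberately class-free draws for
microhomology length and consensus entropy so that not every registered
feature is informative. False positives draw lengths from the same
distribution as truth, so SV length alone cannot separate the classes and
quality metrics must carry the signal — the contrast the BM-vs-FM
comparison is designed to expose.

What the simulator does *not* emulate: reads, genome sequence, realistic
SV length spectra or hotspots, caller-specific systematic biases, or
correlated errors between callers (detections are independent across
callers given truth). Passing tests therefore demonstrate the pipeline's
internal correctness and the claimed invariances, not field performance on
real genomes.

## Numerical and design choices

* **Coordinates.** 1-based POS with inclusive END throughout, matching
  VCF; no half-open conversion anywhere. When SVLEN is absent for a
  deletion, `svlen = END − POS + 1`; insertions may have `end == pos`.
  Contigs compare after `chr`-stripping; autosomes are {1..22}.
* **Lower median.** Representative coordinates use the smaller central
  order statistic on even member counts — deterministic, no fractional
  positions.
* **Transitive closure vs idempotence.** Clustering by connected
  components is order-independent and matches a brute-force all-pairs
  oracle exactly. A consequence: in rare chained configurations (two
  clusters whose members never link pairwise but whose medians fall
  within `max_dist` on both breakpoints), re-merging the consensus set
  with itself can join clusters. Re-merging always follows the same link
  rule; it is the identity exactly when no two representatives are
  mutually linked. The tests assert precisely this conditional property.
* **Determinism.** Single-threaded exact-greedy training, seeded fold
  assignment, first-in-grid tie-breaks, sorted caller/member orderings
  and documented matching tie-breaks make every pipeline stage
  reproducible bit-for-bit; model artifacts round-trip through their JSON
  serialization with identical predictions.
* **Degenerate inputs.** Header-only VCFs parse to empty tables; empty
  consensus sets write header-only VCFs; all-constant feature sets yield
  an empty selection with a warning; single-class training labels are an
  error, as is an all-features-pruned model.
* **Decile calibration testing.** The ranking score's calibration is
  checked per probability decile (bins [0, 0.1), ..., [0.9, 1.0], top bin
  closed). A well-separated classifier concentrates most calls in the
  extreme deciles, leaving middle bins with a handful of calls whose raw
  TP proportions are binomial noise; the monotonicity check therefore
  requires non-decreasing proportions across bins holding at least 30
  calls and, for thinner bins, the absence of any statistically
  significant adjacent inversion (one-sided Fisher test, α = 0.01).
* **Problem sizes.** The test-suite and acceptance runs use 2000 truth
  SVs per type on a 120 Mb genome (training and held-out evaluation
  simulated under different seeds), 1000 (tests) / 200 (acceptance
  script) random merge-oracle instances of up to 200 calls, and a reduced
  hyperparameter grid — the package's desk-scale protocol.

## Limitations

Only deletions and insertions-including-duplications are modeled;
inversions, translocations and breakend notation are out of scope, as are
running the upstream callers, BAM/CRAM handling, sequence-resolved
comparison, genotype-concordance scoring and probability calibration
(isotonic/Platt). Models are per-type and refuse features built under a
different metric registry (hash check). The shipped dialect metric sets
are sensible defaults, not a normative description of any caller version —
audit them against your callers' VCF headers before training on real
data.
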