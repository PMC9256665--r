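---
title: "Benchmarking SNV callers against a dual truth set: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking SNV callers against a dual truth set: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcbench)
```

## Overview

`vcbench` evaluates SNV callers with a truth set that distinguishes the
two biological sources of called variants: sites segregating within the
sampled population (**P**) and sites where the reference genome diverges
from the population's most recent common ancestor (**D**, controlled by
the divergence fraction *d*). This vignette documents the models behind
each stage, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## The population model

`run_wright_fisher()` implements a neutral, constant-size, panmictic
Wright–Fisher diploid population on a single linear sequence. Each
generation every offspring draws two parents uniformly at random; a
gamete is built by recombining the parent's two haplotypes with
Poisson(rL) crossovers at uniform breakpoints and adding Poisson(μL) new
mutations at uniform positions.

Mutations follow an infinite-sites approximation: a drawn position that
already carries a derived allele (segregating or fixed) is resampled, so
every truth site is biallelic with a single derived base drawn uniformly
from the three alternatives. This keeps the classification of calls
unambiguous. Sites fixed population-wide are moved to a separate ledger
(and re-attached at sampling time), which keeps the per-haplotype
mutation sets small; they surface in the truth set flagged `fixed`, since
a caller sees them exactly like divergence sites (homozygous-alternative
in every sample).

**Rescaling.** The intended design is a large population (say 10^6)
scaled down by a factor λ: N/λ individuals with per-generation rates μλ
and rλ. This preserves the population-scaled parameters θ = 4Nμ and
ρ = 4Nr that determine the sampled diversity, at the cost of compressing
time. `sim_params()` takes λ explicitly (`lambda_rescale`) or
pre-rescaled rates directly; its defaults are the rescaled design
N = 1000, μ = 2.0e-5, r = 2.8e-6, 3000 generations, 20 diploid samples.
The genome length default (L = 1e5) is a desk-scale choice — runtime and
memory scale linearly in μL and L, and nothing in the design depends on L
beyond the expected counts, so larger L is a configuration change, not a
model change.

Two calibrations validate the simulator against coalescent theory rather
than against any other implementation: mean pairwise diversity π should
equal θ = 4Nμ per site at equilibrium, and the number of segregating
sites should match Watterson's θ·a_{2n−1}·L. Both are asserted in the
test suite (12–50 replicates, 3-standard-error bands; 10N generations
from a monomorphic start, which is within 1% of equilibrium diversity
since E[π(t)] = θ(1 − e^{−t/2N})). For these calibrations the
recombination rate is set at r/μ = 0.14, the same ratio as the default
rates; recombination does not change E[π] but dramatically reduces its
between-replicate variance, so the rate's order of magnitude matters for
test power, not correctness.

**Sampling ambiguity.** Whether "40 individuals whose first alleles form
20 diploids" means drawing 20 diploid individuals or one haplotype from
each of 40 individuals is ambiguous in the design we emulate; under
random mating the two schemes give statistically identical samples.
`sample_population()` defaults to 20 diploids and offers
`mode = "haploid"` for the other reading.

## Divergence injection

`inject_divergence()` mutates each site independently with probability
*d* (uniform alternative base), returning the diverged reference and
truth set D. Two open choices were resolved as follows:

- **Disjointness from P.** How divergence sites should interact with
  segregating sites is unspecified in the design; by default P positions
  are excluded so that every call classifies unambiguously as TPP, TPD or
  FP. Collisions would create sites that are simultaneously polymorphic
  and divergent — biologically possible but an evaluation nuisance.
- **Bernoulli vs fixed count.** Per-site Bernoulli(d) is the generative
  model; `fixed_count = TRUE` places exactly round(d·L_eligible)
  mutations when exact |D| reproducibility is wanted.
- The divergence grid default is {0, 0.005, 0.01, 0.015, 0.02}: the d = 0
  condition is retained as its own reference because the diagnostics
  (QD bimodality, MQ degradation) are defined by contrast against it.

Only substitutions are injected; indel or structural divergence is out of
scope, as is repeat-aware placement.

## Read simulation

`simulate_read_pairs()` is a minimal paired-end simulator:
round(coverage·L/(2·read_len)) pairs per diploid genome, split evenly
between haplotypes; fragment starts uniform; fragment lengths
Normal(insert_mean, insert_sd) truncated to [read_len, L − start]; mate 2
is the reverse complement of the fragment end; a uniform per-base
substitution error rate; constant base quality (default Q30). Defaults
are 150 bp reads, 300 ± 30 bp inserts, 20× coverage. It deliberately does
not model indel errors, quality trajectories, GC bias or duplicates: its
purpose is to hand realistic-shaped FASTQ to an external mapper + caller,
and those error structures belong to the tools being benchmarked, not to
the benchmark. Read names encode individual, haplotype, fragment and
mate for truth-aware debugging.

## The caller emulator

External mappers and callers are not orchestrated. Instead
`emulate_caller()` converts truth sets into an annotated VCF with
configurable error behaviour, which closes the loop: the evaluator can
be tested against known error rates, and every downstream analytic can
be exercised at desk scale.

- Each truth site is emitted with probability 1 − `fn_rate`; false
  positives arrive as Poisson(`fp_per_mb`·L/10^6) at non-truth positions
  (resampled on collision, so classification stays unambiguous), placed
  inside repeat intervals with probability weight `fp_repeat_enrichment`
  against 1 outside.
- Scores are drawn per class from `default_score_model()`: true calls
  get MQ ~ Normal(59, 3) truncated to [0, 60] and near-null rank sums;
  false positives get MQ ~ Normal(30, 8) and inflated-variance
  annotations. These are free parameters shaped to echo the
  characteristic separation of real caller output, not fitted values,
  and all are configurable.
- **QD mechanism.** QD for true calls is two-component: sites whose
  carriers are all homozygous for the alternative allele (dosage 2 in
  every carrier — D sites and sample-fixed P sites) draw from a high mode
  Normal(25, 4); any site with a heterozygous carrier draws from
  Normal(8, 3). This reproduces the mechanism whereby the QD distribution
  reflects the alternative-allele frequency spectrum: with d = 0 and a
  polymorphic call set the pooled QD is unimodal, and it becomes bimodal
  exactly when divergence-like sites contribute calls.
- **MQ–divergence coupling.** A fraction min(1, base + (1 −
  base)·min(1, `mq_d_coupling`·d)) of true calls draws MQ from the
  false-positive component instead (base = 5%), emulating the loss of
  mapping quality on a diverged reference. The fraction of true P calls
  with MQ < 40 therefore rises monotonically with d — the property that
  makes MQ-based hard filtering destructive at high divergence.

## Evaluation

`classify_calls()` matches by site and ALT allele: TPP requires the
derived allele, TPD requires the ancestral allele (the ALT from the
diverged reference's point of view), anything else — including a call at
a truth site with the wrong ALT — is FP. Genotype concordance is *not*
required for TP status (SNV discovery is being scored, not genotyping; a
separate `genotype_concordance()` report covers the latter). A
positional-overlap mode (`match_alt = FALSE`) is available. Headline
recovery is over truth P; recovery over D and over the union are also
reported, and sample-fixed P sites are tabulated separately since they
are recovered like divergence sites.

The **f score** is the harmonic mean of recovery and precision with
precision = 1 − FP proportion. A literal harmonic mean of recovery and
the FP proportion itself (`literal = TRUE`) is retained for comparison;
it collapses to near zero whenever false positives are rare and cannot
reproduce f values near 0.95 from recovery ≈ 0.9 and FP proportions
below 0.1%, which is why the precision-based form is the default.

Filters: `apply_qual_filter()` retains QUAL ≥ 20 (strictly lower is
discarded; missing QUAL is conservatively discarded, with a warning).
`apply_hard_filter()` removes a record if *any present* annotation
violates its threshold — QD < 2, FS > 60, MQ < 40, MQRankSum < −12.5,
ReadPosRankSum < −8 — and a missing annotation never triggers removal,
matching the standard VariantFiltration convention. All comparisons are
strict inequalities, so QD = 2.0, MQ = 40.0 and QUAL = 20.0 are retained.
Both filters are idempotent. Multiallelic records are split into
biallelic records at VCF ingestion and non-SNV records are dropped with a
logged count. Coordinates are 1-based in VCF I/O and 0-based half-open
internally, converted only at the boundary.

## Stratification and diagnostics

`repeat_track()` ingests BED (4th column = class) or UCSC RepeatMasker
table exports, mapping repClass values into a controlled vocabulary (LTR,
LINE, DNA, RollingCircle, Simple/LowComplexity/Satellite, OtherRepeat).
Nested annotations are resolved by the precedence LTR > LINE > DNA >
RollingCircle > Simple/LowComplexity/Satellite > OtherRepeat —
transposable-element classes dominate because the caller-comparison
tables emphasise them; a count-in-all mode is provided
(`all_classes = TRUE`). `ratio_table()` rounds caller-to-caller ratios to
the nearest integer with ties away from zero (2637/2 → 1319), NA when the
denominator is zero.

`fisher_exact_2x2()` is the two-sided exact hypergeometric test (via
`stats::fisher.test`; the test suite checks it against a full enumeration
oracle). `spearman_trend()` computes Spearman's ρ with an exact
permutation p-value for n ≤ 8 without ties (`stats::cor.test`'s exact
distribution; checked against a full n! enumeration) and the asymptotic
approximation otherwise. At the n = 5 scale of a divergence grid the
smallest achievable exact two-sided p is 2/5! ≈ 0.0167; published
p-values around 10^-5 at n = 5 therefore cannot come from an exact test,
and no attempt is made to match them numerically.

**QD bimodality** is scored by Sarle's coefficient with the finite-sample
correction, b = (g1² + 1)/(g2 + 3(n−1)²/((n−2)(n−3))), flagged bimodal
above the uniform-distribution benchmark 5/9. The choice is pragmatic: a
visual judgement ("the histogram has two modes") needs a testable proxy,
and Sarle's coefficient is simple, deterministic and adequate for the
well-separated modes the emulator produces. It can flag heavily skewed
unimodal data; the threshold is not tuned.

## The pipeline

`run_benchmark()` chains the stages over a divergence grid and a set of
caller profiles, evaluating each raw and filtered call set, stratifying
false positives, computing diagnostics and trends, and (with `out_dir`)
persisting truth files, references, VCFs, a metrics table, a JSON report,
a manifest and a stage log. Every stage derives its seed deterministically
from the global seed (`derive_seed()`), so a configuration plus seed
fully determines the report — byte-identical across runs — regardless of
how many random draws each stage consumes. External callers are handled
by file handoff: FASTA references and FASTQ reads out,
`evaluate_external()` for the VCF coming back.

## Problem sizes

The test suite and the acceptance script run everything at desk scale as
the package's own standard study conditions: populations of 10–200
diploids on 2–200 kb sequences, closed-loop calibration at 1000 truth
sites on 1 Mb over 20 seeds, and coalescent calibration at N = 100,
L = 100 kb over 50 replicates. The statistical assertions use 3-standard-
error bands derived from binomial/Poisson/coalescent sampling theory, so
they are scale-aware rather than tuned tolerances.

## What passing tests do and do not show

The synthetic generators emulate the *structure* of the benchmark — dual
truth sets, allele-frequency-keyed score modes, repeat-enriched false
positives — not any particular caller's behaviour on real reads. A green
suite shows the evaluator, filters, stratification and diagnostics are
correct and that the simulators match their stated sampling theory. It
does not show how an actual mapper + caller performs on a real genome;
for that, hand the pipeline's FASTA/FASTQ to the external tools and
evaluate their VCF with `evaluate_external()`. Known limitations: no
selection, demography or gene conversion in the population model; no
indel or structural variation anywhere; the emulator's miss rate is
independent of d (so recovery-vs-d trends are flat unless the profile is
configured otherwise); and annotation scores are drawn independently per
record, with none of the spatial autocorrelation real pileups produce.
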