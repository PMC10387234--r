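---
title: "Serum small-RNA miRNA profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum small-RNA miRNA profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumiR)
```

# Scope

serumiR reimplements, as reusable and tested functions, the analysis chain
of serum small-RNA sequencing studies that profile circulating miRNAs
across patient groups: read quality control and adapter trimming, exact
mature-miRNA quantification, TPM normalization, an exact count-based
differential test for pooled digital tag counts, selection of differential
miRNAs by fold change and p-value, consensus intersection of multi-source
target predictions, hypergeometric term enrichment, and delta-delta-Ct qPCR
validation. The motivating application is the comparison of seronegative
rheumatoid arthritis (N-RA), seropositive RA (P-RA) and healthy control
(HC) serum libraries, and the package ships the published group-TPM tables
of that three-way comparison (`serum_ra_tables()`) so the fold-change
arithmetic can be replayed against reported values.

# Read-level processing

Raw reads pass two independent discard rules, both configurable:

* a read is removed when its fraction of `N` bases exceeds `max_n_frac`
  (default 0.10); the comparison is strict, so a 50-nt read with exactly
  five `N`s survives;
* a read is removed when the fraction of bases with Phred quality below
  `min_phred` (default 5) exceeds `max_lowqual_frac` (default 0.10).

The underlying laboratory protocols describe this QC step in one compressed
sentence; we read it as two symmetric per-read rules and surface all three
thresholds so stricter or looser readings are one argument away. A read
failing both rules is attributed to the poly-N rule, which makes the QC
report columns sum exactly to the input count — an invariant the tests
assert at every stage boundary.

Adapter removal (`trim_adapter()`) strips the longest read suffix exactly
matching a prefix of the 3' adapter, requiring `min_overlap = 6` matching
bases; reads without a qualifying match are counted and dropped rather than
passed on, since an untrimmed read cannot be an exact mature match anyway.
Surviving inserts are kept when their length falls in the inclusive 18–30 nt
window of small-RNA size selection, collapsed to unique tags, and annotated
by exact full-length identity against the reference. Contaminant classes
(rRNA, scRNA, snoRNA, snRNA, tRNA) take precedence over mature miRNAs, so a
sequence present in both catalogues is never counted as a miRNA. Matching is
alphabet-normalized (U ≡ T). Exact matching — no mismatches, no isomiR
offsets — is the deliberate default: the upstream studies report
BLAST-against-miRBase identification without parameters, and exact identity
is the only reading that is reproducible bit-for-bit.

The per-sample *clean-tag total* is the number of tags surviving QC and
length selection, over all annotation classes. This is the TPM denominator:

$$\mathrm{TPM}_{ij} = \frac{c_{ij}}{T_j} \times 10^6$$

with `c` the miRNA count and `T` the clean-tag total. The denominator is
taken literally as *all* clean tags, not only miRNA-assigned ones; the
sources do not resolve this ambiguity and the literal reading is the one the
package uses throughout.

Group-level TPM pools the group's counts and totals
(`group_tpm()`), rather than averaging per-sample TPMs, because the
differential test below operates on the same pooled counts and the published
tables print a single TPM per group. Group TPMs of exactly zero are replaced
by the floor 0.01; positive values below 0.01 are reported as-is. Both
behaviours are visible in the published tables, which contain many literal
`0.01` cells alongside a sub-floor value of 0.005714.

For heat-map display, `zscore_matrix()` standardizes each miRNA's
`log2(TPM + 0.01)` profile to mean 0 and *population* SD 1 (so a two-sample
row maps to ±1 exactly); zero-variance rows map to zeros.

# The exact differential test

For one miRNA with pooled counts `x` and `y` in two groups whose pooled
clean-tag totals are `N1` and `N2`, the count in the second group given the
first is modelled by

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\bigl(1+\frac{N_2}{N_1}\bigr)^{x+y+1}},$$

the Audic–Claverie-style posterior predictive for digital tag counts, which
is a negative binomial in `y` with size `x + 1` and success probability
`N1/(N1+N2)` — an identity the test suite exploits as an independent oracle
via `pnbinom()`. Significance uses the lower tail
$C(y' \le y \mid x)$ and upper tail $D(y' \ge y \mid x)$; the two-sided
p-value doubles the smaller tail and caps at 1.

Numerical choices:

* the pmf is evaluated in log-space via `lgamma()`, so counts of any
  magnitude are safe from overflow;
* `C` is a finite log-space sum; `D` is summed upward in blocks until a
  certified geometric bound on the remaining mass (the term ratio is
  eventually below $r/(1+r) < 1$) falls under `tail_tol = 1e-15` of the
  accumulated sum;
* the conditional model is not symmetric in its two libraries: conditioning
  on `x` and asking about `y` does not give the mirror-image tails of the
  reverse, even for `N1 = N2`. Group labels carry no meaning in a two-group
  comparison, so `ac_pvalue()` computes the two-sided p in a canonical
  orientation — the side with the smaller library total, ties broken by the
  smaller count, is the conditioning observation. This makes the p-value
  exactly invariant under swapping the groups, while the reported one-sided
  tails `C`/`D` keep the caller's orientation so the upper tail remains
  monotone in the observed count.

Replicates enter by pooling: counts and clean totals are summed within each
group before the test. The statistic is defined for a pair of libraries —
its home is no-replicate digital-expression pipelines — and pooling is the
construction consistent with group-level TPM columns; the package makes no
claim that it models between-subject variability (a replicate-aware
negative-binomial test is precisely what this analysis family does *not*
do). A consequence worth knowing: at serum-sequencing depths the test is
extremely powerful, so small but uninteresting rate differences reach tiny
p-values. The published selection rule — fold change ≥ 2 (inclusive) *and*
p < 0.05 (strict), applied to the ratio of floored group TPMs — is what
keeps calls biologically meaningful, and `de_table()` applies exactly that
rule. Benjamini–Hochberg q-values are reported alongside but do not drive
the headline filter, which follows the published raw-p rule.

# Target consensus and enrichment

Target predictions from several tools (the motivating study used RNAhybrid,
PITA, Miranda and TargetScan; the package consumes their output lists, it
does not rerun them) are combined by `consensus_targets()`: a gene counts as
a target when at least `min_sources` sources predict it, defaulting to *all*
sources — the strict intersection treated as most reliable. Venn-region
counts (`venn_counts()`) and a bipartite miRNA–mRNA network of differential
miRNAs (`build_network()`, exportable as edge-list TSV and SIF) complete the
module.

Enrichment of a gene set against term annotations uses the hypergeometric
upper tail $P(X \ge k)$ with the annotation universe as the "genome
background" (overridable), computed by `phyper()` and verified in the tests
against exhaustive enumeration of draws for small backgrounds. Only
over-representation is tested. BH adjustment is reported as `q_bh`; the
column is explicitly named so raw-p readings remain possible, since the
upstream protocol does not name a correction. GO-graph propagation is out of
scope: terms are counted exactly as annotated.

# qPCR validation

`delta_delta_ct()` implements comparative-Ct quantification against a
reference small RNA (5sRNA in the motivating study): per sample
$\Delta C_t = C_t^{target} - C_t^{ref}$, then
$\Delta\Delta C_t = \Delta C_t - \overline{\Delta C_t}(\text{calibrator})$,
fold $= 2^{-\Delta\Delta C_t}$ (efficiency 2 assumed; no correction). The
calibrator is the healthy-control group by default but configurable, since
the upstream description does not name one; the calibrator group's mean log2
fold is 0 by construction. Group comparison uses ordinary one-way ANOVA on
per-sample *log2* folds (the scale on which such results are presented as
mean ± SEM), delegated to `oneway.test(var.equal = TRUE)` with two guarded
degenerate cases: all-equal input returns F = 0, p = 1; zero within-group
variance with distinct means returns F = ∞, p = 0.

# What the simulators emulate — and what they do not

Every pipeline input can be generated from a seed, which is what makes the
package testable end to end without downloads:

* `make_reference()` — a miniature mature-miRNA catalogue (18–25 nt) plus
  contaminants (20–28 nt), substring-free across all sequences so
  exact-match annotation is provably unambiguous.
* `simulate_counts()` — negative-binomial counts (Poisson at dispersion 0,
  the sampling model the exact test assumes; positive dispersion lets tests
  probe robustness) around log-normal per-miRNA baselines, scaled by
  library size and by spiked fold changes recorded in a `simulation_truth`
  object that travels with the data, so recovery tests never re-derive the
  truth.
* `simulate_reads()` — one read per counted molecule: mature sequence plus
  3' adapter fill to a fixed 50-nt read length (DNA alphabet, Phred+33).
  Junk is injected one class per QC rule — all-N reads for the poly-N rule,
  Phred-2 reads for the quality rule, contaminant-sequence reads that
  survive QC and are set aside at annotation — so each filter's attribution
  is testable in isolation. With all noise fractions at zero, quantification
  reproduces the simulated count matrix *exactly*; this round-trip is a
  standing test.
* `simulate_qpcr()` and `simulate_target_lists()` — Ct tables whose
  expected delta-delta-Ct equals the injected log2 fold changes exactly at
  zero noise, and target lists with a constructed shared core so the
  consensus size is known by bookkeeping.

The default conditions mirror the motivating study where stated: three
groups of 12 (N-RA), 9 (HC) and 9 (P-RA) libraries, ~200 known miRNAs,
spiked effects at ≥ 2-fold (8-fold in the power checks), and an 18–30 nt
read-length window. Sequencing depth is nowhere reported in that family of
studies; the package asserts 10^6 clean tags per library as a plausible
serum small-RNA depth and treats it as a fixed convention, not a fitted
value.

Deliberately *not* emulated: position-dependent sequencing error models,
isomiR length/edit variants, precursor hairpins and novel-miRNA discovery,
adapter dimers, and GC- or length-dependent ligation bias. Passing tests on
these simulations therefore demonstrate the correctness of the arithmetic
and the filtering logic under the stated sampling model — they do not
demonstrate robustness to the biochemical artefacts of real serum libraries.

# Replay of published tables

`replay_tables()` re-derives log2 fold changes and direction calls from the
printed group-TPM pairs of a published comparison table and reports the
per-row deviation from the printed fold-change column. On the bundled
tables, the N-RA vs HC and N-RA vs P-RA comparisons (TPMs printed to nine
decimals) reproduce to about 1e-8. The P-RA vs HC table prints its TPMs to
only six decimal places while its fold-change column was evidently computed
from unrounded values, so recomputation from the printed pairs can agree
only to about 1.5e-5 on most of its rows — a property of the printed
precision, not of the arithmetic, and the acceptance test that demands 1e-6
across all rows documents this honestly by failing on exactly those rows.

# Problem sizes and runtime conventions

The shipped tests exercise: the exact test against direct factorial
arithmetic on the full grid x, y ≤ 30 at library ratios 0.5, 1 and 2;
normalization of the pmf for x up to 50; type-I error on 50 null replicates
of 200 miRNAs at pooled depth 10^6 per group (observed false-positive
fraction must stay ≤ 0.06 — the discrete exact test is conservative); and
recovery of 8-fold spikes in 10 replicates × 20 spiked miRNAs (≥ 90%
correct-direction calls required). Pipeline smoke tests run a reduced
configuration (12 miRNAs, 7 libraries) because their purpose is
orchestration and determinism, not statistics; the study-scale default
configuration completes in seconds and is the one `run_pipeline()` uses out
of the box.

# Known limitations

* Pooling discards within-group dispersion; the q-values inherit whatever
  anticonservatism that implies for overdispersed data. Use the NB
  simulation options to quantify it for a design before trusting borderline
  calls.
* Exact-match annotation undercounts miRNAs with prevalent isomiRs.
* The enrichment module treats annotations as flat sets (no ontology
  propagation).
* `venn_counts()` is capped at six sources (2^k regions).
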