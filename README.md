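# serumiR

Serum small-RNA sequencing pipelines quantify circulating mature miRNAs and
ask which of them separate patient groups — for example seronegative
rheumatoid arthritis (N-RA), seropositive RA (P-RA) and healthy controls
(HC), where no serological marker exists and a circulating miRNA signature
would be diagnostically valuable. serumiR packages that analysis chain as
tested R functions for bioinformaticians who want the arithmetic of such
studies to be reproducible end to end: read QC and adapter trimming, exact
mature-miRNA counting, TPM normalization, an exact count-based differential
test, multi-source target consensus, hypergeometric enrichment, and
delta-delta-Ct qPCR validation — plus seeded simulators for every input, so
the whole pipeline runs and is verifiable without any external download.

## The statistic at the core

For a miRNA with pooled counts *x*, *y* in two groups whose pooled clean-tag
totals are *N₁*, *N₂*, the package models

p(y | x) = (N₂/N₁)^y · (x+y)! / ( x! y! (1 + N₂/N₁)^(x+y+1) ),

the Audic–Claverie-style posterior predictive for digital tag counts
(negative binomial with size x+1 and probability N₁/(N₁+N₂)). Significance
combines the lower tail C(y′ ≤ y | x) and upper tail D(y′ ≥ y | x) as
p = min(1, 2·min(C, D)), evaluated in log-space with a certified geometric
tail bound, and computed in a canonical orientation so the p-value is
exactly invariant under swapping the groups. Differential miRNAs are those
with fold change ≥ 2 on floored group TPMs (TPM = count / clean tags × 10⁶;
zero group TPMs floored at 0.01) and p < 0.05.

## Worked example

A full synthetic study at the default conditions (12 N-RA, 9 HC and 9 P-RA
libraries, 200 miRNAs, 10⁶ clean tags per library, spiked 8-fold effects):

```r
library(serumiR)
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "demo_run"))
head(res$de[["N-RA_vs_HC"]], 5)
#>      mirna_id tpm_a tpm_b   log2fc        p       q direction
#> 1 sim-miR-001 12089  1477  3.03312 0.000000 0.00000        up
#> 2 sim-miR-006  1196  9550 -2.99746 0.000000 0.00000      down
#> 3 sim-miR-003 10041  1263  2.99124 0.000000 0.00000        up
#> 4 sim-miR-002  3512 27307 -2.95887 0.000000 0.00000      down
#> 5 sim-miR-107  6042  5323  0.18295 0.001769 0.07075        ns
```

The four spiked miRNAs of this comparison are recovered with the correct
directions and essentially zero p-values; `sim-miR-107` shows why the
fold-change filter matters at sequencing depth — a 13% rate difference is
"significant" to the exact test (p = 0.0018) but falls far below the 2-fold
threshold and is called `ns`. The run directory contains every intermediate
(counts, TPM and z-score matrices, QC report, DE tables, consensus targets,
Venn regions, network edge list/SIF, enrichment table, qPCR folds) and a
JSON manifest with md5 hashes; rerunning with the same seed reproduces the
hashes bit for bit.

The qPCR module, on the same run's simulated Ct table (true log2 fold +1 in
N-RA vs the HC calibrator):

```r
res$qpcr$anova
#> $F
#> [1] 81.76383
#> $p
#> [1] 3.499269e-12
```

with group mean log2 folds 0.00 (HC, by construction), 0.93 ± 0.08 (N-RA)
and −0.23 ± 0.06 (P-RA).

Replaying a published comparison table from its printed group TPM pairs:

```r
rp <- replay_tables(serum_ra_tables("nra_vs_hc"))
rp[1, c("mirna_id", "tpm_a", "tpm_b", "log2fc_recomputed", "abs_dev")]
#>         mirna_id     tpm_a tpm_b log2fc_recomputed      abs_dev
#> 1 hsa-miR-362-5p 0.1513946  0.01          3.920241 5.840829e-09
```

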