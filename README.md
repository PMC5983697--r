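# tfscreen

Integrative screening for direct transcriptional targets of a regulator.

Genome-wide regulator-target calling rarely rests on one assay. The
evidence that a gene is a direct target typically combines (i) a ChIP-seq
binding site near the gene's transcription start site (TSS), (ii) a
concordant expression response when the regulator is perturbed in both
directions (up under overexpression, down under knockdown), and (iii)
co-expression with the regulator across a tumor cohort. `tfscreen`
implements that integration as a tested, reproducible pipeline, and pairs
it with a seeded synthetic-data generator that plants known targets so
every stage can be validated end to end without any external download.

## What it computes

Given peak sets, a gene annotation, two perturbation expression matrices,
and a cohort matrix:

1. **Peak pooling** — peak sets are merged into disjoint loci
   (`pool_peaks`, union-merge or intersection).
2. **Nearest-TSS assignment** — each locus gets the gene whose TSS
   minimizes |p − TSS| on its chromosome, with a signed, strand-oriented
   distance *d* (upstream negative by default; the mirrored convention is
   a flag). Distances feed a promoter-window summary: the fraction of
   loci with |d| ≤ 2 kb, and a per-gene occupancy table
   (`assign_nearest_tss`, `distance_histogram`, `promoter_fraction`,
   `promoter_occupancy`).
3. **Perturbation ratios and concordance** — per-gene ratios
   (mean(treatment)+ε)/(mean(control)+ε) for the overexpression (OE) and
   knockdown (KD) contrasts, and their cross-dataset concordance with the
   KD axis sign-flipped so concordant regulation scores positive
   (`compute_ratio`, `cross_contrast_concordance`).
4. **Cohort correlation** — Pearson *r* between each gene and the
   regulator on the log2(x+1) scale (`regulator_correlation`).
5. **Candidate selection** — the disjunctive rule: a gene is a candidate
   iff it shows *consistent change* (OE/Ctr ≥ 1.5 **and** KD/Ctr ≤ 0.75)
   **or** *high correlation* (|r| ≥ 0.20); promoter occupancy is an
   optional extra gate, off by default so long-range (hundreds of kb)
   candidates survive (`select_candidates`). All thresholds are
   configurable.
6. **Survival analysis** — per candidate gene, the cohort is bifurcated
   at its median expression and the low/high groups are compared with a
   Kaplan–Meier product-limit curve, a 1-df log-rank test
   ((ΣO₁ⱼ−E₁ⱼ)²/ΣVⱼ with the hypergeometric variance), and the
   observed/expected hazard-ratio display estimate
   HR = (O₁/E₁)/(O₂/E₂) (`median_split`, `km_curve`, `logrank_test`,
   `survival_screen`).
7. **qPCR utility** — 2^−ΔΔCt relative quantification
   (`ddct_fold_change`).

The synthetic generator (`sim_config`, `simulate_all`) emits all inputs
(GTF, narrowPeak, expression TSVs, clinical TSV) plus a JSON truth
manifest, with per-output random substreams so one seed reproduces every
file byte for byte.

## Worked example

```r
library(tfscreen)

sim <- simulate_all(sim_config(seed = 1))            # planted ground truth
asn <- assign_nearest_tss(sim$peaks, sim$genes)
promoter_fraction(asn, window = 2000)$fraction
#> [1] 0.6717488

occ  <- promoter_occupancy(asn, 2000, sim$genes)
oe   <- compute_ratio(sim$oe, sim$oe_contrast)
kd   <- compute_ratio(sim$kd, sim$kd_contrast)
corr <- regulator_correlation(sim$cohort, sim$manifest$regulator_gene)
scr  <- select_candidates(occ, oe, kd, corr)
scr
#> candidate_screen: 195 of 2000 genes selected (0 excluded for missing data)
#>   thresholds: OE/Ctr >= 1.5 & KD/Ctr <= 0.75, or |r| >= 0.2
#>  gene_id best_distance promoter_bound  kd_ratio  oe_ratio   cohort_r ...
#>   g00001         55679          FALSE 0.2106895 3.5146437  1.0000000
#>   g00681           -49           TRUE 0.1921406 2.4143828  0.5384330
#>   g00847            -1           TRUE 0.2500451 2.8939239  0.3723333
#>   ...
```

67.2% of the 3086 simulated loci fall within 2 kb of a TSS (the generator
plants 66.5%), and the screen returns 195 candidates out of 2000 genes —
the 100 planted targets (all recovered at this seed) plus the background
genes that clear a threshold by chance. The top row is the regulator
itself (its self-correlation is exactly 1 and it is strongly shifted in
both perturbations); the remaining top rows are planted targets with
promoter-proximal best distances.

Survival for the planted reporter gene:

```r
grp <- median_split(sim$cohort$values[sim$manifest$reporter_gene, ],
                    sim$clinical)
logrank_test(grp)
#> Log-rank test (low vs high expression group)
#>   n: low 50, high 50;  events O: low 35, high 40;  E: low 47.354, high 27.646
#>   chi-square = 9.4015 (1 df), p = 0.002168, HR (low/high) = 0.511
```

The low-expression group shows fewer events than expected (35 vs 47.4):
the generator planted a protective hazard ratio of 0.4 for low reporter
expression, and the O/E estimate 0.51 recovers its direction and rough
magnitude at n = 100.

A shell entry point wrapping `simulate_all` and `run_all` is installed at
`inst/cli/tfscreen.R`; `run_all(config, outdir)` executes the whole chain
from a YAML/JSON config and writes per-stage TSVs plus a deterministic
`report.json`.

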