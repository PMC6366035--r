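# mirimpact

Linear perturbation modelling of how microRNAs shape the transcriptome
response of irradiated cells.

## The problem

Within an hour of X-ray exposure, hundreds of mRNAs change level, and the
pattern of change tracks the distribution of miRNA recognition motifs in
their 3'-UTRs. `mirimpact` is for researchers who want to quantify that
link: it models the log2 fold change of every transcript as a linear
combination of contributions from the miRNAs that target it,

```
FC_j = Σ_i Δk_i · c'_ji · miRNA_i + b0
```

where `c'_ji` is the weighted binding-site count of miRNA *i* on
transcript *j* (combining miRanda/TargetScan/RNAhybrid-style tables with
an in-package seed-match text scan; default weights 0.3/0.3/0.3/0.1),
`miRNA_i` is the log2 miRNA abundance, `Δk_i` is the irradiation-induced
change in that miRNA's repression strength (positive = repression
weakened, targets rise), and `b0` is a shared miRNA-independent shift. In
matrix form `FC = C'·diag(miRNA)·Δk + b0`, estimated by least squares;
model quality is the Spearman correlation between predicted and observed
fold changes.

Around the model the package provides the full pipeline: Gaussian-mixture
filtering of expression noise, duplicate-probe collapsing, fold-change
computation, split-sample validation, three matrix-randomization null
controls, per-miRNA impact ranking with forward/reverse
cumulative-inclusion curves, structural feature comparisons
(Mann–Whitney U / t-tests), fit-quality classification of transcripts,
and a synthetic data generator with known ground truth so every stage is
testable without microarray downloads.

## Worked example

```r
library(mirimpact)

# a synthetic irradiation experiment: 1000 transcripts, 50 miRNAs,
# 10 truly perturbed, noise set so the signal explains ~40% of variance
sim <- simulate_dataset(n_mrna = 1000, n_mirna = 50, n_active = 10,
                        target_r2 = 0.4, seed = 42)

fit <- mirimpact(sim)
fit
#> miRNA perturbation model (least squares)
#>   1000 transcripts x 50 miRNAs, design rank 51
#>   b0 = 0.1025; Spearman rho (training) = 0.587
```

The fit recovers the intercept (truth 0.1) and orders transcript
responses well (rank correlation 0.59 at this noise level). Ranking
miRNAs by how much each explains alone:

```r
rank_mirnas(sim$C_prime, sim$mirna_expr, sim$fc_observed)
#> miRNA ranking by single-predictor Spearman rho (50 miRNAs)
#>  rank mirna_id rho_single dk_single
#>     1  mir_042    0.34949  0.019282
#>     2  mir_015    0.29599  0.021224
#>     3  mir_036    0.26994  0.013886
#>     4  mir_038    0.09418  0.007511
#>     5  mir_046    0.08657 -0.015043
#>   ... 45 more
```

The top-ranked miRNAs are the planted large-coefficient ones; note the
rank-4/5 drop where the strong effects end. A permutation null confirms
the correlation needs the real interaction structure:

```r
randomization_control(sim$C_prime, sim$mirna_expr, sim$fc_observed,
                      "permute_after_fit", n_reps = 100, seed = 1)
#> Randomization control (permute_after_fit): 100 repetitions
#>   mean rho = -0.0060 (sd 0.0302)
```

Cumulative-inclusion curves (`cumulative_curve()`, `plateau_size()`) show
how many top-ranked miRNAs are needed before the correlation saturates,
and `compare_groups()` / `classify_mrna_fit()` / `sweep_fit_cutoff()`
compare structural features between coefficient-sign groups, top-ranked
vs other miRNAs, and well- vs poorly-predicted transcripts.

A thin command-line front end covering simulate / fit / rank / validate /
randomize is installed at `inst/cli/mirimpact.R`.

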