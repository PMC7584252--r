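# splicefve

Does DNA methylation (and the MeCP2 protein that reads it) explain
alternative splicing, beyond what genomic sequence features already
predict? `splicefve` is an R package for epigenomics/transcriptomics
analysts that turns this question into a measurable quantity: the
held-out **fraction of variance explained (FVE)** of splicing ratios and
of splicing *variation* by different feature sets.

## The model in brief

For a cassette exon with splicing ratio Ψ (fraction of transcripts
including the alternative exon, ASE):

* responses are probit-transformed, `y = Φ⁻¹(Ψ)`, and splicing variation
  between treatment and control is `Δy = Φ⁻¹(Ψ_t) − Φ⁻¹(Ψ_c)`;
* methylation features per event are the region mean methylation
  `m̂C = Σ m̂C / N_C` and the methylation density `M̂C = N_C·m̂C / L`,
  computed over five exon-centred region categories (ASE, exons with the
  ASE, exons without it, introns, introns minus the ASE) in both CG and
  CA dinucleotide contexts — 20 features per event, with between-condition
  differences `ΔΦ⁻¹(m̂C)` (means) and `ΔM̂C` (densities);
* MeCP2 binding enters as `log2(ChIP/Input)` over the ASE and its intron
  flanks;
* a regularized linear model (ridge with evidence-maximized penalty) and
  a random forest are evaluated by
  `FVE(y, ŷ) = 1 − Σ(yᵢ−ŷᵢ)² / Σ(yᵢ−ȳ)²` on five independent random
  75/25 train/test splits (FVE can be negative);
* differential splicing is called per event with a beta-binomial Bayes
  factor (uniform priors, log-space Beta functions) at BF ≥ 3, and
  changes in splicing are related to changes in methylation by Pearson
  correlation on the significant events.

A synthetic-data generator produces annotation (BED), per-cytosine
methylation tracks (bedGraph), read counts and feature matrices with an
*exactly specified* decomposition of the variance of Δy into sequence,
methylation and noise fractions — so the framework's power and null
behaviour are verifiable with no external data.

## Worked example

Plant 40% sequence signal and 20% methylation signal in the splicing
variation of 1000 synthetic events, then ask each feature set how much it
recovers:

```r
library(splicefve)

cfg <- sim_config(n_events = 1000, fve_seq = 0.4, fve_meth = 0.2, seed = 7)
X <- generate_latent_features(cfg)
set.seed(8); md <- rnorm(1000)                      # planted Δ methylation
truth <- generate_psi_and_delta(X, md, cfg)
dy <- delta_response(truth$psi_treat, truth$psi_ctrl)

evaluate_fve(cbind(X, meth_delta = md), dy, "linear_reg",
             seed = 1, feature_set = "seq+meth")
#> FVE [linear_reg | seq+meth]: mean 0.590 over 5 splits (n = 1000)
#>   splits: 0.579 0.596 0.548 0.619 0.608
evaluate_fve(matrix(md, dimnames = list(NULL, "meth_delta")), dy,
             "linear_reg", seed = 1, feature_set = "meth_only")
#> FVE [linear_reg | meth_only]: mean 0.197 over 5 splits (n = 1000)
#>   splits: 0.176 0.220 0.140 0.244 0.206
```

Sequence+methylation features recover ≈ 0.59 of the variation (planted:
0.4 + 0.2 = 0.6) and methylation alone ≈ 0.20 (planted: 0.2). Calling
differential splicing from simulated reads and correlating ΔΨ with the
planted methylation change on the significant events:

```r
reads_c <- simulate_reads(setNames(truth$psi_ctrl, truth$event_id), cfg, "c")
reads_t <- simulate_reads(setNames(truth$psi_treat, truth$event_id), cfg, "t")
calls <- bayes_factor_diff(reads_t$n_inc, reads_t$n_exc,
                           reads_c$n_inc, reads_c$n_exc)
sum(calls$significant)
#> [1] 473
dpsi <- estimate_psi_mle(reads_t$n_inc, reads_t$n_exc) -
  estimate_psi_mle(reads_c$n_inc, reads_c$n_exc)
pearson_delta_correlation(dpsi[calls$significant], md[calls$significant])
#> $r 0.522   $p 2.2e-34   $n 473
```

The whole simulate → quantify → features → regress → report chain is one
call, with every intermediate persisted as plain text and a verifiable
report:

```r
report <- run_pipeline(default_run_config(), "demo_run")
make_report("demo_run")   # recomputes every report number from the files
```

A thin command-line wrapper over these functions is installed at
`inst/scripts/splicefve.R` (subcommands `run`, `simulate`, `quantify`,
`diffsplice`, `report`).

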