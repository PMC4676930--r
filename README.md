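# isoswitch

Substrate-switch time-course RNA-seq analysis of bacterial isoprene
metabolism, for microbiologists studying how *Rhodococcus* sp. AD45 (and
related actinobacteria) sense and degrade isoprene. The package implements
the complete analysis behind the identification of the plasmid-borne
isoprene-responsive gene cluster: RPKM quantification with explicit
handling of 99%-identical duplicated gene pairs, replicate quality control,
a housekeeping-calibrated fold-change criterion against multiple controls,
coverage-based transcription-boundary detection, a wild-type versus
monooxygenase-mutant inducer contrast, a homolog-colocalization screen for
new candidate degraders, and RT-qPCR standard-curve arithmetic — plus a
planted-truth synthetic-data generator so that every stage is testable
without sequencing data.

## The method in brief

Cells pre-grown on succinate are starved and switched to one of five
substrates (isoprene, epoxyisoprene, succinate, glucose, none), sampled at
T0–T5 (0–1500 min), three replicates per cell. Expression is quantified as

```
RPKM[g,s] = count[g,s] / ( (L_g / 1e3) * (N_s / 1e6) )
```

over CDS-assigned counts. After depth (≥ 2 M reads) and replicate
cross-correlation (Pearson R ≥ 0.8 on log10(RPKM+1)) filtering, a gene is
called **substrate-responsive** when

```
F(iso T5 / T0) >= 4  and  F(iso T5 / succ T5) >= 4  and  F(iso T5 / none T5) >= 4
and the same three contrasts at epoxyisoprene T3,
F = mean_num / max(mean_den, 2.5)
```

with the fourfold threshold calibrated on the housekeeping genes *rpoB*,
*gyrA*, *gmk* (their condition range stays within ~fourfold). Genes
fourfold above T0 only at T1–T3 under epoxyisoprene — and not above the
isoprene-arm controls — form the **epoxyisoprene-only** (stress) set.
Transcription start sites and terminators are called as coverage steps
(windowed mean ratio, W = 50 bp, θ = 5) and gene runs with no internal
boundary are classified co-transcribed.

## Worked example

```r
library(isoswitch)

res <- run_pipeline(seed = 42)   # full synthetic study, ~5 s
s <- res$summary

s$retained_samples
#> [1] 84                        # of 90; four failed reactions + two discordant
s$n_responsive
#> [1] 22
sort(s$responsive)
#>  [1] "aldh1"      "aldh2"      "gshA"       "gshB1"      "gshB2"
#>  [6] "isoA"       "isoB"       "isoC"       "isoD"       "isoE"
#> [11] "isoF"       "isoG"       "isoG2"      "isoH"       "isoH2"
#> [16] "isoI"       "isoI2"      "isoJ"       "isoJ2"      "marR2"
#> [21] "SZ00_06083" "SZ00_06098"
s$n_epoxy_only
#> [1] 26
round(s$cluster_fraction_iso_t5, 1)
#> isoprene_T5_r1 isoprene_T5_r2 isoprene_T5_r3
#>           28.0           28.6           28.3
round(res$calibration$ratios, 2)
#> rpoB gyrA  gmk
#> 2.07 2.25 2.08
s$inducer_verdict
#> [1] "downstream-metabolite-induced"
```

Reading the output: the multi-control fourfold rule recovers exactly the
22 contiguous plasmid genes planted as the isoprene-responsive cluster
(the IsoMO operon `isoGHIJABCDEF`, its duplicated partners, the
glutathione-pathway genes and the marR2 regulator), none of the 6,257
other genes; the cluster carries ~28% of all reads in the isoprene-T5
samples; the housekeeping genes move less than 2.3-fold across the whole
experiment, so fourfold is a safe specificity floor; and the
`isoA`-deletion strain responds to epoxyisoprene but not isoprene, i.e.
the inducer is the downstream metabolite, not isoprene itself.

The numbered scripts under `analysis/` run the same stages as a narrated
workflow (simulation → quantification/QC → calling → boundaries → strain
contrast/qPCR → colocalization screen), writing their tables under
`results/`. The methods vignette
(`vignettes/substrate-switch-methods.Rmd`) documents the model, every
tunable parameter and the generator's assumptions.

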