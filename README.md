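# phosloc

Phosphosite localization and PSM rescoring for shotgun phosphoproteomics,
assisted by predicted retention times and fragment-ion intensities.

## The problem

Phosphoproteomics pipelines lose identifications twice: search engines
mis-assign peptides to spectra, and correctly identified phosphopeptides
end up with the phospho group on the wrong S/T/Y residue whenever the
spectrum lacks site-determining fragment ions. Modern deep-learning
predictors (of retention time and of fragment-ion intensity) supply
information that is independent of the spectrum evidence the engine
already used. `phosloc` integrates these predictions at two points:

1. **Site localization.** For each positional isoform *i* of an
   identified phosphopeptide, a base localization score (a binomial
   phosphoRS-style score, or externally supplied scores) is adjusted by
   the spectrum similarity (SS) between predicted and observed spectra
   and by the retention-time agreement:

   Score*ᵢ* = base*ᵢ* × (SSᵢ / maxⱼSSⱼ) × (RTRᵢ / maxⱼRTRⱼ),
   with RTR = min(RTp, RTe)/max(RTp, RTe)
   (or the delta-RT form minⱼDRTⱼ/DRTᵢ, DRT = |RTp − RTe|),

   and site probabilities follow a base-10 softmax,
   Pᵢ = 10^(Scoreᵢ/10) / Σⱼ 10^(Scoreⱼ/10).
   Six SS scores are implemented (dot product, √-dot product, spectral
   contrast angle, Pearson correlation, and spectral entropy similarity
   1 − (2S_AB − S_A − S_B)/ln 4, unweighted and intensity-weighted).

2. **PSM rescoring.** A semi-supervised linear-SVM rescorer in the
   Percolator style combines engine scores, engine-independent features,
   and the two predictor-derived features (weighted-entropy SS and RTR of
   the chosen isoform), with target-decoy q-values at PSM and
   phosphopeptide level and a site-probability confidence filter.

Ground-truth evaluation (false localization rate, FLR = FL/(TL+FL)),
15-mer-keyed phosphosite-level quantification, a seeded synthetic data
generator with a mock predictor, and a small CLI complete the toolkit.
Any predictor that writes the documented TSV interface can stand in for
the bundled mock.

## Worked example

```r
library(phosloc)

sim <- simulate_dataset(simulation_config(n_psms = 300, seed = 42))
loc <- localize_all(sim$psms, sim$spectra, sim$predictions, method = 4)
localization_summary(loc[[2]])
#>   spectrum_id                      peptide positions probability
#> 1    syn00002 QQGGLFNASAKSIFLVGVTPSMLSFGNK     12;24           1
#>   min_site_probability    ss   rtr   drt base
#> 1                    1 0.881 0.993 0.518 2073
```

The doubly phosphorylated peptide of spectrum `syn00002` localizes to
sites 12 and 24 with softmax probability 1 (both marginal site
probabilities 1): the predicted spectrum matches the observed one with
weighted-entropy similarity 0.881, the predicted RT is within 0.52 min of
the observed one (RTR 0.993), and the binomial base score is decisive.

```r
ft <- assemble_feature_table(loc, sim$psms, sim$spectra)
rescored <- semi_supervised_rescore(ft, seed = 42)
confident <- filter_confident(rescored)
sum(confident$passes)
#> 125
```

125 of the 300 simulated PSMs (which include reversed-peptide decoys and
deliberately false matches) pass 1% PSM and peptide FDR with site
probability above 0.75. With the planted ground truth, the standard
four-way method comparison — base localization alone (m1), predictor-
adjusted localization (m4), rescoring without (m5) and with (m7) the
predictor features — counts correctly localized PSMs at 1% FLR:

```r
bm <- benchmark_methods(sim, seed = 42)
bm$counts
#>  m1  m4  m5  m7
#>  94 108 104 127
sprintf("FLR at 0.75 site probability: %.2f%%", 100 * bm$flr_at_075)
#> "FLR at 0.75 site probability: 0.80%"
```

Both integration points help, their combination (m7) most, and the
claimed site probabilities are calibrated: above the 0.75 cutoff the
realized FLR is under 1%.

A thin CLI wraps the same functions:

```sh
Rscript inst/exec/phosloc simulate --out-dir work --seed 7
Rscript inst/exec/phosloc localize --out-dir work \
    --mgf work/spectra.mgf --psms work/psms.tsv \
    --predictions work/predictions.tsv --method 4 --rt-mode rtr
```

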