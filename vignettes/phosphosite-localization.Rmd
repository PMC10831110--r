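---
title: "Deep-learning-feature-assisted phosphosite localization and PSM rescoring"
author: "phosloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning-feature-assisted phosphosite localization and PSM rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosloc)
```

## The problem

Shotgun phosphoproteomics identifies phosphopeptides from MS/MS spectra,
but two error sources limit it: peptide-spectrum matches (PSMs) may assign
the wrong peptide, and even a correct peptide may carry its phospho group
on the wrong serine/threonine/tyrosine when the spectrum lacks
site-determining fragment ions. `phosloc` addresses both with two
predictor-derived features — the similarity between the observed spectrum
and a predicted fragment-ion intensity spectrum, and the agreement between
observed and predicted retention time (RT) — used first to re-localize
phosphosites and then to rescore PSMs. The predictor is pluggable: any
tool that emits per-isoform predicted RTs and fragment intensities through
the tabular interface (`read_prediction_table()`) can drive the pipeline,
and a fully synthetic generator plus mock predictor make every stage
testable without trained models.

## Scoring model

For one PSM with $k$ phospho groups and $n$ candidate S/T/Y residues, all
$\binom{n}{k}$ positional isoforms are enumerated (`enumerate_isoforms()`;
a combinatorial cap, default 512, flags pathological cases as
unlocalizable). Each isoform $i$ receives:

* a **base localization score** `base_i`. The bundled reference is a
  binomial score: the spectrum is filtered to its 10 most intense peaks
  per 100 Th, each primary b/y fragment is matched within the fragment
  tolerance (default 0.02 Da), and the score is
  $-10\log_{10} P(X \ge k_{\mathrm{matched}})$ for
  $X \sim \mathrm{Bin}(n_{\mathrm{ions}}, p)$ with $p$ the chance of a
  random peak landing in one matching window. Externally computed scores
  (e.g. from a dedicated localization tool) can be substituted via a
  three-column TSV (`external_base_scores()`). Neutral-loss ions are
  excluded from the binomial trial set: their count differs between
  positional isomers, which would bias the trial number $n$ between
  otherwise indistinguishable candidates.
* a **spectrum similarity** `ss_i` between predicted and observed
  intensities aligned over the isoform's theoretical ions
  (`align_peaks()`, greedy most-intense-first, one peak per ion, ties to
  the lower-m/z ion). Six scores are available (`spectrum_similarity()`):
  normalized dot product, square-root dot product, spectral contrast
  angle, Pearson correlation, and spectral entropy similarity
  $1 - (2S_{AB} - S_A - S_B)/\ln 4$ on sum-normalized spectra, unweighted
  or intensity-weighted ($I' = I^w$, $w = 0.25 + 0.5S$ for spectral
  entropy $S < 1.5$, applied per spectrum). The weighted entropy score is
  the default, reflecting its empirically strongest discrimination.
* **RT scores** (`rt_scores()`): $\mathrm{DRT} = |RT_p - RT_e|$ and
  $\mathrm{RTR} = \min(RT_p, RT_e)/\max(RT_p, RT_e)$, both in minutes.

Scores combine multiplicatively (`combine_scores()`):

$$\mathrm{Score}_i = \mathrm{base}_i \times
  \frac{ss_i}{\max_j ss_j} \times \frac{rtr_i}{\max_j rtr_j}
  \quad\text{or}\quad
  \mathrm{base}_i \times \frac{ss_i}{\max_j ss_j} \times
  \frac{\min_j drt_j}{drt_i}$$

Method 1 uses the base score alone, method 2 adds the SS factor, method 3
the RT factor, method 4 both. Site probabilities follow a base-10
softmax, $P_i = 10^{\mathrm{Score}_i/10} / \sum_j 10^{\mathrm{Score}_j/10}$,
computed in log space. The chosen isoform is the probability argmax (ties
to the lexicographically smallest position tuple). Per-site marginal
probabilities sum the probabilities of isoforms containing each site; the
confidence filter applies to the minimum marginal across the chosen
isoform's sites, the strictest consistent reading of a per-site
probability threshold.

```{r softmax-example}
sc <- data.frame(base = c(50, 50), ss = c(1, 0.8), drt = c(0.2, 2.5),
                 rtr = c(0.99, 0.90))
softmax_probabilities(combine_scores(sc, method = 4, rt_mode = "RTR"))
```

## Rescoring

`assemble_features()` builds per-PSM vectors from three sets:
engine-specific (primary score, delta score), engine-independent (peptide
length, precursor mass error in ppm, charge one-hot, missed cleavages,
fraction of theoretical ions matched, log total matched intensity) and
predictor-derived (weighted-entropy SS and RTR of the chosen isoform).
`semi_supervised_rescore()` is a self-contained implementation of the
semi-supervised SVM scheme popularized by Percolator: 3-fold
cross-validation; within each training split the initial ranking is the
single feature direction admitting the most targets at 1% FDR, positives
are re-selected at 1% FDR each of 10 iterations, negatives are all
decoys, and a linear SVM (C = 1, z-scored features) is refit; held-out
discriminants are standardized against the training decoys. A PIN export
(`write_pin()`) supports external rescoring tools. q-values use the
decoy/target ratio (capped at 1) with a cumulative minimum from the
bottom of the ranked list; no +1 correction is applied. Peptide-level
q-values come from the best PSM per modified sequence (site placement
included in the key), decoys competing. `filter_confident()` requires PSM
q ≤ 0.01, peptide q ≤ 0.01 and minimum marginal site probability > 0.75
by default. `split_finetune_sets()` carves a seeded 500-identification
test set for predictor fine-tuning and writes predictor-interface TSVs.

## Evaluation and quantification

With ground truth (`ground_truth_library()`), a localization is correct
only if peptide and full site set match a library entry; `flr_curve()`
sorts by site probability and accumulates the false localization rate
$\mathrm{FLR} = FL/(TL+FL)$; `correct_psms_at_flr()` reports the largest
true-localization count at an FLR ceiling. `benchmark_methods()` wires
this into the standard comparison: method 1 and 4 sets are taken at 1%
FDR by engine score, method 5 (rescoring without predictor features) and
method 7 (method 4 localization + rescoring with predictor features) at
1% FDR by discriminant.

Site-level quantification follows the collapse/expand/15-mer procedure:
identical modified sequences merge (quantities summed, best score kept),
records expand to one per phospho position, each maps to protein
positions by exact substring search (Leu/Ile kept distinct; peptides
matching several proteins contribute to each), and quantities sum within
(protein, 15-mer flanking identifier) groups, the 15-mer being the site
residue with 7 flanks per side, '-'-padded at termini. Zeros are treated
as missing, distinct from true zero signal; `normalize_site_table()`
log2-transforms and median-centers each sample column, and
`quantifiability_filter()` enforces per-group coverage.

## The synthetic study conditions

`simulation_config()` fixes the conditions every test and benchmark runs
under. Defaults: 20 proteins (length 100–500, natural-ish residue
frequencies), 1,000–2,000 PSMs depending on the experiment, tryptic
peptides (cleave after K/R not before P, single missed cleavage allowed,
length 7–30, ≥ 1 S/T/Y), 15% doubly phosphorylated, 30% ambiguous PSMs,
fragment intensity CV 0.3, RT jitter 0.5 min, predictor noise 0.3,
ion dropout 0.15, decoy fraction 0.5, false-target rate 0.1, four
quantity channels in two groups.

Design choices a reader should know:

* **RTs** come from a Kyte–Doolittle hydrophobicity sum (about 60 ± 20
  min over typical tryptic peptides) plus a site-position-dependent
  phospho offset of 0.7 min per residue with a small once-per-run random
  component. The positional trend guarantees every isomer pair is
  separated in true RT by at least ~0.7 min per residue of site distance;
  iid offsets were rejected because chance collisions between two
  positions make those isomer pairs permanently unresolvable run-wide,
  which is not how chromatography behaves.
* **Ambiguity** deletes every spectrum peak whose m/z distinguishes the
  true isoform from at least one competitor, the in-silico analogue of
  missing site-determining ions.
* **False targets** (claimed peptide ≠ spectrum source) exist at a
  configurable rate so that target-decoy calibration is measurable; the
  precursor m/z is always consistent with the claimed isoform (±3 ppm),
  as a search engine only reports candidates within its precursor
  tolerance.
* **The mock predictor** reuses the generative RT model and the
  deterministic fragment-intensity pattern, with Gaussian noise. Its
  intensity error is shared per ion label across competing isoforms —
  predictor error is a property of the peptide and instrument, not of
  the site hypothesis — so isomer SS differences come from m/z
  alignment, not noise. Its uninformative mode emits a constant RT and a
  flat intensity over primary ions, whose label sets coincide across
  isomers.
* The engine score is a noisy affine function of the claimed isoform's
  matched-ion fraction, leaving the rescorer genuine room to improve on
  it, as real engines do.

What the generator does **not** emulate: isotope envelopes, co-isolation
and chimeric spectra, charge-state misassignment, TMT reporter-ion
structure (quantities are per-sample columns only), peptides shared
between paralogous proteins, and systematic RT drift. Passing tests
therefore demonstrate the correctness and internal calibration of the
scoring and rescoring machinery under these conditions, not performance
on any particular instrument or cohort.

## Numerical choices and degenerate inputs

* Fragment tolerance defaults to 0.02 Da; matching is greedy,
  deterministic, one-to-one.
* DRT is floored at 0.01 min so an exact RT match cannot zero out
  competitors' `min drt / drt` factors.
* An all-zero intensity vector on either side of a similarity comparison
  scores 0; a constant vector has Pearson correlation 0; `0 ln 0 = 0`.
* If every isoform of a PSM has SS 0 (an uninformative prediction), the
  SS factor is neutralized to 1 with a warning rather than producing
  0/0.
* The binomial tail is evaluated in log space (`pbinom(..., log.p =
  TRUE)`), so scores of several hundred are exact rather than overflowed.
* The softmax subtracts the maximum score before exponentiating.
* Problem sizes in the shipped tests — 2,000 PSMs and 10 seeds for the
  benchmark ordering and calibration checks, 500 PSMs for the ambiguous
  recovery check — were chosen as the smallest sets at which the compared
  counts separate clearly from seed noise.
* On fully ambiguous, noise-free data with the uninformative predictor,
  methods 1 and 4 agree except on the few spectra where a random noise
  peak falls inside a site-determining m/z window of one isomer (about
  1–2% of spectra); the corresponding equality check allows for exactly
  this effect.

## Known limitations

* The binomial base score is a reference implementation in the
  phosphoRS family, not a bit-exact reproduction of any released tool;
  its absolute scale is steeper than typical released scores, which makes
  softmax probabilities more extreme on clean spectra.
* Only b/y ions with charge ≤ 2 and a single H3PO4 neutral loss are
  modeled; ETD ion series and multiple losses are out of scope.
* The q-value estimator uses decoys/targets without the +1 correction;
  at very small list sizes it is anti-conservative, which is why
  calibration is asserted empirically on the synthetic conditions.
* `run_pipeline()` maps peptides to proteins by exact substring search;
  very large proteomes would need an indexed mapper.
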