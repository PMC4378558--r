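---
title: "Envelope scoring and top-down spectral deconvolution with ldeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope scoring and top-down spectral deconvolution with ldeconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldeconv)
```

## The problem

Tandem mass spectra of intact proteins contain many isotopomer envelopes:
clusters of peaks produced by ions of one chemical formula and charge
state `z`, spaced by approximately `1.00235 / z` Th. Deconvolution turns
such a spectrum into a list of neutral monoisotopic masses. The hard part
is deciding, among thousands of candidate (base peak, charge) hypotheses,
which envelope matches are real: envelopes overlap, many peaks are noise,
and a sub-sampled envelope read at half its true charge looks deceptively
plausible.

`ldeconv` scores each candidate envelope match with a five-feature linear
score (the L-score) and calibrates raw scores to local false discovery
rates with per-group lookup tables, then reports a ranked, merged
monoisotopic mass list.

## Model and pipeline

**Averagine isotope model.** When only a mass is known, the elemental
composition is estimated by scaling a hypothetical average residue
(C~4.9384~ H~7.7583~ N~1.3577~ O~1.4773~ S~0.0417~, 111.1254 Da),
rounding the element counts, and adjusting hydrogens to re-hit the target
mass. The centroided theoretical distribution aggregates isotopologues by
neutron count (convolution of per-element isotope distributions; binomial
and multinomial closed forms for speed, a generic convolution power for
sulfur) and places peak `j` at `(M + j * 1.00235 + z * 1.007276) / z`.
Peaks below 1% of total probability are pruned by default, keeping the
contiguous run around the most abundant peak. The spacing constant
1.00235 Da is the centroided convention for peptide-like matter, not the
physical neutron mass.

**Candidate generation.** The noise level is the upper edge of the most
populated intensity-histogram bin (100 bins between 0 and the median
top-decile intensity, so one huge peak cannot stretch the histogram).
Every signal peak is tried as the base peak of an envelope at every
charge up to `max_charge` (default 30): the averagine distribution is
anchored with its most abundant peak on the base peak, matched to the
nearest experimental peaks within `max(0.01 Th, 15 ppm)` (ties break
toward intensity), scaled so the top-3 theoretical peaks carry the same
total intensity as their experimental counterparts, pruned below the
noise level, and filtered by the missing-peak rules: a candidate dies
with 3+ missing peaks, 2 missing of 3, 1 missing of 2, or without
`k - 3` consecutive matched peaks.

**The five features.** For a theoretical envelope `E` and experimental
envelope `E'` with `k` peak pairs:

* `d_x`: RMSD of m/z over pairs without zero-intensity placeholders (Th);
* `d_y`: RMS of per-pair relative-intensity errors, where relative
  intensity is `y / y_h` (`y_h` = tallest theoretical peak); a signed
  error `e` contributes `min(e, t)` if positive and `min(c|e|, ct)` if
  negative, with `t = 0.5`, `c = 2`. Large positive errors usually mean
  peak overlap and are capped; negative errors are rarer and penalized;
* `s`: number of supporting envelopes (same monoisotopic mass within
  15 ppm, allowing a one-isotope error, at another charge);
* `n`: number of neutral-loss envelopes (mass lower by NH~3~ 17.02655 or
  H~2~O 18.01056 Da);
* `m`: number of missing (placeholder) peaks.

The L-score is the per-group linear combination of these features; the
group is the peak-pair count bucket `{2, 3, 4, 5+}` and group 2 carries
no missing-peak weight (its filter forbids missing peaks). The shipped
default weights live in `inst/extdata/lscore_weights.txt`. No intercept
is used: within a group, ranking and the empirical FDR lookup are
invariant to an additive constant. Lower score = more likely correct.

**Local FDR.** Raw scores fall into fixed bins of width 0.02; each bin
stores the fraction of training matches labeled incorrect. Empty bins and
out-of-range scores inherit the nearest populated bin. The shipped
default table (`inst/extdata/lscore_fdr_synthetic.tsv`, regenerated by
`tools/make_default_fdr_table.R`) is trained on *synthetic* spectra with
ground-truth labels, because trained tables are data-set specific; it is
a stand-in to make the pipeline self-contained, and should be retrained
with `build_fdr_table()` when annotated real data are available. An
abstract-feature calibration was tried first and rejected: its score-to-
FDR mapping does not transfer to spectra-derived candidates.

**Selection and reporting.** Candidates are ranked by (local FDR, raw
score). A greedy pass accepts a candidate unless it shares at least half
of its matched experimental peaks with an already-accepted candidate of a
different mass — a deliberately simple stand-in for combinatorial
envelope-selection models; the ranking criterion, which is the
contribution here, is preserved. The report count defaults to
`x = 2 * (ceiling(M / m_avg) - 1)` when a precursor mass `M` is known
(`m_avg` = 118.89 Da, the unweighted mean of the 20 standard residue
average masses), reflecting one b- and one y-fragment per backbone
cleavage. Accepted envelopes with the same mass at different charges
(within 15 ppm, one-isotope error allowed) merge into a single entry with
summed intensity and best FDR; an optional local-FDR ceiling truncates
the list.

## Training

`theoretical_fragments()` builds b/y ladders (plus H~2~O/NH~3~ losses)
from an annotated proteoform; a candidate is labeled correct when its
mass maps to a fragment within 15 ppm with a ±1.00235 Da allowance
(off-by-one-isotope reads are common). `fit_weights()` runs per-group
logistic regression of the incorrect label on the features via IRLS with
a negligible ridge (1e-6) so separable toy sets still converge; the
intercept is fitted and discarded. `build_fdr_table()` bins the training
scores as above.

## What the simulator emulates — and what it does not

`simulate_spectrum()` plants multi-charge averagine envelopes with:

* log-uniform abundances (1e4–1e5) over a uniform noise floor
  (200 peaks / 2,000 Th, intensities up to `min abundance / snr`,
  default SNR 20);
* multiplicative log-normal intensity noise (sigma 0.2) and 5 ppm
  Gaussian m/z jitter;
* detection-limit dropout: a peak of relative intensity `r` drops with
  probability `dropout * exp(-r / 0.15)` (default rate 0.1), so missing
  peaks concentrate at envelope ends, as in real centroided data. A
  uniform per-peak dropout was rejected: it routinely knocks out
  mid-envelope peaks of large envelopes, which the consecutive-run filter
  then (correctly) rejects — a world inconsistent with the filter's
  design;
* an ion species appears at two adjacent charge states with probability
  0.5, which is what makes the supporting-envelope feature informative;
* centroider merging: peaks closer than 15 ppm collapse into one centroid
  (summed intensity, intensity-weighted m/z), so overlapping envelopes
  contaminate each other exactly as a centroider makes them.

It does **not** emulate: deviations of real compositions from averagine
(planted envelopes *are* averagine, so there is no model error on correct
matches), heavy-tailed interference beyond the log-normal, chromatography,
or label noise from unannotated background species. Consequently a green
recovery test establishes that the pipeline finds what its own model
describes under realistic noise — not performance on real instrument
files. One acceptance check is left deliberately red because of this gap:
in this synthetic world the KL divergence slightly outperforms the
L-score pooled over groups (0.928 vs 0.914 at the fixed seed), while the
single features and the dot product are beaten as expected. KL's
real-data failure modes — log blow-ups on model error and interference —
are absent here by construction, and we chose not to inject extra
pathologies whose only purpose would be to defeat one comparator.

`simulate_feature_set()` is a different tool: an abstract generator
(half-normal distances, small-count Poisson counts, labels drawn from the
logistic model with the given weights, mean-centered so zero weights give
50% prevalence) used for weight-recovery and calibration tests. Its
scales (sigma 1.2 and 0.9, rates 0.7/0.5/0.6) were fixed by an a-priori
Fisher-information analysis: they are close to the information-optimal
choice within the half-normal family, giving standard errors of about
0.08 for the largest weight at n = 10,000 — the statistical-power limit
for the ±0.1 recovery check. They are power settings, not spectral
realism.

## Numerical choices

* Matching tolerance `max(0.01 Th, 15 ppm)`; nearest peak wins, ties go
  to the higher intensity.
* Theoretical-distribution prune threshold 0.01 of total probability
  (the sub-noise pruning after scaling is separate and noise-driven).
* Top-3 scaling uses all peaks when fewer than three; placeholders
  contribute zero to the experimental sum; an all-placeholder top-3
  rejects the candidate.
* `k` (the group variable) counts theoretical peaks after sub-noise
  pruning, including placeholder pairs.
* KL divergence adds a pseudocount of 1e-6 of total intensity to every
  component before normalizing; an all-zero experimental vector returns
  `Inf`.
* Duplicate candidates with the same (mass, charge) keep the lowest
  (FDR, score); the FDR-calibration bin width is exactly 0.02.
* Averagine hydrogen adjustment targets the *average* mass; the
  composition always lands within half a hydrogen of the target.

## Known limitations

Profile-mode data, MS1 feature finding across retention time, PTM-aware
labeling, and combinatorial (graph-based) envelope selection are out of
scope. The shipped FDR table is synthetic-trained and should be treated
as a placeholder calibration. Raw L-scores are only weakly comparable
across groups; pooled rankings in `compare_scorers()` therefore use the
raw score and are interpreted qualitatively.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_spectrum(sim_config(n_ions = 5, seed = 7))
res <- deconvolute(sim$spectrum, max_charge = 24)
res$entries
write_masslist(res, "spectrum.msalign")
```
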