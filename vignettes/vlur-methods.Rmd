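---
title: "Methods: visual land use regression from mobile monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visual land use regression from mobile monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Mobile monitoring campaigns drive instrumented cars through a city and
record 1 Hz pollutant concentrations (NO~2~, black carbon, ultrafine
particles) together with GPS positions. Aggregated to a 50 m road-segment
network, these measurements can train land use regression (LUR) models that
map long-term concentrations everywhere in the network. Classic LUR
predictors — land-use shares, traffic intensities, population density in
buffers — miss fine-grained built-environment detail and undocumented
emission sources. Street-view imagery, collected from the same road
perspective as the measurements, can supply that detail as *visual
features*: per-panorama object counts (chimneys, traffic lights, shops,
trees, vehicles, ...) and semantic-segmentation pixel fractions (road,
wall, grass, sky, fence, ...). `vlur` implements the full modelling
pipeline that quantifies what such features add, and ships a synthetic
scenario generator with known ground truth so every stage is testable
without any proprietary data.

Image feature *extraction* (the detection and segmentation networks
themselves) is out of scope: the package consumes post-extraction feature
tables, with counts summed and fractions averaged over the four directional
images of a panorama — counts are extensive, fractions intensive; that
convention is applied once, at the extraction boundary.

# Mobile preprocessing

Raw readings pass through a fixed order of operations:

1. **Plausibility filter** — readings outside a pollutant-specific range
   are removed and counted.
2. **Winsorization** — values below/above the 2.5th/97.5th percentile are
   set to those percentiles (linear-interpolation percentile rule,
   `quantile(type = 7)`). Winsorization is applied campaign-wide per
   pollutant, not per day: it targets instrument artifacts of the raw
   series as a whole. Whether the original procedure winsorized before or
   after the temporal correction is not documented anywhere we could rely
   on; the order here (winsorize first) is a documented package choice, and
   `c(0, 100)` disables trimming entirely — appropriate for noiseless
   validation scenarios where there is nothing to trim.
3. **Reference-site temporal correction** — the background drift a fixed
   monitor sees is removed from each reading:
   `corrected = raw − (ref(hour) − mean(ref))`. The additive
   hourly-deviation form is the default because it is exactly invertible on
   the generator's additive drift; a ratio form
   (`raw · mean(ref)/ref(hour)`) sits behind `method = "ratio"`. Missing
   reference hours are a hard error listing the gaps — nothing is imputed.
4. **Snapping** — each reading is assigned to the road segment minimising
   point-to-line distance, up to `max_snap_distance` (default 20 m, the
   same buffer used for panorama assignment and validation-site matching).
5. **Drive passes** — within one car, drive day, and segment, consecutive
   readings with inter-timestamp gaps ≤ 10 s form one pass. With 1 Hz data
   and 50 m segments a pass lasts seconds, so any same-segment revisit
   after a signal gap is a new traversal. The threshold is configurable.
6. **Mean of means** — the segment value is the mean over drive days of
   the mean over that day's passes of the mean over each pass's readings.
   We read "mean of means" as nesting pass means inside day means (rather
   than pooling passes across days); the alternative reading differs only
   when pass counts are unbalanced across days, and the nested form is the
   one that weights drive days equally. Segments with zero passes are
   absent from the output, never zero-filled. Seasonal aggregation
   partitions passes by drive-day season before aggregating.

The warm season is May–October and the cold season November–April, applied
by calendar month to any year — so October 31 is the last warm day, the
dividing-date convention of the seasonal models.

# Image selection strategies

Panoramas are assigned to their nearest segment within 20 m. Three
selection strategies then produce at most one panorama per segment (per
season for the third):

* **SpecificY** — only panoramas captured inside the campaign window;
  minimal distance wins.
* **MostnearY** — all panoramas; minimal absolute year gap to the campaign
  reference year wins, then distance, then the later capture date. Since
  every segment with any panorama is retained, the MostnearY training set
  always contains the SpecificY one.
* **Season-weighted** — the MostnearY rule applied separately to
  warm-month and cold-month panoramas; two seasonal models are trained on
  season-specific aggregates and the final estimate is the mean of their
  predictions (a segment present in only one season keeps that season's
  prediction, flagged).

The campaign reference year defaults to the calendar year containing most
of the campaign window. Tie-breaks (distance → date → panorama id) are
fixed so all selections are deterministic and row-order invariant; the
original study does not document its tie-breaks, so these are package
choices.

# Predictor matrix and direction priors

Classic and visual features are inner-joined on segment id; only segments
with a mobile aggregate and (for visual variants) a selected panorama
survive, which is exactly why training-set sizes differ by strategy.
Classic-variant models are fit on the same restricted rows as their visual
counterparts, so the classic-vs-visual comparison isolates the visual
columns rather than the sample. Constant columns are dropped with a
warning; duplicate segment rows are an error.

Every column carries a direction prior: traffic, industry, port, airport,
transportation, residential and population variables are expected
positive; urban green and natural/forested areas negative; visual features
are unconstrained by default, because street-view features can carry
genuinely counterintuitive signs (grass flagging highway medians, walls
flagging tunnels) that a prior would suppress. Buffer statistics for
point/line layers use exact planar geometry (inclusion tests; analytic
chord clipping for line length); polygon layers are expected pre-gridded
to weighted cell points, the standard treatment of rasterised land-use
data. Default buffer radii follow the ESCAPE convention
{25, 50, 100, 300, 500, 1000} m.

# Learners

**Supervised stepwise linear regression (SLR).** Forward selection
maximising adjusted R², constrained so that (a) a candidate whose own
coefficient would violate its prior is ineligible this step, and (b) a
candidate whose entry would flip the sign of an already-selected
constrained coefficient is likewise ineligible (rather than triggering a
removal — simpler and deterministic). Selection stops when the best gain
falls below 0.01. Backward pruning then removes variables with p > 0.1
(worst first), variables with VIF > 3 (worst first), and finally any
variable whose constrained sign was flipped by the pruning itself. The
0.01 / 0.1 / 3 defaults are the ESCAPE supervised-LUR convention; all three
are arguments. If nothing can enter, the result is an intercept-only model
with a warning, not an error.

**Random forest.** A standard ensemble backend (`ranger`) behind a seeded
random grid search scored by k-fold cross-validated RMSE. The tuned
hyperparameters are the number of trees, the maximum depth, and the
minimum node size — the backend controls leaf granularity through node
size rather than a leaf-count cap. Forests are built single-threaded from
a fixed seed, so every fit is reproducible.

# Evaluation

R² is the *squared Pearson correlation* between predictions and
observations — deliberately, because that is the convention in this model
family, even though it measures association only and can mask calibration
bias; MAE and RMSE (concentration units) cover calibration, which is why
the SLR/RF ranking can flip between metrics. Cross-validation refits the
learner inside every fold — for the SLR this re-runs the entire stepwise
selection per fold, so no selection leakage inflates the scores, and each
fold's selected set is recorded. External validation matches long-term
fixed sites to segments within 20 m, with a common-subset mode that
intersects the matched sets across strategies for fair comparisons.

Feature importance uses Shapley values with an interventional baseline.
For the SLR the decomposition is exact and instantaneous:
φ~ij~ = β~j~(x~ij~ − x̄~j~). For forests, exact coalition enumeration is
used up to 8 features and a seeded permutation-sampling estimator beyond
(no TreeSHAP-style path attribution is available in this toolchain, and
the sampling estimator is unbiased for the same quantity). The
*street-view ratio* is the visual share of summed mean-absolute Shapley
importance, so the visual and classic shares add to one exactly.

# The synthetic scenario generator

The generator emulates the study design the pipeline targets: a planar 50 m
segment grid (rows 100 m apart so 20 m snapping is unambiguous); classic
predictors with traffic intensities tied to a major/residential road class;
latent per-segment visual features — year-stable Poisson object counts
whose rates follow road class (traffic lights co-vary with traffic
intensity, giving the selection stage realistic collinearity) and
segmentation fractions summing below one; a linear ground-truth surface
with additive seasonal offsets, whose long-term value is defined as the
seasonal mean so the consistency invariant holds even under positivity
clipping; a drive-pass-structured campaign whose readings are seasonal
truth + shared hourly drift + i.i.d. noise, with flagged implausible
outliers; a reference series observing the same drift; multi-year panorama
tables with warm-capture oversampling and a deterministic seasonal
greenery delta; and fixed validation sites placed perpendicular to host
segments, a configured fraction deliberately beyond the 20 m matching
threshold.

Default study conditions: 500 segments, a May 2019 – February 2020
campaign, 40 weekday drive days, 4 passes per segment on average,
instrument noise SD 3, street-view coverage 0.68 per year over 2015–2023,
75% warm-month capture, and an NO~2~-like truth in which traffic
intensity, population, green space, traffic lights and wall/road/grass
pixel fractions all carry signal. The drift is a weekly sinusoid plus a
linear trend, centred to zero mean over the campaign's hourly grid — that
centring is what makes the additive correction exactly invertible in the
noiseless limit.

What the generator does **not** emulate: road topology (routing, one-way
streets), geodesy, spatial autocorrelation of the residual surface
(concentrations are exactly linear in features plus noise; no published
parameters exist for a residual correlation term, so none is imposed by
default), instrument-specific calibration, or image pixels. Passing tests
therefore demonstrate algorithmic correctness and statistical behaviour
under the stated generative assumptions, not performance on real
campaigns, where nonlinearity, spatially structured residuals, and
domain shift between mobile and long-term data all matter.

# Numerical choices and degenerate inputs

* Percentiles: linear interpolation (`type = 7`), documented because
  winsorization results depend on the rule.
* Ties in image selection: distance → earlier date (SpecificY) / later
  date (MostnearY) → panorama id.
* Exactly collinear candidates (`NA` coefficients) are ineligible during
  stepwise entry; VIF is computed as 1/(1 − R²) with the denominator
  floored at 10⁻¹².
* Constant observation vectors make Pearson R² undefined: `score()`
  returns `NA` with a warning while MAE/RMSE are still reported.
* Empty inputs: empty reading tables pass through the pipeline; an empty
  segment table, an inverted plausibility range, or an empty tuning grid
  are errors of class `vlur_invalid_argument`.
* A single-valued series degenerates the density export to one unit-mass
  bin.
* End-to-end exactness on noiseless scenarios holds in the *identity
  regime*: every generating effect must contribute an adjusted-R² gain
  above the selection threshold (otherwise the stopping rule, working as
  designed, leaves it out) and no seasonal truth may touch the positivity
  floor (clipping kinks the otherwise-linear surface). The shipped
  noiseless scenario is chosen inside that regime.

# Problem sizes

The shipped validation studies run at desk scale, chosen to finish in
minutes on one core while keeping every statistical check well-powered:
networks of 60–500 segments, campaigns of 20–40 drive days, 20-seed
replications for the drift-correction and improvement studies, 50
replicates at n = 2000 with 30 candidates for parameter recovery, and
exact Shapley enumeration capped at 8 features. These sizes are package
choices; all scale up through `scenario_config()`.

# Known limitations

* The RF stage cannot reproduce a noiseless surface exactly under
  cross-validation — a bagged ensemble is not an interpolator — so exact
  end-to-end identity holds for the linear learner only.
* The permutation-sampling Shapley estimator carries Monte-Carlo error;
  ratios quoted from it should be read to about two decimal places at the
  default settings.
* External validation compares model predictions against site long-term
  values with no temporal alignment beyond the campaign window, matching
  the annual-scale use of passive-sampler data.
* The additive reference correction assumes the background drift is shared
  and additive; multiplicative drift calls for the ratio variant.
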