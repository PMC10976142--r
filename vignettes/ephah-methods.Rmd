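---
title: "Half-against-half PLS-DA for large-class NIR classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-against-half PLS-DA for large-class NIR classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephah)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the tunable parameters with their defaults and
the reasons behind them, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open. It states
no empirical result that the test suite does not itself compute.

## 1. The classification problem

The data are matrices of NIR diffuse-reflectance spectra: rows are samples,
columns are absorbances on a uniform wavenumber grid (the default mirrors a
common FT-NIR acquisition: 2074 points from 4000 cm⁻¹ at 3.857 cm⁻¹
spacing, so the top end lands at 11 995.66 cm⁻¹ rather than exactly
12 000 — the generator keeps the point count and lets the top end fall where
it falls). Classes are many (ten in the motivating application: polyethylene
packaging from ten different producers) and spectrally similar, since every
class shares the same polymer backbone; what distinguishes classes is small
differences in additive content, visible as small band-amplitude shifts.

## 2. Multiclass decomposition

Binary reductions of a $k$-class problem:

* **OAO** trains $k(k-1)/2$ pairwise models. Each model never sees $k-2$ of
  the classes, yet votes on every test sample; with many classes those
  blind votes become substantial noise.
* **OAA** trains $k$ models of one class against the rest. Each model sees
  all data but with a $1:(k-1)$ imbalance that biases the threshold.
* **EPHAH** trains one binary model per balanced bipartition
  $(G_P, G_N)$ of the class set, $|G_P| = \lceil k/2 \rceil$. For even $k$,
  complements describe the same classifier, so $\binom{k}{k/2}/2$ distinct
  models are needed (the planner keeps, for each complement pair, the subset
  containing the first class — a deterministic choice); for odd $k$ all
  $\binom{k}{\lceil k/2 \rceil}$ subsets are used. Every model is trained on
  every sample with a near-balanced coding, removing both defects at the
  cost of more models: 45 / 10 / 126 for OAO / OAA / EPHAH at $k = 10$.

Prediction: OAO models vote for one of their two classes; EPHAH models with
response $\ge c$ vote for *every* class of $G_P$, otherwise for every class
of $G_N$; the most-voted class wins. OAA uses the maximum response instead of
votes, the standard rule for that decomposition. With $k = 6$ and a binary
oracle that always decides for the side containing the true class, the true
class collects all 10 votes and each other class exactly 4 (it shares a side
with the true class in 4 of the 10 bipartitions) — the acceptance suite
checks this tally.

**Ties.** Maximum-win ties are resolved by recursively building the same
decomposition restricted to the tied classes (trained lazily on the stored
training data and cached per tied subset), re-voting, and recursing to depth
2 on a shrinking tie; a persistent tie falls back to the largest mean signed
response margin and finally to class order. The depth limit and the margin
fallback are our additions: recursion on a non-shrinking tie set does not
terminate, so a deterministic fallback is required.

## 3. The binary engine: NIPALS PLS-DA

Each binary task is a PLS1 regression of the coded response
$y \in \{+1, -1\}$ on the (mean-centered, unscaled) spectra via classic
NIPALS with deflation; no variance scaling, because derivative-pretreated
spectra carry meaningful relative magnitudes. Regression coefficients are
kept for every truncation $1..A$ of the latent variables, making
cross-validation over LV counts cheap. The decision threshold $c$ defaults
to 0, the natural midpoint of the symmetric coding.

**Model complexity.** Each model's LV count is chosen by Monte Carlo
cross-validation: repeated stratified random holdouts (defaults: 100 splits
in the package interface; the acceptance suite uses 15–30 at its reduced
problem sizes, a choice of problem scale rather than of method), error rate
$\mathrm{ERMCCV} = \sum_i M_i / N$ with $M_i$ the misjudged count of split
$i$ and $N$ the total tested; the smallest LV count attaining the minimum
wins. Holdout fraction defaults to 20%. Because each binary task selects its
own complexity, a decomposition reports a *fractional* mean LV count.

## 4. Outlier screening

Samples are screened per class (the class is the statistical population; a
global option exists). For a PCA model with $p$ components fitted about a
column-wise median center, each sample gets

* a **score distance** $\mathrm{SD}_i = \sqrt{\sum_a t_{ia}^2/\lambda_a}$,
* an **orthogonal distance** $\mathrm{OD}_i$, the Euclidean residual norm,

compared against F-based limits: the Hotelling $T^2$ limit
$p(n-1)/(n-p)\,F_{\alpha;p,n-p}$ for SD² and its $(n+1)/n$-inflated
companion for the OD (the two limits differ by exactly that factor — an
identity the tests verify). Both limits are also exposed on the squared
scale on which such thresholds are conventionally tabulated
(e.g. 14.35 / 14.54 at $p=6, n=75, \alpha=0.95$). The four-way taxonomy
(regular, good leverage, orthogonal outlier, bad leverage) follows from the
two exceedances. The removal policy defaults to flagging *either* exceedance;
a high-OD-only policy is available.

Two numerical choices deserve emphasis:

* **Masking resistance.** A PCA fitted on contaminated data absorbs a strong
  outlier into its own loadings, collapsing that sample's OD and inflating
  the eigenvalues that damp its SD. `screen_outliers` therefore defines a
  clean core by Stahel–Donoho directional outlyingness (candidate directions
  through the data points, cut at median + 5 MAD — a deliberately generous
  cut that only excludes gross contamination), fits the PCA on the core, and
  scores every sample against that model. This is a light robustification,
  well short of full ROBPCA (no projection pursuit, no MCD), which is out of
  scope. `fit_pca` itself remains a plain median- or mean-centered SVD.
* **OD scale.** The F-based OD limit is dimensionless while the raw residual
  norm is in absorbance units and depends on the noise level, so ODs are
  standardised to unit median within each screened group before comparison.
  The median is resistant to the outliers being hunted.

The component count defaults to the smallest $p$ reaching 99.9% cumulative
explained variance, the conventional criterion; on small noisy data sets a
fixed $p$ (the tests use 4–6) is more stable and can be passed explicitly.

## 5. Partitioning

* **Kennard–Stone**: max–min Euclidean coverage; ties broken by lowest
  sample index so the selection is deterministic and row-order invariant.
* **SPXY**: Kennard–Stone on the joint distance
  $d_x/\max d_x + d_y/\max d_y$; class labels are one-hot encoded for
  $d_y$ (the method was designed for continuous responses; one-hot coding is
  the natural embedding for a classification task). A constant response
  degenerates gracefully to plain Kennard–Stone.
* **Stratified DUPLEX 6:2:2**: per class, $n_{train} = \lfloor 0.6\,n_c
  \rfloor$ and the remainder is split evenly between validation and test
  with an odd remainder going to validation — the only rounding rule
  consistent with the published per-class counts the acceptance suite checks
  (class sizes 75, 75, 84, 85, 85, 74, 74, 69, 65, 60 give 446/150/150).
  Within a class, sets are filled in round-robin DUPLEX fashion: each set is
  seeded with the most mutually distant remaining pair and then takes the
  remaining sample farthest from its current members.
* **Random**: seeded shuffle-and-cut, stratified by label when present.

## 6. Pretreatment

Fifteen standard single and combined pretreatments are exposed through a
compact name grammar (`SNV`, `MSC`, `SG-w`, `1D[-w]`, `2D[-w]`, joined by
`+`; `SG-w` immediately followed by a derivative token fuses into a single
Savitzky–Golay derivative step of window $w$). Windows are counted in
points — the conventional even or sub-minimal window choices in the
literature are bumped to the nearest legal odd value — and the polynomial
order defaults to 2, which is never stated alongside such names. Derivatives
are returned in physical units (per cm⁻¹, per cm⁻²) by scaling with the grid
step. Savitzky–Golay boundaries use the filter's own polynomial edge rows so
the point count is preserved for downstream matrix shapes. SNV uses the
$n-1$ denominator. MSC regresses each spectrum on a reference (the training
mean); at prediction time the reference is frozen from the training set so
no test information leaks into the correction.

## 7. Synergy-interval PLS

The axis is divided into $k$ equal-width (in cm⁻¹) contiguous half-open
intervals; on a uniform grid each point owns the cell it starts, so the span
runs one step past the last point and every point belongs to exactly one
interval. All $\binom{k}{j}$ combinations of $j$ intervals are evaluated
exhaustively — a budget guard (default $10^6$) rejects infeasible sweeps —
by cross-validated RMSECV of a PLS model on the concatenated columns,
optimised over LV counts up to `lv_max` per combination (whether to fix or
optimise LVs per combination is an open choice; optimising is the safer
default and is what the recovery tests validate). Ties go to the
lexicographically first combination. Within a decomposition, each binary
task runs its own search and contributes $j$ selections to an
interval-frequency table; the share captured by the five most-selected
intervals is the usual summary for declaring characteristic regions.

## 8. The synthetic generator

Each class is a sum of 14 Gaussian bands: 13 shared characteristic peaks of
the methylene combination/overtone system (4250, 4323, 5245, 5338, 5390,
5440, 5700, 5773, 5940, 7010, 7230, 7340, 7378 cm⁻¹ — the published peak
list for this band system has 13 entries and all are used) plus one ester
band at 5300 cm⁻¹ inside the 5160–5500 cm⁻¹ ester second-overtone window.
Gaussian line shapes are an assumption (no line shape is standard for NIR
overtone bands); widths are drawn once, uniformly in 15–40 cm⁻¹, so that
adjacent peaks partially overlap as in measured spectra. Classes share all
band positions, widths and base amplitudes and differ only by per-band
relative amplitude perturbations of scale `class_separation` — the
"same polymer, different additives" structure of the application.

A simulated spectrum is

$$x = g \cdot s_{class} + o + b(\nu) + \varepsilon,$$

with per-sample gain $g \sim 1 + N(0, 0.05)$ and offset
$o \sim N(0, 0.01)$ (multiplicative/additive scatter), a random polynomial
baseline $b$ of degree ≤ 2 with coefficient scale 0.01 on a normalised
abscissa (instrument drift and background), and i.i.d. noise
$\varepsilon \sim N(0, \texttt{noise\_sd})$. One root seed fans out to
per-stage substreams so profiles, spectra and outlier injection can be
regenerated independently.

**Defaults as study conditions.** The default configuration is 10 classes ×
75 samples on the full 2074-point grid with `class_separation = 0.02` and
`noise_sd = 0.01`. The separation/noise pair was calibrated once so that the
default 10-class problem sits in a *moderate-overlap* regime — mean test
accuracies roughly in the 0.6–0.9 band, between chance (0.1) and ceiling
(1.0) — because a strategy comparison is uninformative at either extreme;
our first guess (separation 0.08) made the problem fully separable. All
other scales were chosen as plausible for diffuse-reflectance absorbance
data and not revisited.

**Outlier injection** corrupts a seeded subset in one of three ways:
`shifted-baseline` (large constant offset), `alien-band` (a Gaussian band in
the upper, signal-free grid region, width at least three grid steps so it is
always resolved — this targets a high orthogonal distance), and
`extreme-leverage` (the sample is moved to a fixed number of
score-standard-deviations along the set's dominant principal direction —
targeting a high score distance; the displacement is set absolutely rather
than by scaling the sample's own projection, which for a sample near the
center would produce no effect).

**What the generator does not emulate:** wavelength-dependent scatter,
band-position shifts (temperature/crystallinity effects), non-Gaussian noise,
detector nonlinearity, water-vapour interference, and correlated replicate
structure. Passing tests therefore demonstrate correctness of the
algorithms and recoverability of planted structure under idealised
conditions, not field performance on instrument data.

## 9. Problem sizes used by the tests

The test and acceptance suites run the full workflow at reduced scale — the
package's own choice of desk-scale conditions: coarse grids of 100–500
points covering the same 4000–12 000 cm⁻¹ range, 6–25 samples per class,
MCCV with 15–30 splits, and 10–50 seed replicates for the stochastic
properties (planted-interval recovery, planted-LV-rank recovery,
outlier-flagging rates, and the OAO/OAA/EPHAH comparison as a 20-seed
ensemble mean). The combinatorial and analytic facts (task counts, vote
tallies, cutoff values, split arithmetic, accuracy ratios) are scale-free.

## 10. Known limitations

* The strategy comparison depends on the LV-selection protocol: with a
  fixed common LV count the three decompositions are much closer on this
  generator's data, and OAO can edge ahead; the documented ordering is
  measured under per-task MCCV selection.
* ERMCCV of an EPHAH task is not directly comparable to that of an OAO task
  (different sample populations and class structures enter each binary
  problem).
* The OD control limit applies the F-based formula to a median-standardised
  residual norm; it is a pragmatic convention, not a derived null
  distribution (standard robust-PCA practice uses a Wilson–Hilferty
  chi-square approximation instead, which we deliberately do not).
* Recursive tie resolution retrains sub-models on the stored training data;
  for very large data sets that memory cost may be unwelcome (drop the
  `training` element of the model to disable it; the margin fallback then
  applies).
* The SI-PLS budget guard makes large $\binom{k}{j}$ sweeps fail fast rather
  than run for hours; backward/forward interval selection heuristics are out
  of scope.
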