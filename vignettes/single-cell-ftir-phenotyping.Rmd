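---
title: "Methods: single-cell FTIR phenotyping and heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell FTIR phenotyping and heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scFTIR)
```

This vignette is the package's own account of the science it implements:
the forward model behind the synthetic data, each pretreatment and
analysis step with its assumptions and tunable parameters, the numerical
choices made where the methodology was genuinely open, and what the
passing test suite does and does not demonstrate about real beamline
data.

## 1. The measurement and its nuisance structure

A single-cell mid-IR experiment yields, per cell, an absorbance trace
$A(\nu)$ on a shared wavenumber grid — here 4000–600 cm⁻¹ at 4 cm⁻¹
spacing (851 points), the resolution typical of synchrotron FTIR
microprobes with a cell-sized aperture. The chemical signal is a sum of
absorption bands from the major macromolecule classes; three nuisance
processes sit on top of it:

* **white instrumental noise**, well described as additive Gaussian;
* **broad baseline drift** from detector and optical effects;
* **Mie scattering** by the roughly spherical cell body (radius 2–8 μm,
  refractive index ≈ 1.1–1.5), which superimposes a broad oscillatory
  extinction curve on the absorbance and, in the *resonant* regime,
  couples to the absorption bands themselves because the real refractive
  index and the absorption are linked by the Kramers–Kronig relation.

## 2. The forward simulator

`default_band_model()` fixes one documented band table (single source of
truth for all tests): Gaussian bands at 2920, 2850, 1740, 1650, 1545,
1456, 1390, 1084 and 984 cm⁻¹ with amplitudes relative to Amide I = 1 AU
and FWHMs of 15–40 cm⁻¹ by band class. Senescence is modelled as
multiplicative amplitude scaling $(1 + e\,w_b)$ with weights $w = 1$ on
the lipid bands (2920, 2850, 1456), $w = 0.5$ on the protein bands
(1650, 1545), and a cholesterol-ester carbonyl band at 1740 cm⁻¹ that
grows from zero as $0.3\,e$; no frequency shifts are applied by default.
The weights are **stand-ins**: the biology motivating them (dominant
lipid/cholesterol-ester and protein changes in senescent cells) is
qualitative, and no reference quantifies band-level fold changes. At
effect size $e = 0$ the two populations are statistically identical,
which is what makes the null-calibration tests meaningful.

`render_spectrum()` adds, per cell: lognormal per-band amplitude jitter
(cv 0.15 — a realistic magnitude for single-cell biological
variability), a random polynomial baseline (degree 2, coefficient sd
0.01 AU), and white noise (sd 0.002 AU, i.e. peak SNR ≈ 500, typical of
co-added synchrotron scans). `apply_mie_distortion()` implements the van
de Hulst (anomalous diffraction) extinction efficiency
$$Q(\rho) = 2 - \tfrac{4}{\rho}\sin\rho + \tfrac{4}{\rho^2}(1-\cos\rho),
\qquad \rho = 4\pi r \nu (n-1),$$
with $r$ converted from μm to cm so that $\rho$ is dimensionless; with
`resonant = TRUE` the refractive index is perturbed by the discrete
Kramers–Kronig transform of the absorbance, scaled to a peak excursion
of 10% of $(n-1)$. The distorted trace is $A + 0.1\,Q$ by default, i.e.
scatter oscillations commensurate with the strongest bands. A Taylor
series replaces the closed form below $\rho = 10^{-4}$ where it is
numerically unstable. These generator defaults are the package's fixed
study conditions; they were chosen once, from the physics above, and are
not adjusted per analysis.

Determinism: every cell's randomness derives from `(seed, cell index)`
via a fixed integer recurrence, so any subset of a population is
reproducible in isolation.

What the simulator does **not** emulate: water-vapour and CO₂ lines,
detector nonlinearity, spatial heterogeneity within a cell, correlated
(pink) noise, band-shape changes (only amplitudes move), and
class-imbalanced designs. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical structure,
not performance on any particular beamline's artefacts.

## 3. Pretreatment chain

Order is enforced through the `stage` field (`raw → smoothed →
baseline_corrected → emsc_corrected → second_derivative`); skipping
forward is allowed, reordering is an error, and no operation mutates its
input.

**Smoothing** — 9-point Savitzky–Golay, order 2 (`sg_smooth()`). A plain
9-point smoother in FTIR practice is Savitzky–Golay; it preserves band
shape and reproduces polynomials up to the fit order exactly, including
at the grid edges (the projection matrix uses asymmetric fits there).

**Baseline** — `baseline_correct()` defaults to rubberband correction
(subtracting the lower convex hull, computed by Andrew's monotone
chain), with an ordinary polynomial fit as the alternative. Vendor
"automatic" baselines are proprietary, so absolute band heights here may
differ from values produced by instrument software; both methods are
offset-invariant and flatten affine trends to machine precision.

**RMieS-EMSC** — `rmie_emsc()` regresses each trace on a reference
spectrum, an affine/quadratic baseline, and the leading principal
components of a dictionary of van de Hulst extinction curves spanning
radius 2–8 μm × index 1.1–1.5 (10 × 10 curves, 7 components kept), then
removes the fitted interferents; the reference is replaced by the
corrected trace and the scheme iterates (max 10 iterations, relative-
change tolerance 1e-4). Convergence diagnostics are always attached;
`n_iterations = 1` is classical EMSC. Two deliberate choices:

* *Reference*: a "matrigel-like" synthetic reference (the noiseless
  control band model) by default — a generic cellular spectrum that is
  **not** equal to any simulated cell — or the set mean.
* *Output scale*: the default output subtracts the fitted baseline and
  scatter but keeps each cell's own intensity scale. The classical
  variant that also divides by the multiplicative coefficient
  (`emsc_config(scale = "reference")`) projects every cell onto the
  reference's intensity; for whole single cells that normalisation
  discards real biology — total biomass differs between cells and
  between populations — and measurably weakens downstream group
  separation, so it is opt-in rather than default.

A per-cell resonant dictionary (extinction curves built from the
Kramers–Kronig transform of each spectrum) was evaluated and not
adopted: on these study conditions it gave no measurable recovery or
classification benefit over the shared dictionary at several times the
cost.

**Second derivative** — Savitzky–Golay window 9, order 3 (`ts` set to
the grid spacing so units are AU·cm²). The window/order are exposed;
9/3 is a conventional choice balancing band sharpening against noise
amplification. Absorption maxima appear as negative minima; the
operator is linear and exact on quadratics, which the tests verify
against closed forms.

**Regions** — `extract_region()` implements the standard analysis
windows: lipids 3000–2800 ∪ 1480–1300, proteins 1800–1480, nucleic
acids/carbohydrates 1300–900, and the full informative range 3000–2800 ∪
1800–900 cm⁻¹. Boundary membership uses a half-spacing rule (a grid
point within half a spacing of a window edge is included), applied
everywhere; on the default grid the three fingerprint regions tile
900–1800 cm⁻¹ with exactly the two shared boundary points double-counted.

**Normalisation** — off by default (`l2_normalize()` is available and
tested); cell-to-cell intensity differences are treated as signal, for
the same reason as the EMSC scale choice.

## 4. Heterogeneity statistics

Distances are computed on second-derivative spectra by default — the
derivative suppresses residual baseline and scatter, so distances
reflect band structure — with the non-derivative path available
(`ftir_config(derivative = FALSE)`). The count identities
$n(n-1)/2$, $x\,y$ and $\binom{x+y}{2} = \binom{x}{2} + \binom{y}{2} +
xy$ are asserted over random sizes, and the vectorised distances are
checked against an element-loop oracle to 1e-12.

Histogram fits use Freedman–Diaconis binning by default (scale-free) and
a Levenberg–Marquardt Gaussian fit initialised at the sample moments;
non-convergence is reported in the result object.

The location test in `heterogeneity_report()` deserves care: pairwise
distances sharing cells are dependent, so a naive rank-sum test on the
two distance sets is anticonservative. When the pooled distance matrix
and labels are available (as in `run_pipeline()`), the report instead
permutes the group labels and recomputes the inter-minus-in mean
difference (199 permutations), which is calibrated under the null by
construction; the Wilcoxon p-value is retained only as a descriptive
fallback when just the distance vectors are supplied, and is labelled as
such.

Ward clustering runs on the precomputed Euclidean distance matrix
(`stats::hclust`, `"ward.D2"`). Ward-on-precomputed-distances differs
subtly from Ward-on-coordinates in some toolchains; the package uses the
distances directly, matching a workflow in which the distance matrix is
the exported object. Dendrograms export to Newick via `ape`.

## 5. PCA, ellipses and classification

PCA is mean-centred with no variance scaling (standard for spectra,
where the variables share units). Signs are fixed by making each
loading's largest-magnitude coefficient positive, so score plots are
reproducible. The 95% confidence ellipse is the parametric Gaussian
contour: centre = mean, shape = covariance, squared radius =
$\chi^2_{0.95}(2)$, computed from `qchisq`, never hard-coded; a
small-sample F-corrected variant is available because plotting software
differs in which it draws, and the choice matters at n ≈ 40.

The classification rule is a reconstruction (only membership counts are
typically reported in the motivating workflow): predict the group whose
ellipse contains the cell, breaking both/neither ties by Mahalanobis
distance; a stricter `outside_control` variant calls every cell outside
the control ellipse senescent. All memberships and distances are
returned per cell. Sensitivity and specificity are exact ratios; the
1-decimal rounding seen in reports happens only at presentation.

Note the training and evaluation use the same cells (as is typical when
a confusion table is read off a score plot); reported accuracies are
therefore apparent, not cross-validated, and the null-calibration test
(below) is what guards against overinterpreting them.

## 6. Problem sizes and calibration checks

The shipped tests and the acceptance script use: 40 + 40 cells at effect
size 0.5 for end-to-end runs (20 seeds), 10–15 cells per group for
property sweeps, 20 replicates for the EMSC forward–inverse recovery
check, 10,000 draws for ellipse coverage and Gaussian-fit recovery, and
199 permutations for the location test. These sizes were chosen to match
the canonical 40-cell design and to keep Monte-Carlo standard errors
well inside the asserted bands. With effect size 0 the pipeline's
apparent accuracy sits near chance (the ellipse rule's tie-break makes
it hover slightly above 50%) and the permutation test rejects at its
nominal rate — the pipeline does not manufacture separation.

## 7. Known limitations

* The van de Hulst approximation, not the full Mie series; adequate for
  baseline-artefact modelling, not for quantitative scattering physics.
* No atmospheric correction, Fourier self-deconvolution, or Amide I
  sub-band fitting.
* The EMSC dictionary assumes homogeneous spheres; aspherical or
  internally structured cells produce artefacts outside the model.
* Effect-size weights in the simulator are qualitative stand-ins (see
  §2); absolute classification performance on synthetic data should not
  be read as a claim about any real instrument.
* JCAMP-DX support covers the plain `(X++(Y..Y))` AFFN subset only;
  compressed ASDF encodings are rejected with a message.
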