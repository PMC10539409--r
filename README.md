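# scFTIR

Single-cell FTIR spectral phenotyping and heterogeneity analysis in R.

## The problem

Mid-infrared microspectroscopy measures one absorbance spectrum per cell:
a label-free fingerprint of its lipids (C–H stretches at 3000–2800 cm⁻¹,
CH₂ bend near 1456 cm⁻¹, ester carbonyl near 1740 cm⁻¹), proteins (Amide I
and II near 1650 and 1545 cm⁻¹), and nucleic acids/carbohydrates (PO₂⁻
near 1084 cm⁻¹, RNA C–O near 984 cm⁻¹). Comparing two cell populations —
for example control versus senescent macrophages — raises three
statistical questions this package answers:

1. **Are the populations biochemically different, cell by cell?**
   Quantified by cell-to-cell Euclidean distances
   `d(a, b) = √Σᵢ (aᵢ − bᵢ)²` over the N retained spectral points: one
   group of n cells yields n(n−1)/2 in-group distances; two groups of x
   and y cells yield x·y inter-group distances. Distance histograms are
   summarised by least-squares Gaussian fits and a label-permutation test
   of the inter-minus-in mean difference; the pooled distance matrix is
   clustered by Ward linkage.
2. **Which spectral features drive the difference?** Mean-centred PCA of
   the (second-derivative) spectra; PC1/PC2 score plots with per-group 95%
   confidence ellipses (Mahalanobis radius √χ²₀.₉₅(2)) and loading traces
   aligned to the wavenumber axis.
3. **Can a single cell be called senescent?** Ellipse-membership
   classification (predict the group whose ellipse contains the score;
   Mahalanobis tie-break), scored by sensitivity = TP/(TP+FN) and
   specificity = TN/(TN+FP) against a reference label.

Raw single-cell spectra are dominated by instrument noise, baseline drift
and resonant Mie scattering from the cell body. The pretreatment chain
provides 9-point Savitzky–Golay smoothing, rubberband (convex-hull)
baseline correction, iterative resonant-Mie EMSC scatter correction
against a van de Hulst extinction dictionary, and Savitzky–Golay second
derivatives, with stage ordering enforced.

Because public single-cell FTIR datasets are scarce, the package ships a
forward simulator: parametric absorption-band models for a control and a
senescent population (senescence scales lipid and protein band amplitudes
and grows the 1740 cm⁻¹ cholesterol-ester band), per-cell amplitude
jitter, baseline drift, white noise, and Kramers–Kronig-coupled Mie
distortion. Every analysis stage is tested against this generator.

## Worked example

```r
library(scFTIR)
res <- run_pipeline(ftir_config(seed = 1))
print(res)
#> <ftir_pipeline>
#> <ftir_config> seed 1, 40 + 40 cells, effect 0.5, region full,
#>   emsc TRUE, derivative TRUE, level 0.95, rule membership
#>   PC1/PC2 explained variance: 62.7% / 15.8%
#>   classification accuracy 100.0%; sensitivity 100.0%, specificity 100.0% (positive = 'senescent')
#> <heterogeneity report>
#>   in-group:    mean 0.001912, median 0.001829, sd 0.0006561
#>   inter-group: mean 0.004224, median 0.004121, sd 0.0009795
#>   mean difference (inter - in): 0.002312
#>   label permutation (mean inter - mean in): p = 0.005 (inter-group located above in-group)
```

Reading the output: two simulated populations of 40 cells were smoothed,
baseline-corrected, EMSC-corrected and differentiated; PCA of the
full-region second derivatives puts 62.7% of the variance on PC1, every
cell falls on the correct side of the two 95% ellipses (accuracy 100%),
and inter-group cell-to-cell distances (mean 0.0042 AU·cm², second
derivative units) exceed in-group distances (mean 0.0019), a location
shift the permutation test calls significant at p = 0.005 (the smallest
p-value attainable with 199 label permutations). Individual pieces are
available as `res$pca`, `res$ellipses`, `res$distances`,
`res$heterogeneity`, `res$hca`, `res$performance`, and
`plot(res$pca, res$ellipses)` draws the score plot.

The classic worked example for the metrics alone — a screening that
catches 39 of 39 senescent cells with one false positive among 41 calls:

```r
sensitivity_specificity(confusion_matrix(tp = 39, fp = 1, fn = 0, tn = 40))
#> sensitivity 100.0%, specificity 97.6% (positive = 'senescent')
```

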