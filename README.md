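# irheart

Stain-free histology for cardiac transplant biopsies from mid-infrared
chemical imaging.

## The problem

Acute cellular rejection after heart transplantation is monitored by
endomyocardial biopsy: small right-ventricular tissue samples are stained
(H&E) and a pathologist looks for lymphocytic infiltrates and myocyte damage.
The reading is subjective and slow. FT-IR spectroscopic imaging measures a
full mid-infrared absorbance spectrum at every pixel of an unstained section;
the vibrational bands of proteins (amide I at 1652 cm⁻¹, amide II at
1543 cm⁻¹, the collagen-dominated amide III region at 1204–1239 cm⁻¹) and of
glycogen (1027–1032 cm⁻¹) differ between myocardium, endocardium, fibrotic
tissue and lymphocytes, so every pixel can be classified into a histologic
class by its chemistry alone.

`irheart` implements that pipeline for people working with hyperspectral
tissue images: spectroscopists prototyping stain-free histology, and method
developers who need a controlled synthetic testbed.

## The method

For each pixel spectrum *A(ν)* (absorbance vs wavenumber ν in cm⁻¹, 800–4000
at 2 cm⁻¹ step):

1. **Mask** — pixels with raw *A*(1652) < 0.30 AU carry no protein and are
   excluded.
2. **Baseline** — a two-point linear correction: the chord through fixed
   anchor wavenumbers (defaults 900/1800 and 2800/3600) is subtracted.
3. **Normalize** — divide by the amide I peak height, removing section
   thickness.
4. **Metrics** — reduce the spectrum to scalar features from four families:
   peak height ratios *h(ν₁)/h(ν₂)*, band areas above a local chord, area/
   height and area/area ratios, and centers of gravity
   Σν·A′(ν) / ΣA′(ν). The default library is the 27 published definitions
   (21 height ratios, 3 area/height, 3 centers of gravity).
5. **Classify** — a weighted naive-Bayes model: per class *c* and metric *m*
   a univariate Gaussian likelihood, combined as

   P(c | x) ∝ π_c · Π_m f_cm(x_m)^{w_m},

   with exponents w_m = max(AUC_m − ½, 0) (normalized to mean 1) from each
   metric's one-vs-rest ROC on the training set. Pixels whose maximum
   posterior falls below 0.5 stay *unclassified*.
6. **Evaluate / render** — one-vs-rest ROC curves, Pd at 10% Pfa,
   column-normalized confusion tables, a sample-level rejection call from
   lymphocyte pixel burden, foci (8-connected components) and myocardial
   encroachment, plus pseudo-color class maps.

Because no patient data accompany the method, the package ships a synthetic
phantom generator (`synth_phantom()`): layered biopsy layouts with Gaussian
band models per class, thickness variation, baseline drift, 500:1
acquisition SNR and boundary-mixed pixels, with full ground truth.

## Worked example

```r
library(irheart)

# simulate a 64 x 64 biopsy phantom and fit the classifier on it
ph  <- synth_phantom(phantom_spec(rows = 64, cols = 64, seed = 1))
pp  <- preprocess_cube(ph$cube)                    # mask + baseline + amide-I norm
defs <- default_metric_library()                   # the 27 published metrics
fe  <- compute_features(pp$cube, pp$mask, defs)
fit <- ir_bayes(fe, ph$truth$labels, metric_library = defs)
fit
#> Weighted naive-Bayes FT-IR tissue classifier
#>   classes: Myocardium, Endocardium, Fibrosis-Endocardium, Fibrosis-Myocardium, Lymphocytes
#>   likelihood: gaussian; 17 selected metrics; posterior threshold 0.50
#>   training pixels per class: 2253, 348, 348, 172, 243

pred <- predict(fit, fe)                           # per-pixel class map
confusion(pred, ph$truth$labels, pp$mask)
#> Confusion table (column-normalized %, truth in columns):
#> ... columns each sum to 100; diagonal (correct-class %) reads
#> Myocardium 97.2, Endocardium 88.8, Fibrosis-Endocardium 92.5,
#> Fibrosis-Myocardium 88.4, Lymphocytes 100.0 (errors sit on mixed
#> boundary pixels, which carry the dominant class as truth) ...

post <- predict(fit, fe, type = "posterior")
curve <- roc_one_vs_rest(post, class_code = 5, ph$truth$labels, pp$mask)
pd_at_pfa(curve, 0.10)                             # lymphocyte Pd at 10% Pfa
#> [1] 1

rejection_report(pred)
#> Rejection call: POSITIVE
#>   lymphocyte pixels: 264 (7.848% of 3364 tissue pixels)
#>   foci (>= 4 px, 8-connected): 3; encroaching on myocardium: TRUE
```

The numbers mean: with the default phantom's class separations and noise,
lymphocytes are detected essentially perfectly at the pixel level, and the
sample-level call is positive because lymphocyte foci touch myocardium —
the hallmark used to separate rejecting from non-rejecting samples.

`run_pipeline(run_config(out_dir = "out"))` chains
simulate → preprocess → features → train → classify → evaluate → render and
writes every artifact (ENVI cube, model JSON, confusion and Pd CSVs, ROC
CSVs, rejection JSON, PNG renderings, resolved config, log); identical
config + seed reproduces all numeric artifacts bit-exact. A thin CLI wrapper
lives in `inst/scripts/irheart_pipeline.R`.

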