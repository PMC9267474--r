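# msipath

Quantitative analysis of narrow-band multispectral microscopy of
H&E-stained skin sections: calibrate raw band frames to reflectance,
segment nuclei / keratin pearls / collagen, measure the nucleocytoplasmic
ratio in sliding windows, and separate normal skin from cutaneous squamous
cell carcinoma (cSCC) statistically. A ground-truthed synthetic scene
generator stands in for slide data, so the entire chain is testable end to
end.

## Who this is for

Researchers building or validating label-free / digital-staining pathology
pipelines on multispectral data, and anyone who needs a reference
implementation of the band-wise segmentation + window-ratio approach with
exact, auditable semantics.

## The method

Raw counts are converted to reflectance per band (wavelength λ):

    R(λ) = (I_raw(λ) − I_dark) / (I_ref(λ) − I_dark)

after averaging five repeat frames, with an adaptive two-dimensional gamma
correction `γ(x,y) = 0.5^((m − F(x,y))/m)` (F = Gaussian illumination
estimate, m = its mean) flattening residual nonuniformity. Structures are
segmented at their absorption bands — nuclei 660 nm, keratin/lipid 600 nm,
collagen 520 nm — by contrast-limited local histogram equalization, median
filtering, and adaptive mean thresholding (dark foreground, tissue-local
statistics). A 100×100 px window slides at 50 px stride; underexposed,
blank, low-tissue and keratin-junction windows are excluded; five
non-overlapping windows are selected and the nucleocytoplasmic ratio

    NC% = 100 · nuclear_px / tissue_px

is summarized per section as mean/max/min. Groups are compared with
pooled-variance Student's t-tests and ROC/AUC (tie handling equal to the
Mann–Whitney statistic), cSCC positive.

## Worked example

Simulate a small cohort (3 sections per group at the default 512×640
frame), run the full pipeline in memory, and report:

```r
library(msipath)
res <- run_cohort(n_per_group = 3, seed = 7)
report_cohort(res)
#> Sections: 3 normal, 3 cSCC
#> Group mean nucleocytoplasmic ratio (mean statistic): normal 3.766%, cSCC 17.384%
#> mean ratio: t =   -9.192, p = 0.000778, AUC = 1.000
#> max  ratio: t =   -6.624, p = 0.00269, AUC = 1.000
#> min  ratio: t =   -8.968, p = 0.000855, AUC = 1.000

res$summaries
#>  section_id  label mean_pct max_pct min_pct
#>   normal_01 normal    4.148    5.39    1.90
#>   normal_02 normal    4.262    6.62    2.77
#>   normal_03 normal    2.888    3.20    2.54
#>     cscc_01   cscc   18.684   29.11   12.22
#>     cscc_02   cscc   18.910   24.14   13.36
#>     cscc_03   cscc   14.558   19.67    9.90
```

Each row is one section: the mean/max/min of the nucleocytoplasmic ratio
over its five selected windows, in percent. Carcinoma sections run several
times higher than normal skin; the t-test quantifies the group difference
and the AUC the discrimination (1.0 = the two groups separate completely).

The same analysis as a file-based workflow lives under `analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R   # 21+21 raw sections -> scratch/cohort/
Rscript analysis/02_run_pipeline.R      # calibrate/segment/quantify -> results/*.csv
Rscript analysis/03_group_stats.R       # t-tests, ROC -> results/group_stats.csv
Rscript analysis/04_figures.R           # overlay + plots -> scratch/figures/
```

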