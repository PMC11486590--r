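# spongiometry

Quantitative-MRI morphometry of the metaphyseal spongiosa in the
developing femoral head.

## What problem this solves, and for whom

In Legg-Calvé-Perthes disease (and its piglet model), ischemic injury to
the femoral epiphysis disturbs the metaphysis on the far side of the
growth plate: the *primary spongiosa* (the hypointense zone of
provisional calcification) and the *secondary spongiosa* (the
hyperintense bone-remodelling zone) change in relaxation time and thin
measurably within a week. These bands are 1–2 mm thick at a 0.52 mm MRI
pixel, so conventional region-of-interest statistics are fragile.

`spongiometry` is for imaging scientists who need that measurement as a
tested, reproducible pipeline:

1. **Relaxometry** — per-pixel mono-exponential fits
   `S(t) = S0 · exp(−t/T)` to magnetization-prepared series (T2, T1ρ,
   adiabatic T1ρ/T2ρ), log-linear or signal-domain Levenberg–Marquardt,
   plus bicubic interpolation to the 0.17 mm analysis grid.
2. **Line-profile morphometry** — profiles cast from the proximal
   growth-plate boundary 10 mm into the metaphysis along local boundary
   normals, averaged per depth with an iteratively 3σ-clipped (Gaussian)
   mean; the first profile minimum is the primary spongiosa, the first
   maximum after it the secondary spongiosa; inflection points of the
   smoothed profile delimit the band thicknesses; a 0.7 mm window at four
   times the PS–SS distance samples the mature metaphysis.
3. **Paired statistics** — per metric and contrast:
   `t = mean(d)/(sd(d)/√n)`, 95% CI, paired Cohen's
   `d = |mean(d)|/sd(d)`, and per-subject percent change, reproducing a
   published-tables-style 4 contrasts × 6 metrics summary.
4. **Synthetic data** — banded femoral-head phantoms (analytic Gaussian
   band blending, Rician noise, control/ischemic presets parameterized
   from reference cohort summaries) and a paired-cohort generator, so the
   whole pipeline is testable without scanner data.

See `vignettes/spongiometry-methods.Rmd` for the model, parameter
defaults and known accuracy limits.

## Worked example

```r
library(spongiometry)

# a control-pattern phantom imaged at prep times 0..80 ms, SNR 50
ph  <- generate_phantom(phantom_preset("control", "T2", seed = 42))
map <- interpolate_map(fit_monoexponential(ph$series$T2), 3)
map
#> <relaxation_map> T2: 138 x 84 px @ 0.1733 mm, 11592 fitted px, median T 67.4 ms

measure_femoral_head(map, ph$truth$boundary)
#> <morphometry_result> T2
#>   primary spongiosa:   62.6 ms at 1.66 mm, thickness 1.12 mm
#>   secondary spongiosa: 93.5 ms at 2.97 mm, thickness 1.59 mm
#>   mature metaphysis:   65.8 ms; total thickness 2.71 mm
```

The phantom's true band values were 57.9 / 92 / 65.4 ms with spongiosa
widths 1.12 and 1.90 mm: values are recovered to a few ms (the 62.6 ms
primary-spongiosa reading reflects partial-volume averaging of a 1.12 mm
band at 0.52 mm acquisition), the primary-spongiosa thickness to the
pixel, and the secondary-spongiosa thickness with the ~0.2 mm compression
expected at this resolution.

```r
# a synthetic paired cohort at the secondary-spongiosa T2 effect size
spec <- cohort_spec(10, c(ss_value = 92),    c(ss_value = 12),
                        c(ss_value = -13.3), c(ss_value = 9.3), seed = 1)
paired_analysis(as_paired_cohort(generate_paired_cohort(spec), "T2"),
                "ss_value")
#> <paired_stats> T2 ss_value (n=10): diff -11 +/- 9.95, t=-3.49, p=0.0068, d=1.10
```

Each draw of ten pairs at a true effect of −13.3 ± 9.3 ms yields its own
mean difference (here −11 ms) and is flagged significant in the large
majority of replicates.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/spongiometry", package = "spongiometry"))')
Rscript $CLI make-phantom --out ph --condition control --contrast T2 --seed 5
Rscript $CLI fit-maps     --series ph/T2_series.json --interp 3 --out ph/maps
Rscript $CLI measure      --map ph/maps/T2_map.json --boundary ph/boundary.csv --out ph/res
Rscript $CLI run          --manifest manifest.csv --out results
Rscript $CLI cohort-stats --measurements results/measurements.csv --out results
Rscript $CLI make-cohort  --out cohort.csv --n 10 --seed 2
```

`run` drives fit → measure → stats for a whole manifest
(`subject_id, side, contrast, series, boundary` columns) with a
provenance log (config hash, per-item timings, failures).

## File formats

Image series and maps travel as plain text: one headerless CSV matrix per
preparation time plus a JSON sidecar
(`{prep_times_ms, pixel_spacing_mm, contrast_label, files}`). To convert
a NIfTI series, write each prep-time slice with, e.g., Python's
`nibabel`:

```python
import nibabel, numpy
img = nibabel.load("T2_series.nii.gz").get_fdata()   # x, y, prep
for k in range(img.shape[-1]):
    numpy.savetxt(f"T2_t{k:02d}.csv", img[..., k].T, delimiter=",")
```

then list those files in the sidecar. Boundaries are `x_mm,y_mm` CSVs;
results are one-row CSV/JSON per femoral head.

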