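# kneegap

Virtual gap-balance simulation for mechanically aligned (MA),
measured-resection (MR) total knee arthroplasty (TKA).

## What problem this addresses, and for whom

In MA TKA the distal femur and proximal tibia are cut perpendicular to the
mechanical axes, and the posterior femoral cut — which sets femoral
component rotation — is referenced to bony landmarks. Because individual
anatomy is ignored, the four resulting gaps (extension/flexion ×
medial/lateral) are generally unequal, and the choice of posterior
reference changes how unequal. `kneegap` is for biomechanics and surgical-
simulation researchers who want to quantify those imbalances on 3D knee
surface models (their own, or synthetic cohorts with analytic ground
truth), and to compare the four standard posterior references.

## The model

Per knee, from a landmark set and labeled femoral/tibial articular
surfaces (cartilage included, as in MRI-derived models):

* **Axes** — femoral mechanical axis: hip center → intercondylar notch;
  tibial: ankle center → proximal tibia center. HKA = signed coronal angle
  between them (varus > 0; the 0° boundary goes to the valgus group).
* **Posterior references** — TEA (epicondylar landmarks), WSL (the in-plane
  perpendicular of Whiteside's line), PCA + 3° external rotation (tangent to
  the posterior condyles), FEA (line joining Kåsa least-squares circle
  centers fitted to each condyle's sagittal posterior profile).
* **Cuts** — distal femoral and proximal tibial planes perpendicular to the
  mechanical axes at depth d = 9 mm from the most distal condyle / most
  proximal plateau; posterior femoral planes perpendicular to the distal
  plane, parallel to each reference axis, 9 mm from the most posterior
  condyle along the plane normal.
* **Gaps** — per compartment c ∈ {med, lat}:
  `ext_c = t_distal,c + t_tibial,c`, `flex_c = t_posterior,c + t_tibial,c`,
  where t is the compartment's maximal resected thickness. Imbalances:
  `MLI = lat − med` (per pose), `FEI_c = ext_c − flex_c`; the balance
  criterion at threshold τ is `|FEI_med| ≤ τ ∧ |FEI_lat| ≤ τ`.

A parametric generator (`generate_knee`, `generate_cohort`) builds synthetic
varus/valgus osteoarthritic cohorts from analytic condylar primitives with
exact ground truth; cohort statistics (`welch_t`, `anova_posthoc`,
`chi_squared`, `balance_rate_table`, `imbalance_histogram`) and report
writers round out the pipeline. See the methods vignette
(`vignettes/gap-imbalance-simulation.Rmd`) for conventions, assumptions and
limitations.

## Worked example

```r
library(kneegap)

k <- generate_knee(knee_params(hka = 8.2, wear_fem_med = 1.6,
                               wear_tib_med = 1.4, noise_sd = 0.05,
                               seed = 42), id = "example")
rec <- simulate_knee(k)
rec[, c("method", "hka", "group", "ext_med", "ext_lat",
        "flex_med", "flex_lat", "mli_ext", "mli_flex", "fei_med", "fei_lat")]
#>  method hka group ext_med ext_lat flex_med flex_lat mli_ext mli_flex fei_med fei_lat
#>     TEA 8.2 varus    15.6      18     16.6     16.1    2.45   -0.514   -1.08   1.885
#>     WSL 8.2 varus    15.6      18     16.6     16.1    2.45   -0.514   -1.08   1.885
#>     PCA 8.2 varus    15.6      18     16.6     15.8    2.45   -0.780   -1.08   2.151
#>     FEA 8.2 varus    15.6      18     16.6     17.4    2.45    0.778   -1.08   0.593
```

This is a varus knee with medial femoral and tibial cartilage wear: the
medial extension gap (15.6 mm) is smaller than the lateral (18 mm), giving
a positive extension MLI of 2.45 mm — the classic varus trapezoid. The
extension row is method-independent; the flexion gaps (and so MLI in
flexion and the FEIs) depend on the posterior reference.

At cohort level:

```r
cohort <- generate_cohort(cohort_spec(n_varus = 40, n_valgus = 10, seed = 1))
crec <- simulate_cohort(cohort$knees)
ext <- crec[!duplicated(crec$knee_id), ]   # extension rows, one per knee
summarize_metric(ext, "mli_ext", group = "varus")
#> n = 40: 1.49 +/- 1.07 (-1.13, 3.59)
welch_t(ext$mli_ext[ext$group == "varus"], ext$mli_ext[ext$group == "valgus"])
#> $t [1] 11.98329   $df [1] 17.13246   $p [1] 9.369347e-10

bt <- balance_rate_table(crec)
bt[bt$group == "varus" & bt$method == "TEA", ]
#>  method group threshold  n rate
#>     TEA varus         1 40   10
#>     TEA varus         2 40   45
#>     TEA varus         3 40   90
```

The varus group's mean extension MLI exceeds the valgus group's (Welch
p < 0.001), and the balance rate grows with the threshold — the structural
properties the acceptance tests assert. Cohort magnitudes depend on the
generator's (documented, placeholder) anatomical distributions and are not
calibrated to any real population.

## Command line

```sh
Rscript inst/cli/kneegap generate --out cohort/ --n-varus 50 --n-valgus 10 --seed 7
Rscript inst/cli/kneegap simulate --in cohort/ --out results.csv
Rscript inst/cli/kneegap report   --in results.csv --out report/
```

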