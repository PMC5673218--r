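# lutadose

Organ and tumour dosimetry workflows for ¹⁷⁷Lu-DOTATATE peptide receptor
radionuclide therapy (PRRT), with a digital-phantom simulator that makes
every stage of the pipeline verifiable against analytic ground truth.

PRRT dosimetry is mandatory for organs at risk (above all the kidneys) and
tumours, and clinics estimate it with one of three imaging workflows:

1. **multi-SPECT-CT** — quantitative SPECT/CT volumes of interest at every
   imaging time point;
2. **planar** — conjugate-view (geometric-mean, √(I_a·I_p)) whole-body
   scintigraphy with a thickness-weighted background subtraction,
   `wf = 1 − d_organ/d_body`, and no attenuation correction;
3. **hybrid** — the planar time–activity curve rescaled by a single SPECT
   VOI measurement at ~24 h p.i., with projection-overlapping regions
   removed and substituted from the residual volume
   (factor `V_total/V_residual`).

All three feed the same kinetics and MIRD dose model: a mono-exponential
fit `A(t) = A0·exp(−λ_eff·t)` of each organ's time–activity curve, the
residence time `τ = A0/(λ_eff·A_admin)` (cumulated activity normalised to
the administered activity, in hours), and the mass-adjusted absorbed dose

```
D = τ · A_admin · (3.6×10¹² decays/GBq·h) · Δ_e · (1.602×10⁻¹³ J/MeV) / m
```

with Δ_e = 0.1479 MeV per decay (¹⁷⁷Lu electron energy, local-deposition
model; external S-value tables can be plugged in), reported as dose and as
dose per injected activity (DpA, Gy/GBq ≡ Sv/GBq). Tumours use the sphere
model at liver density with sphere recovery coefficients for the partial
volume effect.

The package is aimed at medical physicists and methods developers who want
to study how these workflow choices — overlap handling, background
weighting, attenuation, partial volume, single-SPECT rescaling — propagate
into organ and tumour doses, on fully controlled synthetic studies or on
their own data (NIfTI volumes and masks, CSV curves, JSON manifests).

## Worked example

Simulate a patient-equivalent study on the bundled reference phantom
(liver with a ~20 g lesion, kidneys, spleen, lungs; the liver overlies the
right kidney in projection) and run all three workflows:

```r
library(lutadose)

study <- simulateStudy(referencePhantomSpec(),
                       referenceAcquisitionSpec(seed = 7),
                       administrationRecord(7.2))   # 7.2 GBq administered
res <- runAllScenarios(study)
res$multi_spect
#> ScenarioResult 'multi_spect': 6 organ(s)
#>         organ   tau_h mass_g dose_Gy dpa_Gy_per_GBq
#>         liver 24.3333 298.92  49.999         6.9443
#>        tumour  1.0566  21.20  43.448         6.0344
#>  kidney_right  0.9523  25.20  23.212         3.2239
#>   kidney_left  0.9494  25.20  23.139         3.2138
#>        spleen  1.9215  45.58  25.893         3.5962
#>         lungs  0.7762  87.88   5.425         0.7534

sapply(res, function(r) r@doses$dpa_Gy_per_GBq[r@doses$organ == "kidney_right"])
#> multi_spect      planar      hybrid
#>    3.223864   10.090229    3.397354
```

The liver-overlapped kidney shows the clinically familiar pattern: the
planar workflow inflates its DpA (here ~3×), the hybrid workflow sits a
few percent above the multi-SPECT-CT value, and the ordering
planar > hybrid > multi-SPECT holds. A cohort of jittered phantoms feeds
the paired statistics:

```r
coh <- simulateCohort(6, seed = 3)
cmp <- compareScenarios(cohortDoseTable(lapply(coh, runAllScenarios)))
ratioTable(cmp)[, c("organ", "hybrid_multi_1dp", "planar_multi_1dp")]
#>          organ hybrid_multi_1dp planar_multi_1dp
#> 1  kidney_left              1.0              0.7
#> 2 kidney_right              1.1              3.3
#> 3        liver              1.0              0.6
#> 4        lungs              1.0              0.9
#> 5       spleen              1.0              0.6
#> 6       tumour              1.0              0.4
```

`cmp` also carries per-organ Friedman and pairwise Wilcoxon signed-rank
tests against the multi-SPECT-CT scenario; `kendallsW()` /
`simulateObserverStudy()` quantify inter-observer concordance of 3D vs 2D
delineation. Overlap-free deep organs go the other way (planar ratios
below 1): without scatter, uncorrected planar quantification loses counts
to attenuation, and superposition is what pushes it above the SPECT-based
estimates — see the methods vignette (`vignettes/dosimetry-workflows.Rmd`)
for the model, its assumptions and its limits.

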