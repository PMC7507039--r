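# vesselperm

Quantitative DCE-MRI permeability mapping and HR-MRI vessel-wall
morphometry for intracranial artery stenosis, in R.

When an inflammatory stenosis of the middle cerebral artery disturbs the
blood–brain barrier, the disturbance is measurable as the volume
transfer constant K<sup>trans</sup> (1/min) of a tracer-kinetic model in
the downstream territory, and the structural lesion is measurable on
vessel-wall MRI as lumen/vessel/wall areas and a stenosis grade.
vesselperm implements both quantitative chains, the cohort statistics
used to compare aetiology groups (CNS vasculitis, atherosclerosis,
moyamoya), and a fully seeded synthetic-data module that generates every
input with known ground truth, so the whole pipeline is validated by
parameter recovery.

## The models

**T1 mapping.** Variable-flip-angle spoiled gradient-echo signals
S(α) = M₀ sin α (1−E₁)/(1−E₁ cos α), E₁ = exp(−TR/T₁), fitted per voxel
by the S/sin α on S/tan α linearisation (`fit_t1_vfa`).

**Concentration.** Invert the SPGR form for R₁(t) per dynamic frame;
C(t) = (R₁(t) − R₁(0))/r₁ with r₁ = 3.6 s⁻¹mM⁻¹
(`signal_to_concentration`).

**Kinetics.** Extended Tofts model

&nbsp;&nbsp;C<sub>t</sub>(t) = V<sub>p</sub> C<sub>p</sub>(t) +
K<sup>trans</sup> ∫₀ᵗ C<sub>p</sub>(τ) exp(−k<sub>ep</sub>(t−τ)) dτ,
&nbsp; k<sub>ep</sub> = K<sup>trans</sup>/V<sub>e</sub>,

with the plasma input C<sub>p</sub> from a sagittal-sinus mask
(`extract_aif`, hematocrit-corrected) or a population curve
(`population_aif`). Fitted voxelwise by the linear least-squares
reformulation (`fit_extended_tofts_linear`), cross-checked by bounded
nonlinear least squares (`fit_extended_tofts_nls`).

**Morphometry.** WA = VA − LA by pixel counting
(`measure_cross_section`); percent stenosis
(1 − LA_target/LA_reference)·100 (`stenosis_degree`); grades mild
(< 50%) / moderate (50–70%) / severe (> 70%) / occlusion (> 90%, or
> 99% as the strict variant); extent focal (≤ 1/3 of M1) / segmental /
full-length (≥ 2/3).

**Statistics.** Summary-statistic and raw two-sample t tests, Levene,
Wilcoxon rank-sum (exact for small samples), Pearson chi-square without
continuity correction, Fisher's exact test, Spearman correlation, and a
normality/variance-gated dispatcher (`compare_groups`).

## Worked example

```r
library(vesselperm)
rep <- run_pipeline(default_run_config(seed = 1))
print(rep)
```

```
vesselperm pipeline report (seed 1 )
  T1 fit: 4096/4096 voxels; Tofts fits: 3968 (679 flagged)
  Ktrans lesion 0.0987, mirror 0.0030 (difference 0.0957 /min)
  cohort tests:
    age_vasculitis_vs_athero         two-sample t (pooled)        p = .001
    smoking_vasculitis_vs_athero     Pearson chi-square           p = .017
    smoking_vasculitis_vs_moyamoya   Pearson chi-square           p = .286
    ktrans_lesion_vs_mirror_acute    two-sample t (welch)         p < .001
    ktrans_acute_vs_none             two-sample t (welch)         p < .001
    stage_by_stenosis                Pearson chi-square           p = .389
```

The phantom's lesion territory was generated at K<sup>trans</sup> =
0.098 /min and its mirror at 0.003 /min; at SNR 50 the fitted ROI means
(0.0987 and 0.0030) recover both, and the lesion–mirror difference of
≈ 0.096 /min is the imaging signature of a disrupted blood–brain
barrier. The cohort tests run on the generated 36-patient table, whose
categorical structure (23/10/3 aetiology split, risk-factor counts,
stage-by-stenosis table) is reproduced exactly for any seed — hence the
deterministic contingency p-values (.017 for smoking vasculitis vs
atherosclerosis, .286 vs moyamoya) — while continuous fields are drawn
from truncated normals at the reference group means.

The same stages can be run as separate file-mediated steps:

```sh
Rscript analysis/01_simulate.R      # phantom, vessel sections, cohort
Rscript analysis/02_fit_kinetics.R  # T1 map -> concentration -> AIF -> Tofts -> ROI
Rscript analysis/03_morphometry.R   # areas, stenosis %, grades
Rscript analysis/04_cohort_stats.R  # test battery + cohort proportions
```

each printing what it found and writing its tables under `results/`.

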