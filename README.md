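# ludosim

Image-based absorbed-dose estimation for [¹⁷⁷Lu]Lu-PSMA-617 radioligand
therapy: **2D planar**, **3D SPECT/CT** and **hybrid** dosimetry, with
method-agreement statistics and a digital-phantom generator.

## The problem

Radioligand therapy of metastatic castration-resistant prostate cancer
with [¹⁷⁷Lu]Lu-PSMA-617 irradiates not only tumour tissue but also
normal organs that physiologically express PSMA — the kidneys, the
liver and the salivary glands, the organs at risk that limit cumulative
activity. Post-therapy dosimetry from the 208 keV photons of ¹⁷⁷Lu is
therefore routine, and three workflows compete:

* **2D method** — serial anterior/posterior whole-body scintigrams at
  ~24, 48 and ≥96 h p.i., quantified by the conjugate-view
  (geometric-mean) method. Cheap, but planar quantification suffers
  from organ overlap, background and segmentation biases.
* **3D method** — serial quantitative SPECT/CT with volume-of-interest
  segmentation and recovery-coefficient partial-volume correction; the
  reference method, but three SPECT/CT sessions per cycle are a heavy
  burden.
* **hybrid method** — kinetics from the serial planar study, absolute
  scale from a *single* SPECT/CT: the 2D time-activity curve is
  rescaled so that it passes through the SPECT activity on day 1 (or
  day 2).

This package implements all three chains end to end, plus the paired
statistics used to compare them (median relative differences, exact
Wilcoxon signed-rank test, Bland-Altman limits of agreement), and a
synthetic digital-patient generator with analytic ground truth so that
every step of the chains is testable.

## Core quantities

* Conjugate view:
  `A = sqrt(C_A · C_P / T̄) · f / cf`, with `T̄ = I_trans/I_blank` the
  mean transmission over the organ, `f = (μt/2)/sinh(μt/2)` the source
  self-attenuation factor and `cf` the per-scan counts/MBq calibration
  from a known-activity vial. Scatter is removed first by the
  dual-energy-window estimate `C_pk − C_sc · W_pk/W_sc`
  (208 keV ± 20 % / 187 keV ± 15 % → width ratio 1.483).
* SPECT: voxel cps × calibration factor (Bq/cps, from a 6595 ml
  cylinder) → VOI activity / RC(volume). The shipped clinical RC table
  is 0.85 (≥20 ml), 0.79 (13 ml), 0.67 (10 ml), 0.59 (6 ml);
  `measure_recovery_curve()` derives the blur-matched curve for
  synthetic studies.
* Kinetics: weighted mono-exponential fit `A0·e^(−λt)`; piecewise TIA =
  rectangle `A(t1)·t1` + trapezoids on `[t1, tn]` + physical-decay tail
  `A(tn)/λ_phys`; TIAC = TIA / administered activity.
* Dose: `D = TIA × S(m)` with mass-scaled dose factors —
  reference-organ factors for kidneys/liver, the unit-density sphere
  model (local electron deposition, Δₑ = 0.1479 MeV per decay) for
  salivary glands and bone metastases. Reported as Gy and Gy/GBq.
* Agreement: per pair `100·(x−y)/((x+y)/2)`; limits of agreement
  `mean ± 1.96·SD`.

## Worked example

```r
library(ludosim)

# a digital patient with biological kinetics, noisy acquisitions
res <- run_pipeline(reference_phantom_spec("biological", seed = 7),
                    noise = TRUE)
print(res)
```

```
Dosimetry pipeline result
        region method tia_MBqh dose_Gy dose_Gy_per_GBq
       kidneys     2D  12918.2   3.499          0.5467
         liver     2D  19654.6   1.064          0.1663
       parotid     2D   1560.0   2.535          0.3961
 submandibular     2D    770.6   3.124          0.4882
      bone_met     2D   1377.2  18.739          2.9279
       kidneys     3D  14174.6   3.839          0.5998
         ...
       kidneys hybrid  14066.5   3.810          0.5953
         ...
```

Per region the table reports the time-integrated activity (MBq·h), the
absorbed dose for this 6.4 GBq cycle and the dose per administered
activity. The 2D estimates sit below the 3D reference (organ-edge
segmentation losses of the planar chain), while the hybrid estimates —
same kinetics, SPECT scale — track the 3D method closely:

```r
print(res$comparison, digits = 3)
#>          region   comparison diff_pct
#> 1       kidneys     2D vs 3D   -9.275
#> ...
#> 6       kidneys hybrid vs 3D   -0.766
```

At cohort scale (24 patients, 65 cycles, one SPECT region class per
patient):

```r
report <- analyze_cohort(generate_fixture_cohort(24, 65, seed = 7))
print(report)
#> Cohort method comparison (reference: 3D)
#>   region   comparison  n median_diff_pct p_value loa_halfwidth_pct
#>  kidneys     2D vs 3D 33         -16.622 0.00626              40.4
#>  kidneys hybrid vs 3D 33           0.185 0.84418              16.2
#>  ...
```

Planar dosimetry underestimates the kidney dose with wide limits of
agreement; hybrid dosimetry is nearly unbiased with limits less than
half as wide — in every region class.

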