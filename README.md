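# bonedma

Viscoelastic constitutive modelling of human alveolar cancellous bone from
dynamic mechanical analysis (DMA), parameterised by bone mineral density
(BMD).

## The problem

Orthodontic tooth movement remodels the cancellous bone of the tooth
socket, and the remodelling shows up as local changes in BMD
(ρ, g/cm³). Because trabecular bone is viscoelastic, the stiffness and
damping that an orthodontic or masticatory load actually sees depend on
both the loading frequency and the local density. `bonedma` is for
bone-biomechanics researchers who want to turn DMA frequency sweeps of
small cancellous-bone specimens into a density-dependent generalized
Maxwell material model — and for anyone who needs a fully synthetic,
reproducible stand-in for such a study to develop and test against.

## The model

A specimen is a generalized Maxwell solid: an equilibrium spring E∞ in
parallel with n spring–dashpot branches (relaxation times τᵢ = ηᵢ/Eᵢ).
In Prony form, with weights gᵢ ∈ (0,1) and instantaneous modulus E₀:

    E(t)  = E∞ + E₀ Σᵢ gᵢ exp(−t/τᵢ)
    E′(ω) = E∞ + E₀ Σᵢ gᵢ τᵢ²ω² / (1 + τᵢ²ω²)
    E″(ω) =      E₀ Σᵢ gᵢ τᵢω  / (1 + τᵢ²ω²)

The density-dependent constitutive model makes the amplitudes power laws
in ρ while sharing one fourth-order spectrum:

    E′(ρ,ω) = Aρᵐ + Aρⁿ Σᵢ gᵢ τᵢ²ω²/(1+τᵢ²ω²)
    E″(ρ,ω) = Bρ^q   Σᵢ gᵢ τᵢω /(1+τᵢ²ω²)

Across specimens the equilibrium modulus follows the power law
E∞ = 1213.482 ρ^2.039 MPa. Parameters are identified from per-frequency
steady-state (E′, E″) pairs by constrained multi-start Levenberg–Marquardt
least squares (τᵢ > 0 and 0 < gᵢ < 1 enforced exactly by the
parameterisation). The methods vignette
(`vignettes/bone-viscoelasticity.Rmd`) documents the model, the
identifiability analysis and every numerical choice.

## Worked example

Simulate the nine-specimen study (3 tooth regions × 3 root depths,
densities 0.604–0.926 g/cm³, sweeps at 0.5/1/2/5 Hz for 20 min at 25 °C),
fit every specimen, and fit the density power law across specimens:

```r
library(bonedma)
report <- suppressWarnings(run_pipeline(config = study_config(seed = 2), seed = 2))
print(report)
```

```
DMA study report: 9 samples fitted (order 4)
   sample_id   BMD equilibrium_mpa r2_joint
 R1_cervical 0.926         957.232 1.000000
   R1_middle 0.766         770.587 1.000000
   R1_apical 0.735         470.087 0.998513
 R2_cervical 0.862         811.281 1.000000
   R2_middle 0.652         636.452 1.000000
   R2_apical 0.616         331.168 1.000000
 R3_cervical 0.826         798.718 1.000000
   R3_middle 0.638         452.126 1.000000
   R3_apical 0.604         209.774 1.000000
Equilibrium-modulus power law:  E_inf = 1177.27 * rho^2.273  (r^2 = 0.8006)
Steady-state percent change, lowest -> highest frequency:
   sample_id   bmd freq_low_hz freq_high_hz storage_change_pct loss_change_pct
 R1_cervical 0.926         0.5            5              8.769          -9.468
   R1_middle 0.766         0.5            5              6.290          -2.420
   R1_apical 0.735         0.5            5              4.960          -7.360
 R2_cervical 0.862         0.5            5             14.238          -9.950
   R2_middle 0.652         0.5            5              2.861         -12.580
   R2_apical 0.616         0.5            5             14.036          -4.102
 R3_cervical 0.826         0.5            5              7.499          -8.244
   R3_middle 0.638         0.5            5              5.707          -4.440
   R3_apical 0.604         0.5            5             22.253          -3.898
```

Reading the output: each specimen's order-4 fit interpolates its four
steady-state frequency points essentially perfectly (joint R² ≈ 1; the
`suppressWarnings` hides the identifiability notice that a 4-frequency
protocol under-determines an order-4 spectrum — see the vignette). The
fitted equilibrium moduli rise with density and their power-law fit
(exponent 2.27, r² 0.80) sits close to the generating relation
(2.039, r² 0.877), with the residual scatter coming from the per-specimen
spectra and the ω→0 extrapolation. The change table shows the expected
frequency behaviour: storage modulus increases (here +2.9…+22%) and loss
modulus decreases (−2.4…−12.6%) from 0.5 Hz to 5 Hz.

The same workflow runs from a shell:

```sh
Rscript inst/cli/bonedma.R run --seed 2 --out-dir out      # simulate + fit + report
Rscript inst/cli/bonedma.R simulate --seed 2 --out-dir out # just write study.csv
Rscript inst/cli/bonedma.R fit --input out/study.csv --out-dir out
```

writing `report.json`, `params.csv`, `powerlaw.json` and `changes.csv`.

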