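# icgpbpk

Whole-body physiologically based pharmacokinetic (PBPK) modelling of
indocyanine green (ICG) liver function tests, for hepatologists,
hepatobiliary surgeons and modellers who need a mechanistic link between a
measured ICG curve and the state of the liver.

ICG is an inert, plasma-protein-bound dye that is cleared exclusively by
hepatic uptake and biliary excretion, with no metabolism, reabsorption or
enterohepatic recirculation. Its plasma disappearance after an intravenous
dose is therefore a direct dynamic liver function test, summarized as the
plasma disappearance rate (ICG-PDR = 100·kel, %/min), the retention ratio
15 min after dosing (ICG-R15 = c(15)/c_max), clearance
(CL = V_d·kel, with V_d = D/(AUC_inf·kel)) and half-life (ln 2/kel).

The package provides:

* a whole-body circulation model (venous/arterial blood, lung,
  gastrointestinal tract, liver, rest) with irreversible convective
  transport `Q_i · C_i` and a three-step liver: Michaelis–Menten sinusoidal
  uptake (with competitive bilirubin inhibition), Michaelis–Menten biliary
  excretion, first-order bile-to-feces transport, all scaling with
  functional liver volume;
* dosing protocols (timed boluses over a finite injection duration,
  infusion segments, priming doses) and a stiff-capable simulator with
  exact mass-balance bookkeeping and ±25% per-parameter uncertainty
  envelopes;
* non-compartmental analysis of simulated or observed curves;
* disease/surgery scenarios: cirrhosis as lockstep intrahepatic shunting +
  parenchymal tissue loss (`f_cirrhosis`, with the Child–Turcotte–Pugh
  classes at 0 / 0.41 / 0.70 / 0.82), hepatectomy (`resection_rate`),
  intraoperative trial clamping (`f_bloodflow`), dose scans, and scan
  inversion;
* weighted multi-start least-squares calibration of the five hepatic
  transport constants;
* survival classification after partial hepatectomy: the logarithmic
  cirrhosis map `f_cirrhosis = a·ln(b·R15_preop) + c`, model-predicted
  postoperative R15, five support-vector classifiers (Data1A, Data1B,
  Data2, PBPK1, PBPK2) with repeated-split cross-validation, ROC and
  cutoff analysis;
* a seeded synthetic-cohort generator emulating a 141-patient surgical
  cohort (109 survivors / 32 non-survivors) for the classification
  pipeline.

## Worked example

```r
library(icgpbpk)

# 0.5 mg/kg bolus in a healthy 75 kg reference subject
tc <- simulate_icg(times = seq(0, 60, by = 0.1))
pk_parameters(tc)
#> ICG non-compartmental parameters
#>   kel      0.1877 1/min   (PDR 18.77 %/min, R^2 1.0000, window 5-15 min)
#>   t_half    3.692 min
#>   CL       0.6387 l/min   (Vd 3.403 l, AUCinf 58.71 mg min/l, dose 37.5 mg)
#>   R15      0.0405         (4.05 %; cmax 16.20 mg/l)   R20 0.0157
```

A healthy subject clears ICG at ≈ 19 %/min and retains only ≈ 4% of the
peak concentration at 15 min. Increasing cirrhosis severity (shunting +
tissue loss in lockstep) slows elimination:

```r
for (f in ctp_mapping()) {
  pk <- pk_parameters(simulate_icg(scenario = cirrhosis_scenario(f),
                                   times = seq(0, 60, by = 0.1)))
  cat(sprintf("f_cirrhosis %.2f: PDR %5.2f %%/min  R15 %5.1f %%  CL %5.0f ml/min\n",
              f, pk$pdr, pk$r15_percent, pk$cl_ml_per_min))
}
#> f_cirrhosis 0.00: PDR 18.77 %/min  R15   4.0 %  CL   639 ml/min
#> f_cirrhosis 0.41: PDR 10.83 %/min  R15  13.1 %  CL   377 ml/min
#> f_cirrhosis 0.70: PDR  5.39 %/min  R15  29.1 %  CL   191 ml/min
#> f_cirrhosis 0.82: PDR  3.20 %/min  R15  40.3 %  CL   114 ml/min
```

Scanning the cirrhosis degree and fitting the logarithmic map gives the
bridge from a *measured* preoperative R15 back to the model:

```r
scan <- run_scan("f_cirrhosis", seq(0, 0.9, by = 0.05))
map  <- fit_map_coefficients(scan)
map$a                           # identifiable slope of f = a ln(b R15) + c
est  <- estimate_fcirrhosis(0.15, map)   # cirrhosis degree for R15 = 15%
predict_postop_r15(est, resection_rate = 0.5)  # predicted postop R15
```

From there, `generate_cohort()`, `build_features()` and
`evaluate_classifier()` run the full survival-classification comparison,
and `cutoff_scan()` reproduces the cutoff analysis on the predicted
postoperative R15 (balanced accuracy peaks near a 35% cutoff).

A thin command-line front end with `simulate`, `nca`, `scan`, `cohort` and
`classify` subcommands is installed under `inst/cli/icgpbpk.R`.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "icgpbpk", load_package = "installed")'
```

The suite contains unit and property tests per module plus an acceptance
suite covering mass conservation, non-compartmental closed forms,
monotone scenario trends, clamping/resection concordance, parameter
recovery, uncertainty envelopes and the classifier comparison.

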