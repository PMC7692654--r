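# thermokin

Thermal-processing decisions for anthocyanin-rich foods hinge on a small
set of kinetic parameters: how fast the pigment and the antioxidant
activity it carries degrade at each holding temperature, and how
sensitive that rate is to temperature. `thermokin` is an R package for
the full analysis chain of an isothermal degradation study of
anthocyanin extracts (purple maize flour extract is the motivating
system): spectrophotometric quantification, per-temperature first-order
fits, the derived thermal-resistance parameters, and sequential in
vitro digestion analysis. A synthetic-data generator with known ground
truth makes every fitting step testable from scratch.

It is aimed at food scientists and kinetics practitioners who have
time–temperature–response tables (CSV) and want defensible parameter
estimates with standard errors, rather than spreadsheet arithmetic.

## The model

Concentration (or activity) at constant temperature follows first-order
decay,

    C(t) = C0 * exp(-k t),

estimated by ordinary least squares of `ln(C_t / C0)` on time with a
free intercept; `k = -slope`. From `k` follow the decimal reduction
time `D = ln(10)/k`, the half-life `t1/2 = ln(2)/k`, and across
temperatures:

- the **z-value**, the temperature increase producing a 10-fold drop in
  `D`, from the slope of `log10(D)` vs `T` (`z = -1/slope`);
- the **activation energy** `Ea = -slope * R` from the Arrhenius plot
  of `ln k` vs `1/T_K` (`R = 8.314 J mol^-1 K^-1`, `T_K = T_C + 273.15`).

Degradation at a temperature is called significant by a one-sided
t-test on the regression slope (default alpha = 0.05); temperatures
failing the test are reported as thermostable and excluded from the
Ea/z regressions.

Quantification uses the pH-differential method
(`TAC = Abs/(eps L) * MW * DF * V/M * 1000`, cyanidin-3-O-glucoside
constants eps = 26,900 L mol^-1 cm^-1, MW = 449.2 Da) and a linear
DPPH/Trolox calibration. Digestion courses are analysed phase-relative
(gastric and intestinal each rebased to their own t = 0) with explicit
dilution bookkeeping at the 5 mL + 10 mL phase switch, and anthocyanin
loss is correlated with antioxidant-activity loss by Pearson's r.

## Worked example

Simulate a full study (80–180 °C in 10 °C steps, sampling at
0/2/5/7/10/20/30/40 min, triplicates, 5% multiplicative noise, no true
degradation below 120 °C) and summarise it:

```r
library(thermokin)
cfg <- generator_config(noise_cv = 0.05, seed = 1)
sim <- simulate_decay(cfg)
summarize_kinetics(sim$series)
#> Thermal degradation summary
#>   thermostable (no significant degradation): 80, 90, 100, 110 degC
#>   temperature_c k_per_min      k_se d_value_min half_life_min r_squared significant
#> 1           120   0.02296 0.0003828      100.29        30.189    0.9983        TRUE
#> 2           130   0.03523 0.0004025       65.36        19.675    0.9992        TRUE
#> ...
#> 7           180   0.21799 0.0008887       10.56         3.180    0.9999        TRUE
#>   Ea = 55.55 +/- 0.25 kJ/mol (r2 = 1.000)
#>   z  = 61.47 +/- 1.18 degC (r2 = 0.998)
```

The generator's true parameters (Ea = 55.75 kJ/mol, k(120 °C) =
0.0228 min^-1) are recovered within their standard errors, and the four
low temperatures are correctly classified thermostable. A
model-implied retention check on the bundled published antioxidant
table:

```r
t2 <- reference_kinetics("antioxidant")
predicted_retention(t2$k_per_min[t2$temperature_c == 180], 7)
#> [1] 71.2   # i.e. ~29% loss after 7 min at 180 degC
```

A thin CLI wraps the same functions
(`Rscript inst/exec/thermokin.R summary decay.csv --out summary.csv`;
subcommands `quantify`, `fit`, `summary`, `digest`, `simulate`,
`report`).

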