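# bbbfexi

Forward simulation and model fitting for **blood–brain barrier (BBB) water
exchange** measurements with **filter-exchange imaging (FEXI)**.

FEXI is a double diffusion-encoding MRI experiment: a diffusion *filter*
block (b-value *b<sub>f</sub>*) suppresses the fast, flow-driven
intravascular signal; during a mixing time *t<sub>m</sub>* transcapillary
water exchange (total rate *k = k<sub>ie</sub> + k<sub>ei</sub>*, s⁻¹)
recovers the pool populations; an *encoding* block (b-value *b*) reads out
the apparent diffusivity. The recovery of the filtered signal across mixing
times encodes the BBB water permeability. The package is aimed at
quantitative-MRI researchers who want to simulate, fit and stress-test FEXI
protocols before (or instead of) acquiring data.

Three modeling paradigms are implemented, each with three free parameters:

| Paradigm | Signal model | Free parameters |
|---|---|---|
| **AXR**  | `S = S(bf,tm) exp(-b·ADC′(tm))`, `ADC′(tm) = ADC(1 − σ e^(−tm·AXR))` | ADC, σ, AXR |
| **2CM**  | explicit two-compartment exchange, no relaxation | D<sub>e</sub>, D<sub>i</sub>, k |
| **2CMr** | two-site exchange with finite T1/T2 (Bloch–McConnell-type block solution, closed-form 2×2 matrix exponential) | D<sub>e</sub>, D<sub>i</sub>, k<sub>r</sub> |

The compartmental models fix the equilibrium blood signal fraction
(f<sub>i</sub><sup>eq</sup> = 5% grey matter / 3% white matter); 2CMr
additionally fixes the four relaxation times. Fitting is bounded multi-start
Nelder–Mead on group-normalized signals (every measurement divided by the
b = 0 signal of its own (b<sub>f</sub>, t<sub>m</sub>) block). Around the
models sit the protocol tools (`default_scheme()`, `subset_scheme()`,
scheme file IO), the simulation drivers (`relaxation_bias_grid()`,
`sequence_sensitivity_sweep()`, `fixed_param_bias()`,
`accuracy_precision_study()`), a digital phantom generator
(`fexi_phantom()`, `generate_phantom()`), voxel-wise map fitting
(`fit_image()`, `roi_median()`, `estimate_snr()`) and scan–rescan
repeatability statistics (`repeatability()`). See the methods vignette
(`vignettes/bbb-fexi-modeling.Rmd`) for the full model description and
design choices.

## Worked example

```r
library(bbbfexi)

gm <- tissue_preset("gm")        # GM at 3 T: fi_eq=0.05, De=1, Di=10, k=3
equilibrium_adc(gm)              # 1.45 um^2/ms
filter_efficiency(gm, 250)       # 0.276

# Bias from ignoring relaxation: noise-free 2CMr signals at the GM
# relaxation point, fitted with the infinite-relaxation paradigms
relaxation_point_bias("T2", "gm", "axr")   # -27.97  (% error in AXR)
relaxation_point_bias("T2", "gm", "2cm")   # -5.79   (% error in k)

# Monte-Carlo accuracy/precision at SNR 60
st <- accuracy_precision_study(fi_eq = 0.05, k = 3, snr = 60,
                               models = c("axr", "2cm", "2cmr"),
                               n_noise = 50, seed = 1)
st$table
#>   fi_eq k_gt snr model n_noise n_discarded accuracy precision
#> 1  0.05    3  60   axr      50           0   -29.59      1.30
#> 2  0.05    3  60   2cm      50           0    -7.87      1.38
#> 3  0.05    3  60  2cmr      50           0     2.69      1.81
```

Reading: with realistic compartmental relaxation times, the AXR model
underestimates the exchange rate by ~30% (accuracy), though with the
tightest interquartile range (precision); the relaxation-aware 2CMr model
is nearly unbiased. `accuracy` is the percent error of the median retained
estimate after discarding extreme fits (≥ 40 s⁻¹), `precision` the IQR in
s⁻¹.

A thin command-line front end ships in `inst/cli/fexisim.R`
(`simulate`, `fit`, `experiment` subcommands), e.g.

```sh
Rscript inst/cli/fexisim.R simulate --model 2cmr --snr 60 --seed 1 --out signals.csv
Rscript inst/cli/fexisim.R fit --model 2cm --data signals.csv --out fit.csv
```

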