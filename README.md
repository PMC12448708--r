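# acitherm

Photosynthetic capacity and its thermal acclimation, from CO2-response
curves to treatment inference.

`acitherm` is for plant ecophysiologists analysing growth-CO2 ×
growth-temperature experiments on C3 plants. It covers the full chain such
studies use:

1. **A/Ci curve fitting.** Apparent maximum Rubisco carboxylation rate
   (*V*<sub>cmax</sub>) and maximum electron transport rate
   (*J*<sub>max</sub>) are estimated per curve by bounded nonlinear least
   squares on the Farquhar–von Caemmerer–Berry model,

   *A*<sub>c</sub> = *V*<sub>cmax</sub> (*C*<sub>i</sub> − Γ\*) /
   (*C*<sub>i</sub> + *K*<sub>c</sub>(1 + *O*/*K*<sub>o</sub>)) − *R*<sub>L</sub>,
   &nbsp;&nbsp;
   *A*<sub>j</sub> = *J*/4 · (*C*<sub>i</sub> − Γ\*) /
   (*C*<sub>i</sub> + 2Γ\*) − *R*<sub>L</sub>,
   &nbsp;&nbsp;
   *A*<sub>net</sub> = min(*A*<sub>c</sub>, *A*<sub>j</sub>),

   with *J* the lower root of θ*J*² − *J*(α*Q* + *J*<sub>max</sub>) +
   α*Q J*<sub>max</sub> = 0, reproducible QC rules (negative *C*<sub>i</sub>,
   capacities outside [10, 500] µmol m⁻² s⁻¹, poor fits), and extraction of
   the growth-CO2 operating point (*A*<sub>growth</sub>, *g*<sub>s</sub>,
   *C*<sub>i</sub>/*C*<sub>a</sub>).
2. **Thermal responses.** Per tree, the short-term temperature response of
   each capacity is fit with a peaked Arrhenius function (fixed
   *H*<sub>d</sub> = 200 kJ mol⁻¹), yielding *k*<sub>opt</sub>,
   *T*<sub>opt</sub>, *E*<sub>a</sub> and the 20 °C-standardised rates;
   *A*<sub>growth</sub>(*T*<sub>l</sub>) gets a quadratic with closed-form
   optimum *T*<sub>optA</sub> = −*b*/2*a*.
3. **Treatment inference.** Repeated-measures linear mixed models (tree
   random intercepts) and ordinary ANOVA on the derived parameters, with
   AICc-based fixed-effect selection and Tukey post-hoc comparisons with a
   compact letter display.
4. **Synthetic study generation.** A seeded generator reproduces the whole
   design (2 years × 5 boreal species × 6 treatments × trees × 4 leaf
   temperatures × the 12-step CO2 sequence) with known ground truth, so
   parameter recovery and the inference machinery are testable without any
   instrument data. Sensitivity tools (alternative Rubisco kinetics presets,
   cuticular-conductance correction of *C*<sub>i</sub>) round out the
   robustness checks.

See `vignettes/acitherm-methods.Rmd` for the model, the numerical choices
and the generator's scope.

## Worked example

Fit one noisy curve (truth: *V*<sub>cmax</sub> = 62, *J*<sub>max</sub> = 118,
*R*<sub>L</sub> = 1.1) and a four-temperature thermal response:

```r
library(acitherm)
kin <- loadKinetics("tobacco")
kat <- kineticsAt(kin, 25)
ca  <- c(400, 300, 200, 150, 100, 50, 400, 600, 800, 1000, 1500, 2000)
ci  <- 0.72 * ca
set.seed(42)
fm  <- fvcbAnet(62, 118, ci, kc = kat$kc, ko = kat$ko,
                gammastar = kat$gammastar, rl = 1.1)
curve <- data.frame(ci = ci, ca = ca, anet = fm$anet + rnorm(12, 0, 0.5),
                    tleaf = 25, q = 1800, step_index = 1:12)
qcFilter(fitACi(curve), curve)
#> <ACiFit>  n = 12  Tleaf = 25 C
#>   Vcmax =   64.17  Jmax =  121.18  RL =  1.13 (estimated)
#>   SSR = 1.741  R2 = 0.9983  limiting: 6 Ac / 6 Aj
#>   QC: accepted

tl <- c(10, 20, 30, 40)
vc <- peakedArrhenius(85, 308.15, 60000, 2e5, tl + 273.15) * exp(rnorm(4, 0, 0.03))
fitPeaked(tl, vc, "Vcmax")
#> <ThermalResponseFit> Vcmax - peaked_arrhenius
#>   kopt = 85.58  Topt = 35.17 C  Ea = 60692  (Hd fixed 200000)
#>   value at 20 C = 35.81  SSR = 0.1216  n = 4
```

The curve fit lands within ~4% of the generating capacities despite 0.5
µmol m⁻² s⁻¹ of noise, labels each point's limiting process, and passes QC;
the thermal fit recovers the optimum to 0.2 °C. A full study runs through
one call:

```r
res <- runPipeline(studyConfig(seed = 1), outdir = "out")
res$pattern$ec_topta_shift_c   # emergent elevated-CO2 shift of ToptA (deg C)
```

which writes per-stage CSVs (fits, thermal parameters, ANOVA tables shaped
like the familiar publication tables, Tukey letters, QC report) plus a run
log with the seed.

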