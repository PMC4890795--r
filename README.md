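# glycalf

Mechanistic simulation and estimation of postprandial glucose–insulin
dynamics driven by **intermittent gastric emptying**, developed for
milk-fed (pre-ruminant) calves and applicable to other monogastric meal
responses.

## Who this is for

Researchers in animal nutrition and glucose metabolism who want to

* simulate the erratic, multi-peak glycemic response to a liquid meal,
* estimate gastric-emptying pattern and rate from an acetaminophen
  (paracetamol) marker timecourse,
* fit minimal-model glucose/insulin parameters to plasma timecourses, and
* rank which physiological parameters control glucose and insulin
  exposure (AUC).

## The model

Five state masses — stomach/plasma acetaminophen $Ac_S, Ac_P$ (mg),
stomach/plasma glucose $Gl_S, Gl_P$ (mmol), plasma insulin $In_P$ (µg) —
with concentrations given by fixed volumes of distribution (0.9 L/kg for
Ac, 0.251 L/kg for glucose and insulin):

$$\dot{Ac}_S = -k_{SP} Ac_S, \qquad
  \dot{Ac}_P = k_{SP} Ac_S - k_{Ac,UAc} Ac_P,$$

$$\dot{Gl}_P = \underbrace{[k_{SP} Gl_S](t - T_{lag,SP})}_{PGl_{ex}}
   + iPGl_{end}
   - (k_{Gl,UGl} + k_{Is,UGl}\, Is)\, c_{Gl_P},$$

$$\dot{In}_P = \frac{V_{PIn}}{1 + (K_{Gl,PIn}/c_{Gl_P})^{exp_{PIn}}}
   - k_{In,UIn}\, c_{In_P},
  \qquad Is(t) = c_{In_P}(t - T_{lag,IS}).$$

The emptying rate $k_{SP}$ switches per sampling interval between fast
($k_{SP,3}$), slow ($k_{SP,2}$) and zero according to a Z-schedule
classified from marker-concentration slopes (threshold ±0.05 mg L⁻¹
min⁻¹). The system is integrated by fixed-step RK4 (`dt = 0.002` min)
with exact analytic replay of the lagged gastric outflow; two
steady-state constraints pin $k_{In,UIn}$ and $iPGl_{end}$ so the
response starts from a steady pre-meal state. See the methods vignette
(`vignettes/calf-glycemia-model.Rmd`) for assumptions, conventions and
limitations.

## Worked example

```r
library(glycalf)

ref  <- reference_animal()        # 60-kg calf, 2-L milk-replacer meal
traj <- simulate_gi(ref$params, ref$z)

auc(traj, "glucose")              # 2700.6 mM min over 0-420 min
auc(traj, "insulin")              # 469.4  ug/L min
count_peaks(traj, "glucose", tol = 1e-4)   # 3 postprandial waves
max(traj$cGlP_mM)                 # 8.18 mM, at t = 52 min
```

The three glucose (and insulin) peaks mirror the intermittent outflow
schedule; basal glucose is 5.98 mM, so the meal raises exposure by
~190 mM·min above baseline.

Fitting the marker model to a bundled synthetic timecourse (5%
observation noise):

```r
ac  <- read_timecourse(system.file("extdata", "synthetic_calf_ac.csv",
                                   package = "glycalf"), "acetaminophen")
fit_ac(ac, classify_z(ac))
#> <ac_fit> mode = two_rate
#>   k_SP2 = 0.000387071  k_SP3 = 0.00342333  k_Ac_UAc = 0.00165792 /min
#>   rMSPE = 5.59%  (RSS = 4.675)
```

i.e. the classified schedule plus two non-zero rates predicts the
marker curve to within 5.6% of the mean observation.

Parameter sensitivity of the 420-min AUCs (0.5×–1.5× perturbations):

```r
sensitivity_table(ref$params, ref$z)
#> <sensitivity_table> AUC mode: total | k_In_UIn: derived
#>   parameter SC_glucose SC_insulin
#> 1  K_Gl_PIn      1.848      1.233
#> 2   exp_PIn      1.142      0.770
#> 3  k_Is_UGl      0.147      1.360
#> 4  T_lag_IS      0.033      0.090
#> 5      k_SP      0.031      0.623
#> 6     V_PIn      0.014      0.078
#> 7  T_lag_SP      0.003      0.008
#> 8  k_Gl_UGl      0.000      0.000
```

The headline: insulin exposure is ~20× more sensitive than glucose
exposure to gastric-emptying rate (0.623 vs 0.031) — faster emptying
recruits the steep limb of the Hill secretion curve, and the extra
insulin keeps glucose AUC almost unchanged.

The glucose–insulin parameters themselves are fitted by differential
evolution (`fit_gi()`, 80 × 200 generations; minutes on one CPU), and a
command-line interface covers the whole pipeline:

```sh
Rscript -e 'glycalf::run_cli()' synth --meal 2 --bw 60 --noise-cv 0.05 --seed 7 --out-dir obs/
Rscript -e 'glycalf::run_cli()' fit-ac --ac obs/acetaminophen.csv --out acfit.json
Rscript -e 'glycalf::run_cli()' fit-gi --glucose obs/glucose.csv --insulin obs/insulin.csv \
        --ac-fit acfit.json --seed 1 --out gifit.json
Rscript -e 'glycalf::run_cli()' sensitivity --out table2.csv
```

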