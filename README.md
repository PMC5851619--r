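# hobdcs

Microvascular cerebral blood flow (CBF) responses to a head-of-bed (HOB)
orthostatic challenge, measured with diffuse correlation spectroscopy
(DCS), analysed end to end: physics forward model → blood-flow-index
fitting → stage windowing and relative-CBF endpoints → nonparametric
cohort statistics. The package targets researchers in biomedical optics
and sleep medicine who study cerebral vasoreactivity in obstructive sleep
apnea (OSA) — where repeated nocturnal hypoxia is suspected to blunt the
brain's ability to restore its perfusion after a postural challenge — and
anyone who needs a tested, reusable DCS analysis chain.

## What it computes

DCS records the intensity autocorrelation g₂(τ) of near-infrared speckle
(785 nm, source-detector separation ρ = 2.4 cm). The field autocorrelation
of the semi-infinite correlation diffusion model with Brownian dynamics,

    G₁(ρ,τ) ∝ exp(−K(τ)r₁)/r₁ − exp(−K(τ)r₂)/r₂,
    K(τ) = sqrt(3 μa μs′ + 6 μs′² k₀² αDb τ),

is mapped through the Siegert relation g₂ = 1 + β g₁² and fitted to each
measured curve (bounded Levenberg–Marquardt, early-lag restriction for
brain sensitivity), yielding a blood flow index αDb in cm²/s at 3-s
resolution. The HOB protocol — supine → 30° → supine, 5 min per stage,
first/last minute excluded — turns each trace into two endpoints:
rCBF_supine→30° and rCBF_30°→supine, percent changes against the initial
supine baseline. The statistics layer provides Kruskal–Wallis with
Bonferroni-corrected pairwise Wilcoxon tests, signed-rank
recovery-to-baseline tests (exact under ties for n ≤ 25), Spearman
correlation with an exhaustive-permutation option, percentile-bootstrap
median CIs, and a forward-stepwise linear model of recovery against sleep
metrics. A seeded synthetic-cohort generator reproduces the statistical
structure of the three OSA severity groups (14 control / 28 mild / 40
moderate-severe), including the coupling of recovery to mean nocturnal
SpO₂, and stands in for the patient data.

## Worked example

```r
library(hobdcs)

# fit one synthetic curve
props <- optical_properties()          # mua 0.1, musp 10 /cm, n 1.4, 785 nm
geom  <- dcs_geometry()                # rho 2.4 cm
curve <- synth_curve(bfi = 1e-8, beta_coh = 0.5, props, geom,
                     noise = noise_spec(seed = 1))
fit_bfi(curve, props, geom)
#> BFI estimate: 9.877e-09 cm^2/s (beta = 0.501, SSR = 0.00658, 56 lags)

# full study-scale run: simulate 82 subjects, fit every in-window curve,
# window the traces, run the statistics battery
res <- full_pipeline(run_config(seed = 1))
res
#> HOB-DCS pipeline result (seed 1, 82 subjects)
#>   supine->30 median: -19.3% (95% CI -20.7, -17.0)
#>   moderate/severe 30->supine median: +9.3%
#>   stepwise (all): mean_spo2
res$report$stepwise_all$coefficients$mean_spo2
#> [1] -2.158293
```

Read: the cohort loses ~19% of its baseline flow when tilted to 30°; the
moderate/severe group is still ~9% above its own supine baseline after
tilting back (failed recovery); and the stepwise model retains mean
nocturnal SpO₂ as the only predictor of that residual offset, at roughly
−2 percent rCBF per percent SpO₂.

A thin command-line front end wraps the same functions:

```sh
Rscript scripts/hobdcs.R simulate-cohort --preset paper-effects --n 14,28,40 --seed 1 --out cohort/
Rscript scripts/hobdcs.R full-run --seed 1 --out run1/
```

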