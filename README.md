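# catrace

Autonomous characterization of dynamic parameters in single-cell
fluorescence time series — typically fura-2 ratiometric calcium
recordings, but any trace with a transient and/or oscillatory response
works.

Real recordings mix the signal of interest with slow baseline drift,
Gaussian instrument noise and intermittent high-amplitude noise spikes.
`catrace` decomposes each trace into these parts and reports, per
recording:

* **Transient response (TR):** time of onset *t*<sub>onset</sub>, 10–90%
  rise time, amplitude, area under the curve (AUC), full width at half
  maximum (FWHM), and the decay constant τ<sub>decay</sub> of the
  mono-exponential tail after the deactivation inflection
  ρ = *t*<sub>de</sub> + γ((*n*−1)/(*n*+1))<sup>1/*n*</sup>.
* **Multi-peaked response (MPR):** number of peaks *N*<sub>osc</sub>,
  mean peak magnitude *E*, mean period *T* and its standard deviation
  σ<sub>*T*</sub>, oscillatory persistence, and duty cycle
  ξ<sup>peak</sup>/*T* — once for **all** detected peaks and once for the
  **coherent** subset (peaks with mutually consistent period and width,
  identified by Gaussian-mixture clustering with a gap-statistic model
  choice), so stochastic discharges can be told apart from deterministic
  oscillations.

Under the hood: derivative estimation by iteratively reweighted
total-variation regularization with data-driven parameters and noise-spike
rejection; drift modelled as saturating-exponential + linear components in
up to two epochs; the transient fitted as a Hill-type activation and
deactivation joined by a C1 cubic Hermite spline, with every stage's
optimum feeding the next stage's initial guess. The model pieces are

    g_act(t) = A_act t^n/(t^n + beta^n) + m_act * Int_0^t x^n/(x^n+beta^n) dx
    g_de(t)  = A_de gamma^n/(t^n + gamma^n) + m_de * Int_0^t gamma^n/(x^n+gamma^n) dx
    D(t)     = a1 (1 - exp(-t/tau1)) + m1 t  [+ second epoch from t2] + z

with `m_de` fixed in closed form so the response returns to zero by the
end of the recording.

See the methods vignette (`vignettes/catrace-methods.Rmd`) for the full
model, the detection criteria, every tunable parameter, and known
limitations.

## Worked example

```r
library(catrace)

# a synthetic 2 Hz, 120 s fura-2-like recording with known ground truth
sim <- generate_trace(fixture_spec(seed = 7))
fit <- characterize_trace(sim$trace)
fit
#> <trace_fit> sim_seed7
#>   detected: TRUE  criteria: 111
#>   t_onset 11.50 s | rise 10-90% 5.27 s | amplitude 0.478 | AUC 10.65 | FWHM 18.33 s | tau 14.14 s
```

`detected: TRUE` with `criteria: 111` means all three detection criteria
passed (a significant derivative maximum exists; the drift lies at least
4σ₋ below the data estimate for six or more samples; the drift-corrected
signal returns toward baseline). The trace was generated with onset at
11 s, amplitude 0.483 and AUC 11.8, so the fitted onset (11.5 s),
amplitude (0.478) and AUC (10.65) recover the truth to within a few
percent at signal-to-noise 20.

Everything is a tibble one pipe away:

```r
glance(fit)      # one row: detection verdict + all 12 parameters + flags
tidy(fit)        # long parameter table (transient / oscillation / drift / noise)
autoplot(fit)    # data, TV estimate, drift and fitted model overlaid

# batch: column 1 = time, each further column one ROI; xlsx or csv
report <- characterize_document("recordings.xlsx", plots = "figs")
write_results(report, "results.csv")
```

Method comparison uses the same machinery the package applies to itself:

```r
ba <- bland_altman(manual_estimates, automated_estimates)
ba
#> <catrace_agreement> n = 2
#>   mean % difference: 3.83%  [95% LoA -35.96%, 43.62%]
#>   slope: 0.600   r^2: 1.000
autoplot(ba)     # percent difference vs Z-score with limits of agreement
```

A thin command-line wrapper lives in `inst/cli/catrace.R`:

```sh
Rscript inst/cli/catrace.R characterize input.xlsx --seed 1 --out results.csv
Rscript inst/cli/catrace.R simulate --seed 3 --osc --out sim.csv
Rscript inst/cli/catrace.R agree manual.csv auto.csv
```

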