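# gcshutdown

Stochastic, lattice-based agent simulation of the germinal center (GC)
reaction, built to ask a single question: **which late-acting processes
can, on their own, terminate a GC?** The package is aimed at computational
immunologists studying affinity maturation, GC lifetime and antibody
feedback, and at modelers who want a compact, reproducible GC engine with
pluggable shutdown mechanisms and matched controls.

## The model in brief

A GC sphere (radius 160 µm, 5 µm lattice) is split into dark and light
zones by static CXCL12/CXCL13 gradients. Founder B cells arrive at 2
cells/h for 4 days, divide six times in the dark zone (mutating a
4-dimensional shape-space receptor with probability 0.5 per daughter;
affinity is Gaussian in shape distance), then collect antigen from
follicular dendritic cells (FDCs; 200 cells, 3000 antigen portions each)
for 0.7 h and compete for T follicular helper (Tfh) signals for 3 h.
Selection requires an integrated signal of 0.5 h; selected cells recycle
with a division number given by a Hill program,

    n_div(x) = n_min + (n_max − n_min) · xⁿ / (xⁿ + Kⁿ),   n = 2, n_min = 1, n_max = 6,

where x is captured antigen p or integrated Tfh signal T_sig depending on
the assumption set (A1–A4), and the Tfh intensity is constant (J = 1) or
J(p) = 3 p²/(p² + 7.1²). 72% of antigen-carrying divisions asymmetrically
hand all antigen to a daughter that exits as an output cell; exiting cells
become plasma cells (half-life 24 h) secreting 3×10⁻¹⁸ mol/h of antibody
into 11 affinity bins (K_D from 10⁻⁵·⁵ to 10⁻⁹·⁵ M, decay ln2/14 d⁻¹,
volume 10 ml).

Seven shutdown mechanisms can be switched on one at a time, each with a
neutral ("control") parameter value: antigen consumption (M1), antibody
feedback masking FDC antigen (M2), FDC dendrite contraction (M3),
immune-complex cycling modulation (M4), decaying Tfh signaling capacity
(M5), terminal differentiation (M6, antigen-, signal- or time-dependent),
and division-capacity exhaustion with DZ–LZ cycling (M7). Diagnostic
readouts (pMHC density of selected cells, uptake success fraction, FDC
network size per B cell, surface antigen fraction, recycling and output
fractions) and an ELISA-like "immune power" statistic,
IP = Σᵢ Aᵢ/(Kᵢ + R) at R = 10⁻⁵ M, discriminate the mechanisms.

## Worked example

```r
library(gcshutdown)

cfg <- gc_scaled_config("M5", "A1")     # Tfh capacity decays, K_T = 600 h
run <- gc_simulate(cfg, seed = 1)
print(run)
#> <gc_run> mechanism M5, assumption A1, seed 1
#>   duration: 21 days (505 hourly rows)
#>   GC volume: peak 3541 cells at day 4.9; final 250
#>   output cells exited: 4231; plasma cells: 4183

ctl <- gc_simulate(gc_scaled_config("control", "A1"), seed = 1)
print(ctl)
#> <gc_run> mechanism control, assumption A1, seed 1
#>   duration: 21 days (505 hourly rows)
#>   GC volume: peak 4199 cells at day 4.9; final 3370

ip_fold_change(run$timeseries$immune_power[505],
               ctl$timeseries$immune_power[505])
#> [1] 0.7318563
```

The control GC peaks around day 5 and persists to day 21, while the same
GC with decaying Tfh signaling contracts to under a tenth of the control —
and produces antibody with a ~0.73-fold immune power, i.e. this way of
ending a GC is costly. `gc_replicates()` wraps the 50-replicate
mean-and-SD protocol; `plot(reps, "volume")` draws the familiar
mean ± SD kinetics; `gc_readouts()`, `gc_peak()`, `normalize_readouts()`
and `compare_timepoints()` implement the diagnostic analyses. A thin
command-line wrapper lives at `inst/cli/gcsim.R`
(`run` / `sweep` / `summarize`).

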