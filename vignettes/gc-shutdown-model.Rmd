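---
title: "An agent-based model of germinal center shutdown"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of germinal center shutdown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcshutdown)
```

## The model

`gcshutdown` simulates a single germinal center (GC) reaction as a
stochastic agent-based system on a three-dimensional discrete lattice and
asks which late-acting processes can, on their own, drive the reaction to
contract ("shutdown"). The GC sphere is split into a dark zone (DZ) and a
light zone (LZ) by static, monotone CXCL12/CXCL13 chemokine gradients along
one axis; motile B cells perform a persistent random walk biased up the
gradient that matches their current state. The LZ hosts two stromal/helper
populations: follicular dendritic cells (FDCs), each a soma with six
axis-aligned dendrites whose occupied lattice sites hold antigen portions,
and T follicular helper (Tfh) cells.

B cells traverse a five-state life cycle:

1. **DZ B cell** — divides `divisions_left` times (founders: 6), each
   daughter mutating its B cell receptor (BCR) with probability 0.5.
   Mutation is a unit step in one dimension of a 4-dimensional discrete
   shape space; affinity to the (single or dual) optimal epitope is
   Gaussian in shape-space distance, $a = e^{-(d/\Gamma)^2}$.
2. **Unselected** — on reaching the LZ the cell opens a 0.7 h antigen
   collection window. Whenever it stands on an FDC-held site and at least
   0.02 h have passed since its last collection event, it attempts uptake;
   an attempt succeeds with probability $a \cdot \min(1, G/G_0)$, where $G$
   is the free (surface, unmasked) antigen at the site and $G_0$ the
   pristine per-site load of a fully grown FDC. Success increments the
   cell's captured-antigen count $p$ (its pMHC density). Cells ending the
   window with $p = 0$ die.
3. **FDC-selected** — the cell seeks Tfh help for 3 h. Contacts last 6 min;
   a Tfh bound by several B cells polarizes toward the one with the highest
   $p$ (persistently, re-polarizing only when its target is lost or
   out-competed; ties are resolved uniformly at random). While polarized
   the cell integrates signal $T_{sig}$ at rate $T_{max}(t)\, J$, with
   $J = 1$ or the Hill law in $p$ below depending on the assumption set.
   Cells reaching $T_{sig} \ge 0.5$ h by the end of the window are
   **Selected**; the rest die.
4. **Selected** — with probability $F$ (zero except under terminal
   differentiation, M6) the cell leaves as an output cell; otherwise it
   recycles to the DZ with a number of divisions set by the division
   program below, evaluated at selection.
5. **Output** — exits the GC chemotactically; exiting cells differentiate
   into antibody-secreting plasma cells with a 24 h half-life.

Founder B cells arrive as a Poisson stream of 2 cells/h for the first
4 days, drawn uniformly from shape points at distance 2–5 from the optimal
epitope. 72% of divisions of antigen-carrying cells are asymmetric: one
daughter inherits all captured antigen and leaves immediately as an output
cell; symmetric divisions split $p$ evenly.

### Division program and Tfh signal intensity

The number of divisions a recycling cell earns is a Hill function of either
its captured antigen $p$ (assumption sets A1/A2) or its integrated Tfh
signal $T_{sig}$ (A3/A4):

$$ n_{div}(x) = n_{min} + (n_{max}-n_{min}) \frac{x^n}{x^n + K^n},
   \qquad n_{min}=1,\; n_{max}=6,\; n = 2, $$

rounded stochastically (floor plus a Bernoulli draw on the fraction, which
preserves the Hill mean; nearest-integer rounding is available). The Tfh
signal intensity is either constant ($J = 1$; A1/A3) or pMHC-dependent
(A2/A4):

$$ J(p) = J_{min} + (J_{max}-J_{min})\frac{p^2}{p^2 + K_p^2},
   \qquad J_{min}=0,\; J_{max}=3,\; K_p = 7.1 .$$

The baseline half-effect constant $K$ equals the per-assumption
$K_{min}$ (1, 1, 0.5, 0 for A1–A4). Because the Tfh polarizes to the
highest-$p$ cell even when $J = 1$, selection retains an indirect pMHC
dependence under every assumption set.

### Shutdown mechanisms

Exactly one mechanism is active per run; each mechanism's control is the
same configuration with the strength parameter at its neutral value, and the
global control (no mechanism, consumption neglected) does not terminate.

| id | process | law / knob | neutral value |
|----|---------|-----------|---------------|
| M1 | antigen consumption | each successful encounter removes `portions_per_encounter` from the site ledger | 0 |
| M2 | antibody feedback | masking $dC_i/dt = k_{on} G N A_i - k_{off,i} C_i$ | $N=0$ |
| M3 | FDC contraction | dendrites grow 0.166 µm/h from 5 µm until day 7, then shrink at $k_c$, back to the 5 µm stubs | $k_c=0$ |
| M4 | IC cycling | $dA_{surf}/dt = k_{ext}(t)(A_{tot}-A_{surf}) - k_{int}A_{surf}$ with $k_{ext}(t)=k_{ext}(0)(1-\frac{t^2}{t^2+K_{ext}^2})$ | $K_{ext}=\infty$ |
| M5 | Tfh capacity | $T_{max}(t)=T_{max}(0)(1-\frac{t^2}{t^2+K_T^2})$ | $K_T=\infty$ |
| M6 | terminal differentiation | $F = X^2/(X^2+K_F^2)$ for $X=p$ (M6a) or $T_{sig}$ (M6b); $F = 1-e^{-kt}$ (M6c) | $F=0$ |
| M7 | division capacity | $K(N_{cyc}) = K_{min} + (K_{max}-K_{min})\frac{N_{cyc}^2}{N_{cyc}^2+K_K^2}$ | $K_K=\infty$ |

Antibody produced by plasma cells is tracked in 11 affinity bins sharing
$k_{on} = 10^6\, \mathrm{M^{-1}h^{-1}}$ with dissociation constants
log-uniform over $10^{-5.5}$–$10^{-9.5}$ M; each bin follows
$dA_i/dt = (k_1/V)\, n_{p,i} - k_2 A_i$ with
$k_1 = 3\times10^{-18}$ mol/h/cell, $k_2 = \ln 2 / 14\ \mathrm{day^{-1}}$
and $V = 10$ ml. An exiting cell's affinity is mapped log-linearly onto the
$K_D$ range to pick its bin. The efficiency of the reaction is summarized
by the immune power at day 21,
$IP = \sum_i A_i R / (K_i + R) / R$ at test antigen concentration
$R = 10^{-5}$ M, reported as fold change over the control run.

## Design choices in the open parts of the model

The cited processes fix rates, windows and thresholds, but a cell-resolved
implementation needs additional rules. The ones that matter, with the
package's defaults:

* **Geometry and motility.** Radius 160 µm at 5 µm spacing (one cell
  diameter); B cell speed 7.5 µm/min as a persistent biased walk
  (persistence is implemented as a per-move probability 0.3 of redrawing
  the direction; the chemotactic bias 0.9 applies when a direction is
  redrawn and only while the cell is outside its target zone). Output
  cells drift toward the LZ pole and are removed at the boundary.
* **Clocks.** The lattice step is 0.002 h (1/150 h in the scaled profile),
  chosen to resolve the 0.02 h minimum between collection events; the
  collection window starts when an Unselected cell first enters the LZ, so
  DZ-to-LZ transit does not consume it.
* **Availability-scaled uptake.** Success probability is affinity times
  $\min(1, G/G_0)$. This makes masked, internalized or consumed antigen
  reduce capture smoothly, while FDC contraction (which concentrates the
  conserved antigen on fewer sites) reduces the number of encounters
  without lowering per-encounter success — reproducing the diagnostic
  separation between the two classes of antigen limitation. A capture
  increments $p$ by one unit; the M1 knob controls how much is removed
  from the FDC ledger.
* **Tfh search time.** After each 6-min contact a B cell spends 0.1 h
  (`rebind_delay_h`) scanning before it can bind again. This bounds the
  signal a perfectly successful cell can integrate in one 3 h window at
  roughly $1.2\,T_{max}(0)$ — selection is attainable but not saturated,
  which is what lets a declining $T_{max}(t)$ (M5) terminate the reaction.
  $T_{max}(0) = 1$ so that thresholds are in literal polarized-hours.
* **Dendrite discretization.** An arm of length $L$ occupies
  $\lfloor L/5\,\mu m \rfloor$ sites beyond the soma along its axis;
  contraction under M3 ends at the initial 5 µm stubs (the pre-growth
  morphology) rather than at bare somata, and every geometry change
  redistributes each FDC's conserved antigen equally over its current
  sites.
* **Masking and cycling as occupancy fractions.** The masking ODE (per
  antibody bin) and the surface/interior cycling ODE are integrated as
  network-wide occupancy fractions applied to the per-site antigen totals
  (a mean-field treatment within the FDC network). This keeps the ledger
  conservation *free + masked + interior + consumed = initial* exact. Both
  ODEs, and the antibody ODE, use piecewise-exponential updates that are
  exact for frozen coefficients, with substeps guarding the time-varying
  rates.
* **Calibration of the founder repertoire.** Founders are drawn at
  shape-space distance 2–5 from the optimum with $\Gamma = 2.8$. The lower
  edge matters: under the pMHC-dependent signal law (A2/A4), cells need
  $p \gtrsim 2$ for selection, so founder affinities of order
  $10^{-1}$–$10^{-2}$ are required for the control reaction to establish
  itself under all four assumption sets. This band was fixed once, before
  the mechanism analyses.
* **Death rules.** Cells die only by failing collection or failing the Tfh
  threshold; divisions are deferred (not lost) when no neighboring site is
  free.

## What stabilizes the control reaction

With consumption neglected, the control GC grows until Tfh help saturates:
most Tfh polarization time is consumed by cells that ultimately fail, and
the selection throughput (hence the recycling influx into the DZ) plateaus.
The standing population is then roughly *selection throughput x division
tree size*. This buffering has a consequence worth stating explicitly:
mechanisms that act by lowering the number of divisions of cells that are
still selected (M3 under A1 in particular) shift the equilibrium by a
factor of about $2^{\Delta n_{div}}$, and because any selected cell has
$p \ge 1$ and hence $n_{div} \ge 3.5$ at $K = 1$, the attainable
suppression from antigen scarcity alone is bounded near
$2^{-2.4} \approx 0.19$ of control; observed day-21 volumes for M3 under
A1 settle around half the control rather than collapsing. Mechanisms that
attack survival (M1, M2, M4 through failed collection; M5 through the
signal threshold), the recycling fraction (M6c) or the division program
directly (M7, whose $K$ can exceed any $p$) escape this bound and
terminate the reaction.

The same buffering shapes the immune-power comparisons. With selection
throughput pinned at the Tfh capacity, the control and the
terminal-differentiation/division-capacity runs produce output cells at
comparable rates while both persist, so a quantity advantage for the
shutdown mechanisms cannot arise; and because the calibrated founder
repertoire matures to near-optimal affinity within about a week in every
run, the output-quality channel (faster cycling concentrating output in
higher-affinity antibody bins) is saturated as well. In this
implementation the immune-power fold change versus control is therefore
below one for the Tfh-capacity mechanism (clearly so) and near or below
one for terminal differentiation and division-capacity exhaustion, rather
than above one; the diagnostic trend readouts, not the efficiency
statistic, are what separate these mechanisms here.

## Scaled profile and problem sizes

The replicate suites use `gc_scaled_config()`: radius 90 µm with 36 FDCs
and 36 Tfh (preserving the full-size system's FDC site coverage of the LZ,
~14%, and its Tfh-limited selection regime), timestep 1/150 h, and the
antibody dilution volume scaled with the system (1.8 ml) so the feedback
coupling per unit of GC output is unchanged. Suites run 21 simulated days;
mechanism-versus-control comparisons use 20 replicates for the diagnostic
trend tests and 5 replicates for the qualitative shutdown checks, with
replicate seeds derived deterministically from one master seed. The
full-size default configuration is used for the parameter-behavior checks
(agent counts, antigen loads, influx, division and mutation statistics) on
shorter horizons.

## What the synthetic runs do and do not show

The simulation reproduces the *relative, qualitative* signatures of the
candidate shutdown processes — which readouts decline after the volume
peak under which mechanism — under a single idealized antigen, static
chemokine fields, a fixed Tfh pool and hard-coded windows. It does not
emulate measurement noise, staining efficiency, GC-to-GC heterogeneity
within a lymph node, antigen re-deposition, or Tfh/Tfr population
dynamics; passing suites therefore support the internal logic of the
mechanism diagnostics, not quantitative predictions for any particular
immunization. Absolute cell counts depend on the calibration knobs listed
above; all mechanism comparisons are run against matched controls at
identical settings.

## A short example

```{r example, eval = FALSE}
cfg <- gc_scaled_config("M5", "A1", K_T = 600)
run <- gc_simulate(cfg, seed = 1)
print(run)
plot(run, "volume")

reps <- gc_replicates(gc_scaled_config("control", "A1"), n = 5, seed = 1)
print(reps)
```
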