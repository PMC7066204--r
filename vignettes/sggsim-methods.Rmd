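---
title: "Modelling self-generated chemoattractant gradients with sggsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-generated chemoattractant gradients with sggsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sggsim)
```

## The model

sggsim couples a continuum attractant field to discrete cell agents.

**Field.** The attractant lives on a uniform square lattice (spacing
$\Delta x$, concentration in nM) and diffuses by the 2D heat equation
$\partial c/\partial t = D \nabla^2 c$ with no-flux outer borders.
Designated lattice nodes can be pinned at their initial concentration,
turning them into infinite reservoirs or sinks; imposed-gradient chambers
are built from a 0 nM strip at the cell end and a high-concentration strip at
the far end, while self-generated scenarios use no pinned nodes at all - the
attractant is finite, and any gradient has to be carved out of it by the
cells.

**Receptors.** A cell senses the nearest node's concentration through the
single-site binding isotherm $y = c/(c + K_d)$ with $K_d = 12$ nM, a typical
affinity for small-molecule attractant receptors. Everything a cell does -
steering, enzyme induction, division - is driven by receptor occupancy, not
raw concentration. This is the mechanistic heart of the package: at
saturating concentrations a steep concentration gradient produces almost no
occupancy difference across a cell, so guidance fails from above as well as
from below.

**Motility.** Cells move at constant speed (10 um/min, a vegetative
*Dictyostelium* scale) and reorient every 5 s. A proposed heading is drawn
from a wrapped normal distribution centred on the current heading
($\sigma = 0.6$ rad; sampled as a normal reduced mod $2\pi$, accurate for
$\sigma \lesssim 1.5$); a bias vector along the local *occupancy* gradient
is added to the unit persistence vector, and the summed vector's angle
becomes the new heading. The occupancy gradient is a least-squares plane fit
over the grid nodes within 6 um of the centroid (the same node set used for
degradation), so a cell's directional information comes only from the patch
of substrate it touches.

**Steering gain.** The bias magnitude is
$b = b_{\max}\,\min(|\nabla y| / g_s,\, 1)$ with $b_{\max} = 3$ and
$g_s = 10^{-3}\,\mu m^{-1}$ by default, and steering is suppressed entirely
when the mean occupancy over the overlapped patch falls below a floor
$y_{\min}$: a cell with almost no bound receptors has no directional
information, however steep the *relative* gradient. The floor is the
model's deterministic stand-in for receptor counting noise - without it the
occupancy gradient's sensitivity diverges as $c \to 0$ (because
$dy/dc \to 1/K_d$), and a degrading cell could steer on arbitrarily faint
traces of the attractant it has just destroyed. Two properties motivated
the saturating-ramp form. First, a
persistent random walker integrates bias over many reorientations, so even
$b \approx 0.2$ yields a chemotactic index above 0.5; a linear ramp with a
hard saturation gives the sharp transition between "legible" and
"illegible" gradients that saturable receptors show in experiments. Second,
the saturation cap means a steeper-than-necessary gradient cannot push cells
harder - exactly the behaviour that makes self-generated waves travel at
cell speed rather than at gradient-sharpening speed. $g_s$ corresponds to a
1% occupancy difference across a 10 um cell; it was calibrated jointly with
$b_{\max}$ so that an imposed 0-300 nM gradient over 1 mm is followed
efficiently while 0-3 uM is mostly illegible (the imposed-gradient
saturation series). The parameter table below lists the per-attractant
values.

**Degradation.** A cell removes attractant from its overlapped nodes at the
Michaelis-Menten rate $r = V_{\max} c/(c + K_m)$, computed from the mean
concentration over the patch and split evenly across its nodes (clamped at
zero; all removals are tallied so mass is exactly accounted for). When
degradation is *induced*, $V_{\max}$ is multiplied by the Hill factor
$v_b + (1 - v_b)\, y_\mu^h / (k_i^h + y_\mu^h)$ of the trailing one-minute
mean occupancy $y_\mu$, with $v_b = 0.05$, $k_i = 0.4$, $h = 2$: a
switch-like enzyme induction with a 5% basal leak.

**Mitosis.** When the attractant is also a mitogen, the division *rate*
interpolates linearly from 0 at a trailing occupancy of 0.35 to 1/min at
occupancy 1, so the expected waiting time is infinite at the floor and
exactly 1 min at full occupancy; rate-linear interpolation is the unique
two-point choice with no extra parameters. Division is a Poisson event per
tick. Both mother and daughter have their occupancy window zeroed, which
keeps their division rate at zero until the one-minute window refills - the
refractory period is emergent rather than an explicit timer.

## Numerics

The diffusion solver is the DuFort-Frankel leapfrog
$$u^{n+1}_{ij} = \frac{(1-4\alpha)u^{n-1}_{ij} + 2\alpha\,(N+S+E+W)}
{1+4\alpha}, \qquad \alpha = \frac{D\,\Delta t}{\Delta x^2},$$
with zero-flux ghost nodes equal to the centre value (the finite-volume
convention, which conserves mass exactly) and pinned nodes re-imposed on
both time levels after every sweep. The engine picks the largest sub-step
with $\alpha \le 0.75$ that divides the 1 s agent tick evenly; the two-level
scheme is bootstrapped by forward-Euler sub-steps at or below the FTCS
stability limit.

Two numerical details are worth knowing about:

* **Computational mode.** Leapfrog schemes decouple the space-time-parity
  sublattices; rough data (a point load, or the sharp local sink a cell
  makes) excites a neutral checkerboard mode that never decays. Each sweep
  therefore applies a Robert-Asselin-Williams time filter
  ($\nu = 0.1$, $\alpha_W = 0.53$). The plain Robert-Asselin form is
  *unstable* in combination with DuFort-Frankel for $\alpha > 1/4$ (the
  checkerboard eigenvalue leaves the unit circle - easily verified from the
  2x2 amplification matrix), while the Williams variant damps the
  computational mode at every wavenumber, leaves smooth solutions
  essentially untouched, and conserves mass exactly.
* **Degradation and the two time levels.** Cell sinks decrement *both* time
  levels identically. Decrementing only the current level lets the leapfrog
  weights amplify the removed mass by $(1+w_1)^{-1}$ with
  $w_1 = (1-4\alpha)/(1+4\alpha)$, silently breaking the mass-balance
  identity (initial mass - final mass = cumulative degraded) that the test
  suite checks to $10^{-6}$.

Cells are updated in stable id order after the field sub-steps of each tick
(sense, degrade, reorient, move, divide); daughters join at the end of the
array and first act on the next tick. All randomness flows through R's
global RNG, so `set.seed()` - or the scenario's `seed` field - makes runs
bit-reproducible; window means are recomputed from the buffer rather than
tracked incrementally so that results cannot depend on how a run is chunked.

## Calibrated parameters

The printed kinetic parameters ($K_d$, $v_b$, $k_i$, $h$, the mitogen floor
and 1-min division time, the 6 um overlap) are used as given. Parameters the
underlying experimental system does not pin down were fixed once, by
calibration against the qualitative behaviours the assays must show, and are
then shared by every scenario:

| parameter | value | units | role |
|---|---|---|---|
| `D` | 150 | um^2/s | attractant diffusivity (small molecule in agarose) |
| `dx` | 4 (bridges), 6 (large arenas) | um | lattice spacing |
| field sub-step | $\alpha \le 0.75$ | - | accuracy-driven, not stability-driven |
| `speed` | 10 | um/min | vegetative *Dictyostelium* scale |
| `sigma` | 0.6 | rad | persistence of the random walk |
| `reorientation_interval` | 5 | s | direction update cadence |
| `bias_strength` | 3 | - | saturated steering bias |
| `sensing_scale` | 1e-3 (5e-4 two-spot) | 1/um | occupancy gradient at which steering saturates |
| `steering_floor` | 0.005 (0.15 two-spot) | - | minimum patch occupancy for steering |
| `vmax` | 6e6 | nM um^2/min | per-cell maximal degradation |
| `km` | 1500 | nM | Michaelis constant of degradation |

The two-spot scenario models a different attractant (cAMP) from the
bridge, population and disc-well scenarios (folate), so it carries its own
diffusivity (100 um^2/s) and receptor characteristics: a lower steering
saturation scale and a much higher occupancy floor. The floor is what
removes the low end of the constitutively degrading cells' dynamic range -
they destroy the weak 1 uM signal before enough receptors are ever
occupied - while cells whose enzymes must first be induced retain it.
Bridge-wave cells, by contrast, legitimately ride the deeply depleted edge
of their self-generated folate gradient at 1-2% occupancy, which is why
the folate floor is nominal.

$V_{\max}$ and $K_m$ deserve comment, because the two ends of the
concentration ladder pull them in opposite directions. If the *low*-end
degradation rate is too high, a small wave vaporises the attractant faster
than cells can follow and loses its own gradient; if the *saturated* rate is
too low, the population cannot beat the diffusive influx at 30-100 uM and
never forms a wave. The ratio of those two rates is set by $K_m$: with
$K_m = 1.5$ uM the rate at 30 nM is ~2% of $V_{\max}$ while the rate at
30 uM is ~95%, which lets one $(V_{\max}, K_m)$ pair keep the self-generated
response score flat across three orders of magnitude of attractant.

## The four assays

* **Bridge** (`build_bridge()`): a 1 mm x 200 um channel. Imposed mode pins
  source/sink strips and, by default, starts from the steady linear ramp
  (`field$prefill = "steady"`), emulating a pre-equilibrated chamber - at
  D = 150 um^2/s a 1 mm gradient takes ~30 min to form, which would eat the
  1 h scoring window; `prefill = "empty"` restores the forming-gradient
  variant. Self mode fills the channel and two finite 1 mm reservoir
  regions uniformly. Scored by the response score (fraction of seeded cells
  whose x-displacement from their own start exceeds 400 um at 1 h), the
  time for n cells to reach the far end, and the mean distance of the 10
  leading cells.
* **Population scan** (`build_population_scan()`): the self-generated bridge
  over a series of cell counts; the derived control parameter is the total
  $V_{\max}$ (count x per-cell $V_{\max}$).
* **Disc well** (`build_disc_well()`): cells seeded in a central disc in a
  uniform background; the wave is scored by the mean radial displacement of
  the leading cells. This is the geometry where the mitogen matters: the
  expanding front dilutes the population until the attractant influx
  overwhelms it, unless saturated cells divide.
* **Two-spot** (`build_two_spot()`): equal 400 um-radius discs of cells
  (100 of them) and attractant, centres 1000 um apart, no pinned nodes, in
  a 3200 x 1600 um arena, scored at 2 h. A run is positive when at least
  twice as many cells lie in the attractant-facing half (relative to the
  original drop centre) as in the far half. The "500 nl drop" of the bench
  assay maps to the 400 um disc footprint; the centre distance follows the
  ~500 um spot separation.

## What the generator does and does not emulate

Synthetic runs reproduce the *mechanisms* - receptor saturation, collective
degradation, delay-then-respond dynamics, mitogenic rescue, induced-enzyme
range extension - under idealised conditions: a 2D substrate, uniform
motility, no receptor noise, no cell-cell exclusion, no attractant loss
into the third dimension. Passing tests therefore demonstrate that the
model produces these behaviours, not that real cells are quantitatively
matched; the bench versions of these assays live in thicker agar, with
noisy, adhering, variably sized cells. The known consequence visible in our
own results is that simulated dynamic ranges are narrower than the six
orders of magnitude real two-spot assays can show.

## Problem sizes in the test suite

The acceptance-style tests run scaled-down study conditions chosen to keep
the full suite in the tens of minutes: 100-cell bridges (10-seed means for
the imposed saturation series, 2 seeds elsewhere), a 300 um well in place
of the 1 mm one, capped mitogenic populations, and 3-replicate two-spot
majorities probed from the ends of the concentration ladder (the positive
range is contiguous). The acceptance script runs the full 5-replicate,
6-concentration, 3-logic two-spot grid. Scaling up the replicate counts
tightens the stochastic bands but does not change any qualitative
outcome.

## Known limitations

* The DuFort-Frankel + RAW combination is robust but first-order in time
  near rough features; very sharp initial conditions briefly clamp small
  negative undershoots (tracked in `clamped_mass`, typically <1e-3 of the
  degraded mass).
* `sample_concentration()` is nearest-node by design (cells interact with
  discrete grid points); positions are never interpolated, so scores can
  shift by up to one lattice increment.
* Reflecting walls slightly enrich cell density at boundaries over long
  runs; arenas are padded so walls stay far from the action.
* With a mitogenic attractant and a saturating background the population
  grows exponentially until degradation catches up; the scenario field
  `max_cells` (default 20000) caps runaway growth, visible as a population
  that plateaus exactly at the cap.
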