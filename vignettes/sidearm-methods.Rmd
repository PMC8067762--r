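---
title: "Viscoelastic characterization of neurofilament sidearms: models and methods"
author: "sidearm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic characterization of neurofilament sidearms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidearm)
```

## The problem

Neurofilaments (NFs) are intermediate filaments of the axonal cytoskeleton.
Their intrinsically disordered C-terminal projections — the *sidearms* — set
the spacing between filaments and, at the strain rates relevant to traumatic
brain injury (nominal pulling rates of $10^8$–$10^9\,\mathrm{s^{-1}}$),
dominate the filament's tensile and relaxation response. Steered-pulling
molecular dynamics produces two kinds of raw output for this problem:

1. **per-atom trajectory frames** carrying coordinates and per-atom
   stress$\cdot$volume virial tensors, from which group stress and
   engineering strain must be extracted, and
2. **relaxation records**: the time-dependent modulus $E(t)$ after the
   sidearm is stretched to a constant hold strain (here
   $\varepsilon_0 = 0.8$, an 80 % stretch) and held for about 1 ns.

`sidearm` implements the post-processing chain only — extraction, curve
building, Prony-series fitting, and conversion to shear/bulk moduli — and
supplies a synthetic-data module so the entire chain runs and is tested at
desk scale without any molecular dynamics.

## The relaxation model

The relaxation modulus is modeled as a Prony series (a generalized Maxwell
solid):

$$E(t) = E_1 + \sum_{i} E_i\, e^{-t/\tau_i},$$

with long-term modulus $E_1 \ge 0$, branch moduli $E_i \ge 0$ (GPa) and
relaxation times $\tau_i > 0$ (ps). One branch gives the *three-parameter
model* $E(t) = E_1 + E_2 e^{-t/\tau}$; when the fitted long-term modulus is
negligible the material is called a *two-parameter model* ($E_1 = 0$). All
moduli in the package are GPa and all times ps; strains are dimensionless
engineering strains.

`prony_fit()` is the central estimator. It minimizes the L2 norm of the
residual between the trace and the model with a derivative-free Nelder–Mead
simplex search, which matches how such relaxation fits are usually done
(norm minimization from guessed starting values), and returns a classed
object with the usual `coef`/`predict`/`residuals`/`plot`/`simulate`
methods.

Numerical choices, all tunable through arguments:

* **Initialization.** Deterministic and scale-free: $E_1^0$ is the mean of
  the last 10 % of the trace, $E_2^0 = E(0) - E_1^0$, and $\tau^0$ the first
  time the trace falls to $E_1^0 + E_2^0/e$. When the trace shows no decay
  ($E_2^0 \le 0$) the branch is started near zero rather than inventing a
  spurious one.
* **Constraints.** Non-negativity of moduli and positivity of $\tau$ are
  enforced by construction: moduli enter the search squared and $\tau$
  log-transformed, so the simplex runs unconstrained.
* **Multi-start.** 8 restarts by default; restarts 2… jitter the initial
  parameters multiplicatively by $U(0.5, 2)$ under the run seed. The best
  restart is returned and the objective is, by construction, no worse than
  any tried start.
* **Convergence.** Relative tolerance $10^{-10}$ on the simplex, at most
  $10^4$ evaluations, and a second simplex pass restarted at the optimum to
  sharpen convergence. On noiseless single-branch traces this recovers
  parameters to near machine precision; the test suite requires $10^{-3}$
  relative.
* **Loading phase.** `relaxation_modulus()` drops samples before the hold
  begins and re-zeroes time there: at high pulling rates the loading-region
  response is ignored in the characterization.
* **Form selection.** `select_form()` declares the two-parameter form when
  $E_1 < f \cdot E(0)$ with $f = 0.01$ by default, then refits with $E_1$
  pinned to zero. The threshold is a fraction of the instantaneous modulus
  so the rule is scale-free.
* **Generalization.** `n_branches > 1` fits the full Prony sum (5-, 7-,
  …-parameter models); branches are stored canonically sorted by $\tau$, so
  branch order never changes the represented function.

## Correspondence conversion

With a constant Poisson's ratio $\nu$, the elastic–viscoelastic
correspondence principle maps the Laplace-domain relations
$\bar G^*(s) = \bar E^*(s)/(2(1+\nu))$ and
$\bar K^*(s) = \bar E^*(s)/(3(1-2\nu))$ back to the time domain in closed
form: every modulus scales by a constant and **relaxation times are
preserved**,

$$G_i = \frac{E_i}{2(1+\nu)}, \qquad K_i = \frac{E_i}{3(1-2\nu)}.$$

`to_shear()`/`to_bulk()` implement this; `converted_moduli()` and
`moduli_table()` assemble the usual summary table across $\nu$ values. The
default ratios are $\nu \in \{0.33, 0.48\}$ — a compressible and a nearly
incompressible scenario; published shear/bulk parameter tables for NF-L
sidearms are arithmetically consistent with exactly these two values, which
is why 0.33 is preferred here over the rounder 0.3 sometimes quoted
alongside such tables. $K$ diverges as $\nu \to 0.5$ and the package raises
a singularity error saying so rather than returning a huge number.

Because $\tau$-preservation is exact under constant $\nu$, any converted
table whose relaxation times differ from the source model's cannot have come
from this conversion; the package never reproduces such rows.

The closed form is cross-checked by `inverse_laplace_check()`, which
numerically inverts the Laplace-domain expressions with a fixed-Talbot
contour method (Abate–Valkó). $M = 24$ contour terms is the double-precision
sweet spot for these transforms — accuracy degrades for $M \gtrsim 40$
through cancellation in $e^{rt}$ — giving agreement with the closed form to
about $10^{-9}$ relative; points where two contour resolutions disagree are
flagged `unstable`, never smoothed. The general $\nu(s)$ form of the
correspondence relations is exposed only through this numerical route,
since the constant-$\nu$ case is the one computed in practice.

## Extraction from trajectory frames

`read_dump()` parses the `ITEM:`-delimited text dump dialect (TIMESTEP /
NUMBER OF ATOMS / BOX BOUNDS / ATOMS), taking the column order from the
ATOMS header; stress columns may be named `sxx … syz` or carry `[1]`–`[6]`
compute suffixes. Image flags unwrap wrapped coordinates on read. A
malformed trailing frame is dropped with a warning, preserving prior frames.

Per-atom virial output comes as stress$\cdot$volume in $\mathrm{atm\,Å^3}$
(the real-units convention), so group stress needs the group's occupied
volume. `voronoi_volumes()` computes per-atom Voronoi cell volumes with a
periodic tessellation of the box:

* each cell is the intersection of bisector half-spaces against the
  periodic images of all atoms;
* vertices are enumerated by vectorized triple-plane intersection with
  distance-sorted pruning (a bisector whose half-distance exceeds the
  current circumradius cannot cut the cell);
* volumes come from fanning each face into pyramids over the site; faces
  are deduplicated on their vertex set so near-duplicate planes (e.g.
  bisectors to a jittered coincident pair) cannot double-count;
* periodic tessellation volumes sum to the box volume exactly, which the
  tests require to $10^{-6}$ relative and cross-check per atom against a
  Monte-Carlo nearest-site estimate;
* coincident positions are jittered by $10^{-6}$ Å under a fixed seed with
  a warning (degenerate tessellation), and a non-periodic fallback clips
  cells to the box — an approximation appropriate for non-periodic runs.

`group_stress()` then reports
$\sigma = -\left(\sum_i (sv)_i\right) / \left(\sum_i v_i\right) \times
1.01325\times10^{-4}$ GPa: the virial-pressure sign is negated so tension is
positive, and the conversion is atm → GPa. The reported scalar stress is the
axial normal component along the pulling axis; `von_mises()` is offered as
an alternative invariant. Strain is displacement-based:
$\varepsilon(t) = \bar u_\mathrm{axis}(t)/L_0$, the mean axial displacement
of the pulled group from the first frame over a reference length.

## Tensile analysis

`build_curve()` joins stress and strain series on the strain grid (linear
interpolation when resolutions differ); `stiffness()` is an ordinary
least-squares slope over a **user-specified** strain window. No automatic
unfolding/stretching changepoint detection is attempted: in the pulled
sidearms the two regimes overlap and cannot be cleanly distinguished, so
inventing a segmentation would be false precision. Typical reporting windows
end near strain 2.17 for the lower rate and 3.6 for the higher one,
mirroring the ~220 % and ~360 % pulls these analyses usually record.
`compare_rates()` orders stiffness by nominal rate and flags violations of
the expected stiffer-at-higher-rate ordering; duplicate rates are reported
as ties, never merged.

## The synthetic-data module

The generators stand in for the MD output and define the study conditions
used throughout the tests:

* `generate_relaxation_trace()`: samples a Prony model on a uniform grid —
  default 1 ns duration, 1 ps spacing, hold strain 0.8 — with additive
  i.i.d. Gaussian noise on the modulus. No noise magnitude is established
  for such traces, so the default used in the noisy-recovery studies
  (0.05 GPa, roughly 5 % of a ~1 GPa instantaneous modulus) is this
  package's choice, documented here, not a literature value. Gaussian
  additive noise is the simplest model that exercises the fitter; real
  traces have correlated, non-stationary fluctuations.
* `generate_tensile_curve()`: continuous piecewise-linear two-stage curve
  (shallow unfolding slope, then steeper stretching slope), with additive
  Gaussian fluctuation. Defaults: unfolding slope 0.05 GPa, stretching
  slope 0.5 GPa (the ~0.5 GPa scale reported for stiff high-rate response),
  breakpoint at strain 1, fluctuation 0.02 GPa. Real pulls show overlapping
  regimes and rate-dependent roughness that the piecewise-linear form does
  not emulate.
* `generate_frames()`: toy trajectory frames with *exactly* prescribed
  group stress — atom positions are drawn once and held fixed across
  frames, per-atom stresses fluctuate around the target but their
  volume-weighted mean is projected back onto the prescription. This gives
  the extraction stage a machine-precision ground truth.

Passing tests on these generators demonstrate that the *pipeline* is
correct — units, signs, volumes, fitting, conversion — not that any
particular filament has particular moduli: regenerating published per-rate
parameter values would require the original all-atom trajectories. The
published single-branch parameter sets for NF-L
($E_1 = 0.103$, $E_2 = 0.827$ GPa, $\tau = 87.866$ ps at
$10^8\,\mathrm{s^{-1}}$; $E_1 = 0$, $E_2 = 2$ GPa, $\tau = 100$ ps at
$10^9\,\mathrm{s^{-1}}$) are therefore used as *example inputs* — for
conversion-table regeneration and as generator ground truth — and the
qualitative claims (rate-dependent form switch, stiffer at higher rate) are
tested on synthetic stand-ins.

## Pipelines, determinism and problem sizes

`run_relaxation_pipeline()` and `run_tensile_pipeline()` orchestrate the
stages with CSV/JSON interchange so each stage is independently runnable
(the same stages back the six `inst/cli/sidearm.R` subcommands: `simulate`,
`extract`, `tensile`, `relax-fit`, `convert`, `run-all`). Every artifact
embeds the config hash and seed; re-running with an identical config and
seed is byte-identical. A failing stage aborts with the stage name and
preserves earlier artifacts.

The test suite and the acceptance script size their problems for a desk
machine: relaxation traces of $10^3$ samples, noisy-recovery studies of
100 seeds, toy frames of 8–50 atoms in boxes of 15–30 Å, and a $4\times10^6$
sample Monte-Carlo check of the Voronoi volumes. These sizes were chosen so
each check resolves its tolerance comfortably (e.g. the Monte-Carlo
per-atom sampling error of ~0.3 % sits well inside the 1 % comparison band).

## Known limitations

* The Voronoi implementation targets small frames (tens to a few hundred
  atoms); it is exact but $O(n^2)$-ish per frame and written in pure R, not
  a replacement for a production tessellation library on million-atom
  systems.
* Only constant Poisson's ratio conversions are provided in closed form; a
  frequency- or $s$-dependent $\nu$ enters only through the numerical
  inversion oracle.
* Creep-compliance fitting, isochronous linearity analysis and
  frequency-domain (storage/loss) moduli are out of scope, as are binary
  dump formats and any recomputation of stress from forces.
* The fitted $\tau$ of a noisy trace is biased slightly low when the trace
  barely covers one relaxation time; the 1 ns default covers ~11$\tau$ for
  the reference models, where the median recovery error is well under 1 %.
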