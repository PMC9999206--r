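---
title: "Modelling label-free impedance-activated droplet sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling label-free impedance-activated droplet sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Random encapsulation of cells into microfluidic droplets is Poissonian: at
the loading that maximizes single-cell droplets (λ = 1, 36.8 % singles),
about a quarter of droplets carry two or more cells, so single-cell purity
cannot exceed ~58 % by rejecting empties alone. Working at low loading
(λ ≈ 0.05) restores purity but throttles throughput to a few single-cell
droplets per second. An impedance-activated sorter escapes this trade-off:
each droplet is interrogated electrically as it passes a pair of coplanar
electrode pairs, classified as empty / single-cell / multi-cell from its
differential current amplitude, and — if it matches the selected class —
pushed into a target outlet by a travelling surface-acoustic-wave pulse.

`dropsort` is a simulation twin of that instrument. It generates
ground-truth droplet streams, predicts the electrical signal physics,
synthesizes realistic traces, screens and gates them in the style of the
embedded sorting program, and scores the virtual sort with the standard
metrics (purity, recovery, enrichment fold, throughput). Every stage is
deterministic given one master seed.

## Encapsulation model

Cell counts per droplet are i.i.d. Poisson(λ). All analytic quantities are
thin, tested wrappers over the Poisson pmf:

* `single_cell_probability(lam)`, `multi_cell_probability(lam)`;
* `theoretical_purity(lam)` = P(1)/P(>0), the purity ceiling without
  multi-cell rejection;
* `theoretical_sorted_throughput(lam, cap)` = cap × P(1), the sustained
  single-cell collection rate of a sorter interrogating `cap` droplets/s.

`lambda_from_suspension()` converts a suspension concentration to λ as the
expected number of cells per droplet volume, λ = C·(π/6)d³. Published
device calibrations pair 10⁵ cells/ml with λ = 0.05 and 10⁷ cells/ml with
λ = 0.5; these pairs are *not* consistent with the volume arithmetic (for
a 40 µm droplet, 10⁷ cells/ml gives λ = 0.335). Device-specific effects
(cell sedimentation, inlet geometry, non-uniform sampling of the
suspension) routinely bend this mapping, so we expose both routes rather
than guessing: the arithmetic function, and `encapsulation_presets()`
carrying the published pairs verbatim.

`sample_stream()` draws diameters as Normal(40 µm, CV 3 % by default —
flow focusing is near-monodisperse; the CV is configurable up to 30 % for
size-sensitivity studies), cell positions as Uniform(0, 1) along the
droplet axis, viability flags as Bernoulli, and arrivals either as a
Poisson process or quasi-periodic ("regular", the realistic choice for a
flow-focusing generator and the default in the shipped demo configs).

## Dielectric model

**Single-shell cell.** A cell is a conductive cytoplasm sphere coated by a
thin insulating membrane. `cell_complex_permittivity()` collapses it to an
equivalent homogeneous sphere via the Maxwell–Wagner single-shell formula.
Above tens of MHz the membrane is electrically shorted and the cytoplasm
(0.5 S/m) dominates — which is why the probe runs at 40 MHz. A
permeabilized (dead) cell exchanges its cytoplasm with the suspending
buffer; we model it by substituting the medium conductivity, which makes
it nearly invisible at 40 MHz. The shell parameters (radius 9 µm, membrane
7 nm at ≈1 µF/cm², ε_cyto = 60, σ_mem = 10⁻⁶ S/m) are literature values
for an MCF-7-like cell and are configurable; the sorted-for contrast comes
from the cytoplasm-to-medium conductivity gap, not from fine shell
details.

**Field solver.** `solve_field()` solves ∇·(σ*∇φ) = 0,
σ* = σ + jωε₀ε_r, on the 2D axial–height cross-section of the sensing
region (180 × 20 µm, two 20 µm electrodes with a 20 µm gap on the bottom
wall, 5 V on one electrode, the other grounded, zero normal current
elsewhere). The scheme is a conservative finite-volume 5-point stencil on
a regular grid; the complex system is solved as its equivalent real block
form with sparse LU (`Matrix`). Because the discretization is
conservative, the two electrode currents balance to solver precision —
current conservation is asserted below 10⁻⁶ in the tests. The 2D solution
is per unit depth and is scaled by the 30 µm channel width to report
amperes.

*Numerical behaviour.* The coplanar electrode edges carry the usual
square-root field singularity, so the current converges first-order in the
grid step. The default step is 0.5 µm: halving it moves the current by
about 1 % (the tested band is < 2 %), and for a uniform conductive medium
the solver agrees with the conformal-mapping closed form for coplanar
strips on a half-plane, G = (σ/2)·K(k′)/K(k) with k = g/(g + 2w), within
a few percent once the domain is tall enough to emulate the half-plane.
Qualitative sweeps (orderings, monotone trends) are run at 1 µm, where
they are unchanged and four times cheaper.

**Scene geometry.** A 40 µm droplet in a 20 µm channel is squeezed to a
pancake; in the cross-section it is a full-height region whose axial
extent is the diameter. Cells are disks. Two layouts are available:

* `"dispersed"` — independent disks at mid-height at the cells' own
  fractional positions;
* `"aggregate"` (default) — co-encapsulated cells clump: a row of
  touching/overlapping disks spanning at most one cell diameter, resting
  ~1 µm above the bottom wall. Two cells side by side fill the sensitive
  volume over the electrode gap; a third largely overlaps the pair in
  projection (in three dimensions it sits out of the sensing plane). This
  reproduces the measured pattern: a large amplitude step from one to two
  cells and a small one from two to three, which is precisely why the
  instrument can gate "multi" without resolving exact counts above two.

**Homogenized mode.** A 2D cross-section overstates an inclusion's volume
fraction (a 9 µm cell is 32 % of the droplet cross-section but only 9 %
of its volume), so explicit disks exaggerate amplitude-level contrast.
For claims about *how big* the cell signal is relative to the droplet —
the PBS invisibility of cells, the conductivity sweep — scenes can be
`homogenize = TRUE`: the droplet interior is painted with the
Maxwell–Garnett effective conductivity of the suspension
(`droplet_effective_sigma()`), which carries the true 3D volume fraction.
Explicit disks remain the tool for geometry-dependent questions (position
effects, aggregate saturation). The two routes agree on the class
ordering empty < single < multi at all frequencies of interest.

**Contrast metrics.** Interfacial impedances (electrode double layer,
thin oil film) are deliberately omitted: the 40 MHz probe shorts them.
Without them, the amplitude *ratio* |I_cell|/|I_empty| in the
low-conductivity medium is mild and nearly flat in frequency, while the
absolute differential amplitude |ΔI| — the quantity the instrument
actually thresholds against a fixed noise floor in µA — grows by orders
of magnitude from 100 kHz to 40 MHz. Reports therefore carry both
columns, and frequency-trend assertions are made on |ΔI|.

## Acoustic model

A travelling surface acoustic wave exerts a radiation force
F = Y_T·πr²·E on a sphere of radius r at mean energy density E. (The
traveling-wave cross-section form is adopted as the standard expression;
we do not claim it verbatim from any specific source.) `radiation_force_factor()`
computes Y_T from the fluid-sphere partial-wave series
(Yosioka–Kawasima/Hasegawa): scattering coefficients from pressure and
normal-velocity continuity using spherical Bessel functions (half-integer
`besselJ`/`besselY`), summed with adaptive truncation past the n ≈ kr
shoulder. Two independent checks pin it down: the coefficients satisfy
the boundary conditions to machine precision, and below kr = 0.05 the
series matches the monopole/dipole Rayleigh closed form
(4/9)(ka)⁴[f₀² + f₀f₁ + ¾f₁²] within 2 %.

With literature fluid parameters (water droplet ρ = 998, c = 1481; HFE
oil ρ = 1614, c = 660; MCF-7 as an effective fluid sphere ρ = 1068,
c = 1550) the droplet Y_T plateaus at order unity for diameters ≥ 10 µm,
tens of times the cell's Y_T at matched size — the force on the droplet is
independent of its contents (adding one cell shifts the droplet-average
density well under 1 % and Y_T by well under 2 %). The published ratio of
three orders of magnitude depends on unprinted acoustic cell parameters;
under our literature defaults we assert only "much greater than ten".

`deflection_feasible()` closes the loop with first-order mechanics: the
droplet reaches Stokes terminal velocity essentially instantly, so the
lateral displacement over a pulse is F·t/(6πµR). The default energy
density (5 J/m³) is a nominal calibration chosen so the standard 5 ms
pulse displaces a 40 µm droplet across one 30 µm channel width;
absolute drive-power-to-E conversion is out of scope.

## Trace synthesis

The two electrode pairs subtract, so a droplet produces a bipolar
template: a positive flat-top lobe (plateau with Gaussian edges) at the
first pair and its mirror image at the second, one pitch later. Droplet
size sets the transit time (lobe width = (diameter + electrode span) /
velocity) but not the amplitude — reproducing the measured size
insensitivity. A cell-bearing droplet's plateau sits at 85 % of its class
amplitude with a narrow bump at the cell's fractional position topping
the template up to exactly the class amplitude; the lobe maximum
therefore sits where the cell is, as observed in position-sensitive
droplet impedance signals. The position-to-offset link carries Gaussian
jitter (SD 0.153 by default, chosen so the recovered correlation lands
near R² ≈ 0.78 for uniform positions; var(U)/(var(U)+sd²) = 0.78).

Class mean amplitudes come from the field solver
(`amplitude_from_model()`): peak amplitude of class k is |I_k − I_oil|,
scaled so the two-cell class sits at 0.45 µA — placing multi-cell
droplets above a 0.4 µA gate. The frozen default table (empty 0.213,
single 0.313, two-cell 0.450, three-cell 0.481, permeabilized 0.192 µA)
is regenerable from the solver and checked against it in the tests.
Droplet-to-droplet amplitude scatter (CV 5 %) and additive white Gaussian
noise (0.02 µA default) are calibration knobs: the defaults put
gate-based screening accuracy in the high-90s percent regime, which is a
modelling choice, not a measured claim. Template overlap raises an error
unless coincidence mode is enabled, in which case templates superpose.

## Screening and triggering

`detect_events()` mimics the embedded peak finder: threshold-crossing
segmentation of positive lobes (crossings separated by less than half a
pitch are merged — they are noise fragments of one lobe), amplitude as
the segment maximum, and a validity requirement that the mirrored
negative lobe follows within a two-pitch window (rejecting glitches:
pure noise produces essentially no paired events at a 5σ threshold).
The sub-peak offset is the argmax after smoothing at about the bump
width.

`classify_events()` applies the amplitude gates; boundary values go to
the higher-count class (conservative for single-cell purity at a tight
upper bound), and amplitudes in a gap between the empty threshold and
the single gate are labelled ambiguous and routed to waste.

`calibrate_gates()` reproduces the pre-run practice of sampling the
mixture and placing the gate by eye — deterministically: a fixed-grid
kernel density estimate (Sheather–Jones bandwidth) is segmented at its
local minima; density lobes carrying less than 2 % of the mass merge
into their neighbours (small-sample wiggles are not modes), valleys that
do not dip below half their smaller flank merge too, and the strongest
remaining valleys become the thresholds. Unimodal samples raise an
error rather than guessing.

`schedule_triggers()` fires a pulse `activation_delay` after a
target-class peak unless the actuator is within its lockout
(pulse width + dead time, at least 1/max-rate); skipped targets are
logged. The schedule provably never violates the 200 Hz cap. Recovery
losses in the end-to-end runs come mostly from this timing, as in the
real instrument: at 200 droplets/s the pulse width equals the droplet
spacing, so position-dependent peak-time jitter occasionally lands two
targets inside one lockout.

## Sorting metrics

`virtual_sort()` routes a droplet to the target outlet iff its event was
detected, gated into the target class, fired a trigger, and the acoustic
deflection is feasible; everything else follows the default flow to
waste. `sort_metrics()` reports composition on two explicit bases (all
droplets, and cell-containing droplets only — published figures mix the
two), purity (target-class fraction in the target outlet), recovery
(against *all* true target-class droplets entering the sorter, so
detection failures and timing skips count against it; the published
denominator is not stated, ours is declared), enrichment fold
(post/pre fraction), per-class rejection, and target-outlet throughput.
The engine is tested against brute-force per-droplet tallies and a
closed-form confusion-matrix oracle.

## Problem sizes and reproducibility

The shipped analyses use streams of 10³–10⁵ droplets, sweep grids of
~10 points, and a 0.5–1 µm solver grid; these sizes make every result
reproducible on a laptop core in minutes while leaving the Monte-Carlo
standard errors far inside the asserted tolerances. One master seed fans
out to per-stage child seeds through a fixed affine rule
(`dropsort:::child_seed`), so stages can be rerun in isolation;
identical configs produce byte-identical traces, ledgers and metrics.

## What the synthetic data does and does not show

The generator emulates Poisson loading, near-monodisperse size scatter,
class-dependent bipolar peaks with position-dependent sub-peaks, white
noise, and arrival statistics up to 200 Hz. It does not emulate baseline
wander, electrode drift or fouling, droplet merging/size drift during
hours-long runs, coincidence pile-up (off by default), or the real
instrument's analog chain. Passing tests therefore validate the
*algorithms* — encapsulation statistics, field solution, gating,
timing, metric accounting — under the stated model of the data, not the
instrument's experimental performance; the published experimental
accuracy/purity/recovery figures depend on unprinted noise levels and
gate settings and are deliberately not asserted. What the model does
assert about the experiments is structural: the class-amplitude
ordering and saturation, the medium/frequency optimization trends, the
droplet-size insensitivity, the content-independent actuation, and the
Poisson arithmetic connecting loading, purity ceilings and throughput.

## Known limitations

* The 2D cross-section cannot be quantitatively faithful to both the
  droplet baseline and the cell increment at once; the
  explicit/homogenized split documents which claims each mode supports.
* Electrode polarization and oil-film capacitance are omitted; below
  ~10 MHz the predicted absolute currents are therefore optimistic.
* Acoustic propagation is lossless single-scattering on fluid spheres;
  streaming, attenuation and wall effects are out of scope, so the
  energy density is a nominal, not absolute, quantity.
* The λ-to-concentration mapping and the acoustic energy density are
  calibration points, not derived quantities.
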