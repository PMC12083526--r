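---
title: "Difference density, extrapolation and kinetics: the methods behind trsfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference density, extrapolation and kinetics: the methods behind trsfx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trsfx)
```

# The problem

A pump-probe structural experiment on a photoactive protein crystal yields,
per time delay, a reflection dataset in which only a fraction
$\alpha$ of the molecules have reacted. trsfx implements the computational
chain that turns such data into mechanistic quantities: difference electron
density (DED) maps, per-region density time traces, an SVD decomposition of
map series, occupancy (activated-fraction) estimation by structure-factor
extrapolation, real-space refinement of side-chain reaction coordinates by
DED correlation (dFoCC), kinetic model fits on logarithmic time grids, and a
parallel single-crystal UV/Vis absorption pipeline. Everything runs in space
group P1 on toy systems generated by the package itself, so the entire chain
is testable on a laptop with no experimental download.

# Difference density maps

Observed DED maps use the classic isomorphous recipe: the light dataset is
scaled onto the dark reference with an isotropic model
$k\,e^{-B_{rel}s^2}$ (SCALEIT-like, $s^2 = 1/(4d^2)$), difference amplitudes
$\Delta F = |F_{o,l}| - |F_{o,dark}|$ are formed on the common reflections,
and the map is synthesized with phases from the dark model. Two data-quality
filters are always available and on by default:

* **SNR filter** — only amplitudes with $F/\sigma > 3$ in *both* parents are
  used (`snr_min = 3`);
* **low-resolution cutoff** — reflections at $d \ge 10$ Å are excluded
  (`d_low = 10`), preventing high-intensity low-resolution terms from
  dominating the difference synthesis.

Maps are stored in absolute units; every threshold in the package is
expressed in units of the map RMS ($\sigma$), computed on demand, because
contour levels in this field are universally quoted in $\sigma$. Map
synthesis omits the $(0,0,0)$ term, so every map has exactly zero mean.
The default grid spacing is $d_{min}/3$, a common oversampling choice.

A useful small-signal property (tested): a mixture with activated fraction
$\alpha$ gives a DED map that is, voxel-wise, $\approx\alpha$ times the map
of the pure light state. This linearity is what makes integrated DED a
usable kinetic observable.

# Density integration and SVD

`integrate_region()` mirrors the standard map-quantification procedure:
threshold the map at $3\sigma$, select voxels within a radius (default
2.0 Å — wide enough to cover covalent geometry, narrow enough not to bleed
into neighbors; no value is prescribed by the field) of the atoms of
interest, and sum values of the requested sign. `svd_decompose()` stacks
masked voxels (rows) against time points (columns), so the left singular
vectors are time-invariant component maps, the right singular vectors their
magnitude traces, and the singular values their weights. SVD signs are fixed
deterministically (largest-|loading| voxel positive); each map is
thresholded against its own $\sigma$, mirroring per-map contouring.

# Occupancy from structure-factor extrapolation

Extrapolated structure factors amplify the difference amplitudes on top of
the calculated dark set,
$$|F_{ext}| = N\,w\,\Delta F + |F_{c,dark}|,$$
with per-reflection "Bayesian" q-weights
$w = 1/(1 + \sigma^2/\langle\sigma^2\rangle + \Delta F^2/\langle\Delta F^2\rangle)$
(the Ren/Šrajer form; a plain pluggable vector can replace it). Because a
difference map built from amplitude differences carries features at roughly
half their true height, full deconvolution of a state populated at fraction
$\alpha$ needs $N \approx 2/\alpha$ — the package interprets the
"$N = 2$ per occupancy" convention as $N = 2/\alpha$ throughout.

Two numerical choices matter here and were settled by experiment on the
synthetic world (both are exposed as arguments):

* **Weight normalization.** The raw q-weights average $\sim$0.3–0.4, so
  feeding them into $N w \Delta F$ would rescale the entire $N$ axis and
  bias $\alpha$ low by a factor $\approx \langle w \rangle$. The scan
  therefore uses mean-normalized weights ($w/\langle w\rangle$), which keep
  the *relative* down-weighting of noisy and outlier amplitudes while
  leaving the $N$ scale meaningful.
* **Residual definition.** The residual negative density $\Delta\rho_{res}$
  is integrated directly from the extrapolated map, within the marker region
  where the (weighted) DED map shows significant negative signal (beyond
  $-3\sigma$). Subtracting the calculated dark-model map first — available
  as `subtrahend = "dark_calc"` — makes the residual *exactly* linear in
  $N$ (the subtraction leaves $N$ times the weighted difference synthesis)
  and hence destroys the very inflection the method needs; it is kept only
  for comparison.

The physics of the scan: while $N < 2/\alpha$ the dark-state density at the
departing atoms is only partially subtracted and the marker contains
essentially no negative density; beyond $N \approx 2/\alpha$ the amplified
difference terms over-subtract those atoms and negative density grows
steadily. `estimate_occupancy()` locates the breakpoint. Because the
residual grows superlinearly past onset (the over-subtracted region both
deepens and widens with $N$), a free two-line fit lands systematically late;
the default estimator instead fits a flat-plus-linear hinge to
$\sqrt{\Delta\rho_{res}}$, restricted to the onset half of the rise whenever
the scan shows a genuine flat regime. The textbook free two-segment fit is
retained as `transform = "none"` and recovers the breakpoint of an exactly
piecewise-linear scan to machine precision. On the toy crystal the full
procedure recovers $\alpha \in \{0.1, 0.2, 0.5, 1.0\}$ with median error
within 25%, and $\alpha = 0.2$ within about 3–4 percentage points — the
residual underestimate reflects the soft exhaustion onset, not a tunable
constant, and is reported as computed.

# dFoCC refinement

dFoCC asks: which side-chain rotation best explains the observed DED? For a
candidate conformer the package computes $|F_{c,l}| - |F_{c,dark}|$, builds
the calculated DED map on the observed map's grid, and scores the Pearson
correlation over a fixed mask (union of 2.5 Å spheres around the moving
atoms in the dark position and at the search-span extremes, so departing and
arriving density are covered for every candidate). The search is
deterministic coordinate descent: each round sweeps every declared rotation
axis on a 1-D grid (initial step 10°, span ±60° by default), re-centers on
the best conformer, and halves the step and window on stalls, terminating at
0.1° — the conformational resolution limit of the data; an implied-
displacement criterion (0.1 Å) can be enabled via `min_step_ang` for coarse
searches. Ties break toward the smaller total |offset|, then earlier axis
order. A full Cartesian conformer library explodes combinatorially; on
noise-free single-axis problems the coordinate-descent optimum provably (and
test-verifiably) matches an exhaustive 0.1° grid argmax within one final
step. No steric term is applied — candidates are scored purely by
correlation, as in the procedure the package models; clash checking belongs
to downstream refinement, which is out of scope.

# Kinetics

Two models cover the observables:

* first-order accumulation $A_\infty(1 - e^{-t/\tau})$;
* a two-step sequential (rise-then-decay) form
  $baseline + A\,\frac{\tau_2}{\tau_2-\tau_1}(e^{-t/\tau_2} - e^{-t/\tau_1})$,
  the intermediate population of an A→B→C scheme, with $\tau_1 < \tau_2$
  imposed as an identifiability convention (the form is invariant under
  swapping the constants up to amplitude rescaling). The degenerate
  $\tau_1 = \tau_2$ limit is available behind a flag.

Fitting is weighted least squares in linear value space on the (typically
log-spaced) time grid: amplitudes and baseline enter linearly and are
profiled out exactly; the time constants are located by a log-spaced grid
spanning the data range, polished by Nelder-Mead/Brent, with the
user-supplied initialization always included among the starts (so the
returned fit can never be worse than the initialization). Standard errors
come from the Jacobian at the optimum. Repeated time points are averaged
before fitting. Constant traces return a flagged-degenerate fit rather than
an error.

# The spectral pipeline

Single-crystal pump-probe absorption spectra arrive as (wavelength,
absorbance) pairs, one fresh crystal per delay, so optical path length is a
per-point nuisance. The pipeline is: difference spectrum (transient − dark);
Savitzky-Golay smoothing (21-point window, cubic — the window shrinks
symmetrically at the edges, reducing the order only where fewer points than
order+1 remain); trapezoidal integration of the radical band (580–640 nm);
normalization by the dark-state oxidized-flavin band (456–490 nm, chosen on
the red flank to minimize Rayleigh scattering) after subtracting a fitted
$b\lambda^{-4} + c$ scattering baseline (fit window 700–800 nm, a documented
default — the absorption-free window is not prescribed); averaging of
repeated delays; and standardization of the assembled trace to a maximum of
1. Scaling any crystal's transient+dark pair by a constant provably leaves
its trace point unchanged — that invariance *is* the purpose of the
normalization, and it is tested.

Two-state concentrations come from Lambert-Beer at 450/635 nm with the
tabulated molar extinction coefficients (oxidized flavin: 11204 and 0;
neutral semiquinone radical: 3833 and 4958 M⁻¹cm⁻¹). 635 nm is used as the
tabulated wavelength even where 630 nm appears in running text, because the
printed coefficients are for 635 nm.

# The synthetic world

`make_toy_crystal()` builds a 33-atom P1 cell (18 × 15 × 12 Å): a
three-residue peptide whose central residue is an Asn-analog side chain with
rotatable chi1/chi2 axes, a flat fused 10-atom ring standing in for an
isoalloxazine, and six waters. Heavy-atom geometry is fixed; the seed only
jitters solvent positions and B-factors. The standard light state rotates
the chi2-like axis by −86.4°, the magnitude of the switch the toy emulates.

Generator defaults are the stated experimental conditions: activated
fractions around 20% (the printed extrapolation estimate), 19-point pump-
probe delay grids from 10 ns to 233 ms built from the named snapshot delays
padded with log-spaced fillers, spectral delays 10 µs–5 s, first-order
constants near 43.9 ms and two-step pairs (59 µs, 15 ms) and (13 ms, ~200 ms
for the slow decay, a stand-in where only the rise constant is printed),
per-crystal optical path factors in [0.5, 2], and amplitude noise of 1%
(diffraction) or 5% (traces/spectra) where a level is stated.

Partial occupancy is modeled in *structure-factor space*,
$F_{mix} = (1-\alpha)F_{dark} + \alpha F_{light}$, the physically correct
description of a space-averaged crystal. Multi-locus time series treat loci
as independently activated, mixing the $2^k$ combination states with
Bernoulli-product weights ($k \le 3$). Observed amplitudes get fractional
Gaussian noise with matching sigmas — the simplest model consistent with
SNR-based filtering; counting statistics, detector effects, partiality and
indexing ambiguity are deliberately absent. "5% noise" on a generated trace
means additive Gaussian noise with a standard deviation of 5% of the trace
maximum (for spectra: of the full-conversion difference-band amplitude of
that crystal); the choice between relative and additive noise is not
prescribed anywhere, and the additive reading keeps noise well-defined at
the zero-signal early delays. All generators draw from a local seeded RNG
(Mersenne-Twister) that never touches the caller's stream.

A green test on this world therefore establishes algorithmic correctness
and statistical recoverability under idealized isomorphous noise — not
robustness to the systematic errors of real serial crystallography.

# Numerical choices and degenerate inputs

* Structure factors by direct summation with published 4-Gaussian form
  factors (a single-Gaussian "toy" mode exists for simpler oracles); maps by
  FFT with Friedel completion; both are cross-checked against brute-force
  summation in the test suite (1e-6 / 1e-8).
* Negative extrapolated scalar amplitudes are clipped to zero and counted
  (attribute `n_clipped`) — zeroing keeps the reflection set complete where
  rejection would punch holes in the synthesis.
* An all-zero difference set yields uniform q-weights with a warning; a
  marker without 3σ DED signal yields a zero scan with a warning rather
  than a misleading sphere integral; an identically zero or exactly linear
  scan raises a no-inflection error.
* A flat observed DED map returns the base conformer with a warning (no
  move is justified by a null signal); a conformer that moves nothing has
  undefined correlation and errors when scored directly.
* Zero-variance vectors in correlation maps give NA rows/columns with a
  warning, never a silent zero.

# Known limitations

P1 only (no symmetry machinery, by design); isotropic scaling and B-factors;
no intensity merging or French-Wilson conversion; no atomic refinement
against extrapolated amplitudes; MTZ binary I/O is not provided (reflections
travel as CSV or minimal structure-factor mmCIF; maps as CCP4/MRC mode 2).
The occupancy estimator assumes the scan spans both regimes of the
residual-density curve; occupancies below ~5% put the breakpoint beyond the
default N grid and need a wider grid.
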