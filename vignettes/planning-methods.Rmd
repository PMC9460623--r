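---
title: "Two-stage excitation planning for microwave breast hyperthermia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage excitation planning for microwave breast hyperthermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhfocus)
```

## The planning problem

Microwave hyperthermia raises a breast tumor's temperature into the 39-45 C
range by focusing microwave energy on it with a phased applicator — an array
of antennas surrounding the breast whose per-channel drive voltages $a_i$
and phases $\phi_i$ must be chosen so the deposited energy concentrates on
the target while sparing healthy tissue. At a single operating frequency
(2.45 GHz here) the total field is the superposition of per-channel
unit-drive fields,

$$\mathbf{E}_{tot}(r) = \sum_{i=1}^{N} a_i\, \mathbf{E}_i(r)\, e^{j\phi_i},$$

and the quantity that drives tissue heating is the heating potential

$$Q_0(r) = \tfrac{1}{2}\,\sigma(r)\,
  \lvert\mathbf{E}_{tot}(r)\rvert^2 \quad [\mathrm{W/m^3}],$$

where $\sigma$ is the tissue conductivity and $\lvert\cdot\rvert^2$ sums
the squared complex moduli of all vector components — no real-field or
zero-imaginary-part simplification is made anywhere in the package. Under
mild assumptions the maximum of $Q_0$ and the steady-state temperature
maximum coincide, so the package plans in the heating-potential domain and
deliberately leaves the bio-heat equation out of scope.

Focusing quality is scored by the fraction of in-breast energy landing in a
10 mm target square,

$$\Omega_{target} = 100\,\%\times
\frac{\sum_{target}\sigma\lvert\mathbf{E}_{tot}\rvert^2}
     {\sum_{breast}\sigma\lvert\mathbf{E}_{tot}\rvert^2},$$

by the same fraction for the dominant off-target hotspot
($\Omega_{hotspot}$), by their quotient $\Psi = \Omega_{hotspot} /
\Omega_{target}$ (lower is better), and by the average deposition over the
target, $P_{av}$, quoted at a fixed 6 W total input power.

## Applicator schemes

Two applicator geometries are encoded:

* **linear** — 12 antennas in two rows of six (2 cm pitch) on opposite
  sides of the breast; three successive antennas share one drive, so
  $N = 4$ channels. Phase constraints: $\phi_1 = 0$ (reference), free
  $\phi_2, \phi_3$, and $\phi_4 = \phi_2 + \phi_3$ (mod 360).
* **circular** — 12 antennas on a ring at 30 degree spacing, each its own
  channel. $\phi_1 = 0$; the six even-numbered antennas are free; each odd
  antenna takes the wrapped sum of its two neighbours.

The circular constraint admits a reading with five rather than six free
phases; the implementation follows the per-antenna constraint rule with six
free even-antenna phases, which the reported per-antenna excitation sets
satisfy, and exposes the free-phase count per scheme in one place
(`free_phase_count`).

All phases live in degrees, wrapped to $(-180, 180]$; radians appear only
inside $e^{j\phi}$. Voltage-to-power conversion uses the lumped-port
convention $P = V^2/R$ with $R = 50\,\Omega$ (1 V $\to$ 0.02 W), and the
6 W budget counts all 12 physical antennas in both schemes — a
linear-scheme channel voltage feeds each of its three antennas.

## Synthetic phantom

`generate_phantom()` emulates a heterogeneously dense breast slice: an
ellipse (default outer semi-axes 42 x 32 mm on the 71 x 91 grid at
1 mm/pixel) with a 2 mm skin rim and a glandular texture synthesized as a
Gaussian random field, spectrally low-pass filtered at a correlation length
`heterogeneity` (default 8 mm, a typical glandular structure scale). The
interior conductivity is min-max rescaled to exactly [1.00, 1.88] S/m and
the permittivity co-varies over [10, 55]; skin is fixed at
$\epsilon_r = 38$, $\sigma = 1.5$ S/m (inside the background conductivity
range; the slice data the phantom emulates report no separate skin value).
Outside the breast $\sigma = 0$, which automatically excludes those pixels
from every energy sum. Tumors are 5 mm-radius discs with $\epsilon_r = 40$,
$\sigma = 2.0$ S/m — deliberately just above the 1.88 S/m background
maximum. In the infinite-correlation-length limit the spectral filter
annihilates every non-constant mode, and the rescaling degenerates; the
generator then uses the range midpoints (1.44 S/m, 32.5), making the limit
well-defined and testable.

The pixel convention is fixed once: row index increases with $-y$, column
with $+x$, coordinates in mm from the grid centre, and a point belongs to
the pixel centre within half a pixel under a half-open rule. With the
default 1 mm pitch the 10 mm target square therefore covers exactly 100
pixels.

## Field model

The per-channel unit-excitation fields would come from a full-wave FEM
solve in a laboratory workflow; the package accepts such fields through a
documented plain-JSON container (`read_fieldset()`) and everything
downstream depends only on that contract. Its built-in model
(`simulate_unit_fields()`) is a deliberately transparent physical
approximation: each antenna radiates a cylindrical wave

$$s(r) = A\,\frac{e^{-j\,\bar{k}(r)\,d(r)}}{\sqrt{\max(d(r), d_{min})}},$$

where $d$ is the antenna-pixel distance and $\bar{k}$ is the complex
wavenumber $k = \omega\sqrt{\mu_0\varepsilon_0(\epsilon_r -
j\sigma/\omega\varepsilon_0)}$ averaged along the straight ray from antenna
to pixel (material sampled every half pixel; free space outside the grid).
The scalar is assigned to the in-plane unit vector transverse to the ray.
This reproduces the two features the optimization exploits — phase
accumulation and lossy attenuation through heterogeneous tissue — while
ignoring scattering, multipath and antenna coupling; that is a stated
fidelity limit, not an accident. Consequences: passing tests demonstrate
that the planning machinery inverts *this* field model, and the method's
metric levels here are not comparable number-for-number with values
computed on FEM fields.

Numerical choices: the time convention is $e^{+j\omega t}$, so the
principal square root gives $\mathrm{Im}(k) < 0$ and decay;
$d_{min}$ is one pixel, guarding the source singularity; and the amplitude
$A = \sqrt{P\,\eta_0/\pi}$ routes the 0.02 W port power of a 1 V drive
through a unit-height free-space cylinder, which lands $P_{av}$ at the
6 W budget in the kW/m^3 decade a clinical planning calculation reports.

## Training corpora and the masked target

Stage 1 draws integer free phases uniformly from $\{0,\dots,359\}$
(unit voltages), superposes, converts to heating potential, and min-max
normalizes each map to [0, 1]; labels are the interleaved
$(\sin, \cos)$ of each free phase, which avoids the wrap discontinuity a
raw-degree regression would have to learn. Stage 2 fixes the stage-1
phases, draws integer voltages 0-9 per channel (all-zero draws are
re-drawn: a zero field has no normalizable map), and labels with the
voltages rescaled by the 9 V ceiling. Because the heating potential is
homogeneous of degree 2 in the drive and then min-max scaled, uniformly
rescaled voltage vectors produce identical inputs — an intrinsic,
documented ambiguity that the 6 W renormalization resolves at reporting
time. Default corpus sizes are 2000 (linear) and 50,000 (circular), split
80/20 into training and validation.

At planning time the unknown ideal heating map is replaced by a binary
mask: 1 on the 10 mm square centred on the target, 0 elsewhere. The mask is
fed to both trained networks as-is (it is already on the [0, 1] scale of
the training inputs).

## Network and training engine

Both stages share one architecture: three 3x3 'same'-padded convolutions
with 16, 64 and 128 filters, each ReLU-activated and followed by 2x2 max
pooling; batch normalization after the convolution stack; flatten; and
three dense layers. The output width is the only difference between the
stages: $2 n_{free}$ sin/cos values (4 linear / 12 circular) for stage 1,
$N$ voltages (4 / 12) for stage 2. Training minimizes mean absolute error
with Adam at learning rate $10^{-4}$, batch size 100 (linear) or 200
(circular).

Choices the architecture description leaves open were fixed once: dense
hidden widths 256 and 64 (a monotone funnel; recorded in `cnn_spec()`),
batch normalization placed once after the convolution stack, 'same'
convolution padding (so 71 x 91 pools to 35 x 45, 17 x 22, 8 x 11), at most
100 epochs with early stopping on validation loss at patience 10, and
He/Glorot-scaled seeded initialization. The engine itself is implemented in
the package (single-precision im2col + BLAS GEMM convolutions with exact
backpropagation through pooling and batch normalization, verified against
finite differences); training is reproducible given the initialization and
shuffling seeds.

Decoding is the two-argument arctangent of each $(\sin,\cos)$ output pair,
which projects off-circle regression outputs radially; a $(0,0)$ pair is an
error, not a guess. Predicted free phases are always expanded through the
scheme constraint, so a reported phase vector satisfies it by construction.
Predicted voltages are clipped to [0, 1], rescaled by 9, and renormalized
to the 6 W budget before powers are quoted.

## Look-up-table baselines

The brute-force baseline enumerates all integer-degree free-phase pairs
(360 x 360 = 129,600 cells for the linear scheme) and, at the winning
phases, a 41-level voltage grid per channel (0 to 1 V in 0.025 V steps,
41^4 = 2,825,761 cells, the all-zero cell skipped). Both tables maximize
$\Omega_{target}$ only — hotspots are deliberately invisible to them,
which is exactly the asymmetry the comparison with the masked-target
network probes. Cells are scored in vectorized blocks through per-region
Hermitian coupling matrices
$M^R_{ij} = \sum_{r\in R}\sigma\,\mathbf{E}_i\cdot\mathbf{E}_j^*$, so a
cell costs one small quadratic form instead of a full-grid superposition;
the identity with the naive per-cell loop is oracle-tested. Ties break to
the first cell in lexicographic order; enumerations projected beyond
$10^7$ cells are refused with a size estimate.

## Hotspot definition

"Dominant hotspot" is operationalized as the best-scoring window congruent
to the target square, slid over every in-grid position that overlaps the
breast and does not intersect the target square (ties: smallest row, then
column). A window shaped like the target makes $\Psi$ a like-for-like
energy ratio, and the printed metric triples are mutually consistent under
exactly this reading. $P_{av}$ is implemented as the mean heating
potential over the target pixels (keeping the one-half of $Q_0$, which
keeps its units honest); the variant without the one-half that the metric
is sometimes quoted with is available via
`options(mhfocus.pav_printed_formula = TRUE)`.

## Problem sizes used by the tests

The test suite exercises the full linear study conditions where that is
informative and small synthetic cases elsewhere: the acceptance checks
train stage 1 on the complete 2000-sample, 71 x 91 linear corpus for 12
epochs (validation error is already far below the random baseline there:
held-out mean circular phase error of a few degrees against the 90 degree
uniform-random expectation, and the masked-target solution reaches well
over half the 129,600-cell look-up table's best $\Omega_{target}$), while
unit tests use 12-32 pixel grids, toy field sets with hand-checkable
values, and exhaustive brute-force oracles. The full-scale circular corpus
(50,000 samples) is supported but not exercised by the default test run;
its pipeline path is tested at reduced size.

## Known limitations

* The field model is single-scattering-free: no multipath, no antenna
  coupling, no matching medium. Metric levels on FEM-computed fields will
  differ; the container contract exists precisely so such fields can be
  substituted.
* The phantom is a statistical emulation of a heterogeneously dense
  breast, not an MRI-registered one; its conductivity range, tumor
  contrast and geometry are pinned to the reference values so metric
  behaviour is comparable, but pixel-wise maps are not.
* Planning is 2D (central slice). Vertical defocusing and 3D hotspots are
  out of scope.
* The voltage stage inherits whatever bias the phase stage's solution has:
  its corpus is generated at the predicted phases, exactly as in the
  two-stage protocol.
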