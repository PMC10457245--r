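---
title: "Methods: XANES, STXM co-localization and LCF in camap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: XANES, STXM co-localization and LCF in camap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camap)
```

`camap` chains the spectro-microscopic analyses used to ask whether
calcium is associated with organic carbon in soil: XANES spectrum
processing, STXM stack co-localization, linear-combination fitting (LCF)
with factor-analytic standard screening, μ-XRF species mapping, and the
supporting bulk-chemistry statistics. This vignette is the package's own
account of those methods: the models and their assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was open.

## Edge-step normalization

All spectral comparison in the package happens on normalized spectra. The
model is the standard XAS convention: a linear background under the whole
spectrum and an edge jump that carries the element amount,

$$\mu_{\mathrm{norm}}(E) \;=\; \frac{\mu(E) - (a + bE)}{P(E_0)},$$

where $a + bE$ is the least-squares line through the pre-edge window and
$P$ is a polynomial (order 0–2, default 2) fitted to the
pre-edge-subtracted post-edge window. Dividing by the scalar $P(E_0)$
(not by the polynomial pointwise) sets the edge step at $E_0$ to exactly
1.0 by construction and makes the output invariant to any positive
rescaling of the input — both properties are asserted in the test suite
at 1e-10. Two presets ship with the package:

| preset | pre-edge (eV) | post-edge (eV) | E0 (eV) | order |
|---|---|---|---|---|
| `Ca-K-PtReyes` | 4013.39–4033.39 | 4063.39–4243.39 | 4043.39 | 2 |
| `C-K-PtReyes` | 279.8–283.3 | 291.8–302.0 | 284.8 | 2 |

$E_0$ is always an explicit parameter and never inferred from the data,
because at the Ca K-edge two distinct energy conventions coexist: the
normalization $E_0$ (4043.39 eV) and the monochromator calibration
reference (first-derivative maximum of gypsum at 4043.89 eV). The
calibration routine locates the derivative maximum with a parabolic
refinement through the three points around the discrete maximum — sub-grid
accuracy without assuming a line shape — and applies a rigid translation
of the energy axis. Interpolation everywhere (replicate merging, grid
alignment, standard resampling) is piecewise linear: it preserves
two-column data fidelity and cannot overshoot. Fit windows are clipped to
the available grid, with a warning when 10% or more of a window is lost.
Exact third-decimal agreement with other normalization software is not
claimed; the derivative and interpolation schemes are declared here
instead.

## STXM stacks and Boolean co-localization

A stack is a series of transmission images over increasing photon energy.
Optical density is $OD = -\ln(I/I_0)$ per pixel; $I_0$ may be a scalar, a
per-energy vector, or a pixel region averaged per frame. Zero-count
pixels have no finite OD and are flagged invalid rather than clamped —
downstream masks exclude them explicitly.

Element maps are above-minus-below edge differences (C: 295/280 eV, Ca:
349.4/342 eV, Fe: 710/698 eV). Saturation masking removes pixels whose OD
exceeds 1.0 — *strictly* greater, so a pixel at exactly 1.0 survives. The
test value is by default the per-pixel maximum OD over all frames, the
most conservative basis; a single-frame basis is available. The Boolean
classes are then

* `C_total` $= (C > t_C) \wedge \mathrm{sat}$
* `CaC_noFe` $= C_{\mathrm{total}} \wedge (Ca > t_{Ca}) \wedge \neg(Fe > t_{Fe})$
* `FeC_noCa` $= C_{\mathrm{total}} \wedge (Fe > t_{Fe}) \wedge \neg(Ca > t_{Ca})$
* `FeCaC` $= C_{\mathrm{total}} \wedge (Ca > t_{Ca}) \wedge (Fe > t_{Fe})$

so the two exclusive classes are disjoint and all subclasses nest in
`C_total`; these invariants are asserted on every pipeline run. Because
no principled universal threshold exists for "element present", the
default is mean + 2 SD of the map over a background region (auto-detected
as the pixels at or below the map median when none is marked), overridable
per element — robust, scale-free and reproducible. The subset spectrum of
a class is the plain mean OD over its pixels, so the union spectrum is
exactly the pixel-count-weighted average of the subclass spectra.

Two printed conventions deserve a note. The Ca map pair is sometimes
quoted as 394.4/342 eV, which is implausible for the Ca L-edge (principal
peaks 348–352 eV); the default here is 349.4/342.0 eV, with the quoted
value available verbatim via `stack_map_defaults(ca_above = 394.4)`.
Stacks are accepted as pre-aligned; an integer-pixel cross-correlation
aligner is provided as a convenience only.

## LCF with the 99–101% weight-sum convention

`lcf_fit` solves $\min_w \lVert y - \sum_k w_k s_k \rVert^2$ subject to
$w_k \ge 0$ with the weight sum left *unconstrained*, using a
deterministic Lawson–Hanson active-set solver written for the package
(small standard sets solve exactly in a few iterations; the solver is
cross-checked against an independent implementation and a dense simplex
grid search in the tests). The raw weight sum is recorded — sums near
100% indicate an internally consistent fit — flagged when outside a
configurable window (default 95–105%), and the weights are then
normalized to 100% for reporting. Fit quality is the XAS R-factor
$\sum(y-\hat y)^2/\sum y^2$ (invariant under common rescaling) and
reduced $\chi^2 = \sum(y-\hat y)^2/(n-p)$. Weight uncertainties are
1-sigma values from the linearized covariance of the active set scaled by
the residual variance; this convention is declared rather than matched to
any external software. The default fit windows are the normalization
interiors (Ca K 4030–4100 eV, C K 283–295 eV). No per-standard energy
shifts or scale factors are fitted.

`total_c_partition` applies a two-component LCF of the total-C subset
spectrum onto the Fe–C and Ca–C subset spectra. Because each subset
spectrum is normalized to unit edge step and the C edge step is
proportional to the carbon amount, the recovered weights estimate the
fractions of measured organic carbon associated with each metal; on
synthetic stacks this recovery is benchmarked against the generator's
realized carbon masses restricted to the measured (classified,
unsaturated) pixels, which is the quantity the spectra actually encode.

## Factor analysis and SPOIL screening

Candidate standards for LCF are screened by testing whether each can be
reproduced from the principal components of the sample set. The PCA is
uncentred by default — absorption spectra share a common edge that is
itself a meaningful factor; a centred mode exists. For a target $x$ with
loadings $t = U^\top x$ and projection $\hat x = U t$:

* $AET = \mathrm{RMS}(x - \hat x)$ (apparent error in the target),
* $REP = RE \cdot \lVert t \rVert / \sqrt{r}$ (error expected in
  $\hat x$ from the data's own noise, with $RE$ the Malinowski real error
  computed from the discarded eigenvalues and $r$ the channel count),
* $RET = \sqrt{\max(AET^2 - REP^2, 0)}$, and $\mathrm{SPOIL} = RET/REP$.

SPOIL bands follow the published scale: <1.5 excellent, 1.5–3 good, 3–4.5
fair, 4.5–6 acceptable, >6 unacceptable. A noiseless model gives
$REP = 0$: in-space targets get SPOIL 0, out-of-space targets SPOIL
$\infty$ (unacceptable); numerically exact low-rank sample sets have
their $RE$ snapped to zero (relative threshold 1e-10) so floating-point
residue is not mistaken for noise. Two practical caveats surfaced during
development and are worth knowing: the embedded-error automatic rank
selection is reliable for homoscedastic noise (the tested construction)
but overfits under heteroscedastic Poisson noise, where choosing the rank
from the eigenvalue spectrum directly is sounder; and a sample set with
little compositional variation barely constrains the contrast directions,
so even true endmembers can screen poorly — the analysis drivers
therefore screen against the class subset spectra across stacks, which
span the composition range, not the totals alone.

## μ-XRF species mapping

Multi-energy maps repeat a fluorescence raster at incident energies
chosen to contrast species; the default quartet (4040, 4049, 4055,
4080 eV) brackets the pre-edge, white line, shoulder and post-edge of the
Ca K-edge. Reference spectra are sampled at the map energies by linear
interpolation, and each pixel's count vector is fit by non-negative least
squares (non-negativity is imposed and declared). Pixels below a total
count threshold are left unfit and flagged — masking is explicit, never
silent. Dominant-species maps break exact ties toward the first standard
and flag them. On noiseless phantoms the painted area fractions are
reproduced exactly (tested); weights scale linearly with any common frame
rescaling. Dead-time and self-absorption corrections are assumed done
upstream.

## Bulk statistics

CEC is the valence-weighted charge sum over Al³⁺, Ca²⁺, Mg²⁺, Na⁺ and K⁺
(H⁺ excluded throughout), in cmol_c kg⁻¹ from mol kg⁻¹ inputs; base
saturation is the non-acid share of that charge. Table associations are
ordinary least squares over complete rows; the table PCA standardizes
variables first (correlation-matrix PCA), dropping zero-variance columns
with a warning. Linear mixed models are deliberately out of scope.

## The synthetic generator: what it emulates, and what it does not

The generator provides every downstream stage with inputs whose truth is
known exactly.

* **Endmember spectra** are an arctangent step (γ = 0.5 eV by default; a
  standard phenomenology, chosen because no line-shape model is implied
  by the data the package targets) plus Gaussian peaks. The C library
  carries a "plant-like" signature (aromatic 285.0, phenolic 286.4,
  carboxylic 288.0 eV) and a "microbial-like" one (carboxylic 288.0,
  O-alkyl 289.5 eV); the Ca L endmember has the L3/L2 quartet at 348.1,
  349.2, 351.5, 352.2 eV; Fe is a presence channel only. These are
  stand-ins with the right peak positions, not reconstructions of any
  measured library.
* **Scenes** are axis-aligned ellipses with uniform random centres;
  overlap resolves by draw order — the simplest shape family that
  exercises co-localization geometry. Composition classes (Ca–C, Fe–C,
  Fe–Ca–C, C-only) have fixed endmember mass fractions summing to 1;
  background carries none. Thickness is i.i.d. log-normal per particle
  pixel (default meanlog log 0.6, sdlog 0.45), optionally clipped, which
  makes the saturation-mask exceedance probability available in closed
  form for testing.
* **Stacks** follow Beer–Lambert,
  $I(E,p) = I_0 e^{-t(p) \sum_k f_k(p)\,\mu_k(E)}$, with Poisson counting
  noise by default (matching counting detectors; Gaussian available for
  speed, none for round-trip tests, where OD recovers the absorbance
  field to 1e-10). The default grid has 30 energies: 1-eV sampling over
  278–302 eV plus the Ca and Fe map frame pairs.
* **Bulk tables** couple exchangeable Ca linearly to SOC with noise
  scaled so the expected $R^2$ equals the target (default 0.69, the
  regime of interest); other cations are drawn independently in
  field-plausible ranges for an acidic grassland (pH 3.8–5.3, SOC
  0.6–4%). An unreachable target given the stated noise floor warns and
  reports the realized value.

What the generator does *not* emulate: beam drift, detector dead time,
monochromator glitches, self-absorption, sub-pixel misalignment, or any
real soil mineralogy. Passing tests therefore demonstrate that the
*analysis chain* is correct and unbiased under its stated model — not
that real beamline data satisfy that model.

## Problem sizes and determinism

The shipped analyses use 96×96 to 128×128 pixel scenes, 30-energy stacks,
10–18 stacks per experiment, and bulk tables of 200 samples — sizes at
which every result in the README reproduces in well under a minute while
leaving the statistical comparisons meaningful. All generators take
explicit integer seeds and are bitwise reproducible; `run_pipeline()`
embeds the seed and a configuration hash in every artifact and
byte-identical reports across reruns are asserted in the tests. The
incident intensity default (2000 counts) gives per-pixel OD noise of a
few percent — class-mean spectra over hundreds of pixels are then
essentially noise-free, which is why partition recovery to fractions of a
percentage point is expected rather than optimistic.

## Known limitations

* The SPOIL algebra implemented is one declared Malinowski variant;
  published SPOIL values from other codes need not match numerically.
* LCF fits no per-standard energy shifts, so miscalibrated standards
  must be calibrated first.
* The Boolean presence thresholds are a convention; results near the
  threshold are sensitive to it, which is why the threshold used is
  recorded in every `classify_pixels` result.
* Stack I/O uses a per-energy TIFF directory dialect with 16-bit count
  quantization (relative error ≤ 1/65535 of the frame maximum); exact
  counts should stay in memory or be regenerated from seeds.
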