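---
title: "Models and methods behind semfilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind semfilm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semfilm)
```

`semfilm` models SEM imaging of unstained biomolecules mounted under a
metal-coated SiN membrane: electron transport through the film, the
electrostatics of spot charging, forward image formation, and the
deconvolution/resolution pipeline. This vignette documents the models, the
parameters that matter, the numerical choices, and the limits of what the
package's synthetic tests can show about real micrographs.

## Electron transport model

The Monte Carlo engine is a classic single-scattering simulator with
continuous slowing down:

* **Elastic scattering.** Total screened-Rutherford cross-section
  $\sigma(Z,E) = 5.21\times10^{-21}\,\frac{Z^2}{E^2}\,
  \frac{4\pi}{\alpha(1+\alpha)}\left(\frac{E+511}{E+1024}\right)^2\
  \mathrm{cm^2}$, screening parameter $\alpha = 3.4\times10^{-3}Z^{0.67}/E$
  ($E$ in keV). The relativistic factor uses the 1024 constant so that one
  convention is pinned throughout code and tests. Polar angles are drawn
  from the inverse CDF $\cos\theta = 1 - 2\alpha u/(1+\alpha-u)$; azimuths
  are uniform.
* **Energy loss.** Joy–Luo modified Bethe stopping power with
  $k_i = 0.731 + 0.0688\log_{10}Z_i$ and Berger–Seltzer mean ionization
  potentials. The $k_iJ_i$ offset keeps the logarithm positive down to the
  transport cutoff of 0.05 keV, below which an electron is booked as
  absorbed and its residual energy deposited at its final position.
* **Mixtures.** Mean free paths add reciprocally over elements weighted by
  atomic density ($N_A \rho w_i/A_i$); the scattering element of each event
  is drawn with probability proportional to $n_i\sigma_i$. SiN is treated
  with Si$_3$N$_4$ stoichiometry (weight fractions 0.6006/0.3994), a
  declared choice — only the density (3.12 g/cm³) is fixed by the film's
  specification.
* **Interfaces.** A sampled free path that would cross a layer boundary is
  truncated there; the electron advances $10^{-6}$ nm into the next medium
  and a fresh free path is drawn from that material. No mid-step material
  mixing is attempted.
* **Fates.** Crossing $z=0$ moving upward is backscattering (re-entry is
  not tracked), crossing the bottom of the stack is transmission, reaching
  the cutoff is absorption. These partition every run exactly, and
  per-trajectory bookkeeping (initial energy = deposited + exit kinetic
  energy, to $10^{-9}$ keV) is asserted in the test suite.

The beam enters at $z=0$ travelling straight down with entry $(x,y)$ drawn
from a Gaussian whose FWHM equals the spot diameter (3 nm default); a
top-hat disk profile is available. The RNG is a per-electron substream
(xoshiro256\*\* seeded by splitmix64 from the run seed and the electron
index), so runs are bit-reproducible and trajectory $i$ does not change
when `n_electrons` does.

Two membrane thicknesses appear in the film's description: 60 nm is used
for transport runs and 50 nm for the nominal imaging membrane and the
charging capacitor. Both are plain configuration choices
(`metal_coated_sin_stack(sin_thickness = ...)`).

### Known limitations of the transport model

Single-scattering screened-Rutherford transport is the textbook SEM model
and is what this package deliberately implements, but its cross-sections
for heavy elements at 3–5 keV are substantially *larger* than tabulated
Mott cross-sections. Consequences we observe and document rather than
tune away:

* Bulk backscatter coefficients come out high for high-Z targets
  (η(Au) ≈ 0.59 at 4 keV vs ≈ 0.48 experimentally) — a known property of
  this cross-section family.
* Transmission through the Ni/Au-coated stack is strongly suppressed
  relative to Mott-based simulators: at 4.0 kV we transmit ≈ 1.7% of
  primaries and at 3.6 kV ≈ 0.1%, where Mott-based simulation of the same
  stack reports ≈ 20% and ≈ 10%. The *shape* of the physics is right —
  transmission rises monotonically with voltage, ≥ 80% of primaries are
  absorbed at 3.6 kV, and the lateral beam-spread FWHM under the film
  (≈ 37 nm at 4.0 kV) matches the ≈ 40 nm figure that sets the
  resolution floor — but absolute transmitted fractions inherit the
  cross-section family. An independent from-scratch implementation of the
  same formulas reproduces these numbers exactly, so they are a property
  of the model, not of the code.
* No secondary-electron cascade is modelled. The under-film contrast
  mechanism runs on SEs, but no quantitative SE model is specified for
  this geometry; transmitted-primary statistics stand in for the
  SE-relevant lateral spread, which is also how the beam-spread figure is
  defined.

## Charging model

The irradiated spot is an ideal parallel-plate capacitor through the film:
$C = \varepsilon_0\varepsilon A/d$ with $\varepsilon = 7.5$ for SiN,
$A = 7.07$ nm² (a 3-nm spot) and $d = 50$ nm, giving
$C = 9.39\times10^{-21}$ F and $q/C \approx 17$ V per trapped electron.
The per-pixel dose at 31.3 pA, 40 s, 1280×1024 is 5,963 electrons; that
number is defined with $q = 1.602\times10^{-19}$ C, which is why the
package fixes the elementary charge at that precision rather than full
CODATA. Reaching a 400 V spot potential needs
$\lceil 400\,C/q\rceil = 24$ electrons by direct arithmetic; a commonly
quoted round figure is "about 30", which `charging_report()` accepts as an
explicit override (giving the 30/5963 ≈ 0.5% charging fraction) but never
substitutes silently. Two figures in the source arithmetic do not
reconcile — a 10 MV/cm field-emission threshold across 50 nm corresponds
to 50 V, not 400 V — so the report carries the field, the threshold
comparison and the electron counts separately and leaves the
interpretation to the reader.

## Phantoms and forward imaging

Phantoms are mass-thickness maps (nm of protein-equivalent material),
rendered analytically and rasterized with 4× supersampling so that
symmetry tests are meaningful at 1–2 nm/px. Tier thicknesses (envelope
25, core 55, disk 80 nm for the rod virion; arm 12 / centre 25 nm for the
pentamer; core 14 / cap 24 nm for the dumbbell) are declared defaults, not
measured values: no envelope thickness or relative density is specified
anywhere for these specimens, so the defaults were chosen once to give a
strong but unsaturated contrast range and are documented here.

Image formation is $\mathrm{Poisson}\big(\mathrm{dose}\cdot(\mathrm{PSF}
\otimes e^{-\mu t})\big)$: the specimen attenuates the locally injected
signal, the beam-spread kernel blurs it, shot noise is applied. The
exponential law is the simplest monotone volume-contrast law consistent
with the imaging mode's thickness dependence; the tunnelling transmission
itself has no specified functional form, so $\mu$ is phenomenological
with default 0.02 /nm (an 80-nm virion transmits ≈ 20% of the local
signal — strong dark contrast). Attenuate-first, blur-second ordering is
fixed and load-bearing: swapping it changes edge profiles and hence
resolution numbers. The beam-spread PSF is built by revolving the radial
exit histogram of a transport run into a 2D kernel (annulus counts →
areal density → linear interpolation at pixel radii → normalization).

## Processing pipeline

The chain mirrors standard practice for this imaging mode: contrast
inversion (`max - value`), 2D Gaussian filtering (9×9, σ = 1 px default;
11×11 is the other documented size — figure-level settings being the more
specific, 9×9 is the default), Lucy–Richardson deconvolution
(multiplicative updates, reflective padding, division guard $10^{-12}$,
12 iterations default), compound two-Gaussian PSFs (241-px kernels with
narrow/wide σ presets 12/60, 14/60 and 40/100 px for the virion, pentamer
and proteasome classes). The description of the mixture weighting in the
source protocol is garbled ("the value of 60σ is half that of 14σ"); we
read it as the wide component carrying half the narrow one's amplitude,
i.e. one third of total mass, and expose the weight as a plain parameter
so other readings are one argument away. Whether those σ are pixels or nm
is likewise unstated; they are treated as pixels, consistent with the
241-pixel kernel context.

Convolution uses FFTs on symmetrically padded arrays: mirror padding with
a symmetric kernel conserves total flux exactly, which is what makes the
smoothing and RL flux-conservation tests meaningful at the $10^{-9}$ and
$10^{-6}$ levels.

Resolution is the Reimer edge criterion: the profile is normalized to
[0, 1] using the mean of its two outer thirds as plateau levels, and the
resolution is the distance between the 0.75 and 0.25 crossings (linear
interpolation). For a Gaussian-blurred edge this equals
$2\cdot0.6745\,\sigma = 1.349\,\sigma$, which the tests verify to 1%
on finely sampled profiles. The outer-thirds plateau rule is documented
because it changes sub-nm results: profiles must extend a few σ past the
transition on both sides or the normalization biases the crossings.

## What the synthetic tests do and do not show

The generator emulates: correct specimen geometry at the imaged scales,
beam-spread blur measured from the transport engine, the documented dose
(5,963 e/px) and Poisson statistics. It does not emulate: detector
response and gain noise, scan distortion and drift, specimen flexibility
(real antibody arms are floppy; the phantom's are rigid), carbon
contamination, or the actual SE tunnelling physics. The full-chain test
property — RL with a matched compound PSF strictly improves Reimer
resolution on a simulated virion micrograph at reference dose — therefore
demonstrates the pipeline's internal consistency, not a claim about any
particular instrument's micrographs; reported real-data resolution gains
can only be verified against the original image data.

## Problem sizes and determinism

Default desk-scale runs use $10^5$ electrons per voltage for transport
summaries ($2\times10^5$ in `scripts/acceptance.R`), a 192×96 px virion
scene at 2 nm/px for the imaging chain, and $10^6$ draws for the sampling
oracles; at these sizes every statistical tolerance in the tests is ≥ 4
binomial/standard errors from its expectation under the fixed seeds. All
stochastic components take explicit integer seeds and are bit-reproducible
given them.
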