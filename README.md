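# semfilm

Electron transport and image simulation for SEM of unstained biomolecules
mounted under a metal-coated silicon-nitride film.

## The problem

Unstained proteins and viruses give almost no contrast in electron
microscopy and are damaged by direct irradiation. One way around both
problems is to mount the specimen on the *underside* of a thin insulating
SiN membrane coated with Ni and Au, and scan the *top* with a low-voltage
(3.6–4 kV) beam. Most primaries are absorbed in the metal, so the specimen
is never directly irradiated; the insulating film charges up at the
irradiated spot, and the resulting field drives low-energy secondary
electrons through the film into the specimen, producing TEM-like,
volume-sensitive contrast. `semfilm` implements the computational machinery
behind that imaging mode for people who want to reason about it
quantitatively: microscopists choosing film stacks and voltages, and image
analysts calibrating the deconvolution step.

## What it computes

- **Electron physics per material** — Berger–Seltzer mean ionization
  potential, screened-Rutherford total elastic cross-section
  `sigma = 5.21e-21 (Z^2/E^2) (4*pi/(alpha(1+alpha))) ((E+511)/(E+1024))^2 cm^2`
  with screening `alpha = 3.4e-3 Z^0.67 / E`, and Joy–Luo stopping power
  `dE/ds = 7.85e4 (rho/E) sum_i (w_i Z_i/A_i) ln(1.166 (E + k_i J_i)/J_i)`,
  valid down to the 0.05 keV transport cutoff.
- **Monte Carlo transport** (`run_transport`, compiled core) — single
  elastic scattering plus continuous slowing down through an arbitrary
  layered stack; electron fates (transmitted / backscattered / absorbed),
  lateral and radial exit distributions, per-trajectory energy bookkeeping.
- **Charging arithmetic** (`charging_report`) — the spot-capacitor model
  `C = eps0*eps*A/d`, potential per trapped electron `q/C`, electrons
  needed to reach a field-emission-level potential, and the per-pixel dose
  `I*t/(q*W*H)`.
- **Phantoms and forward imaging** — rod virion (with internal 30-nm
  disks), star-shaped antibody pentamer, dumbbell proteasome and
  straight-edge mass-thickness maps; micrograph simulation as
  `Poisson(dose * (PSF ⊗ exp(-mu t)))`.
- **Post-processing** — contrast inversion, 2D Gaussian filtering,
  compound-Gaussian PSFs, Lucy–Richardson deconvolution, and edge-based
  (Reimer 0.75→0.25) resolution estimation.

## Worked example

```r
library(semfilm)
stack <- metal_coated_sin_stack(sin_thickness = 60)
summ <- run_transport(stack, beam_spec(4.0), transport_config(1e5, rng_seed = 1))
summ
#> <transport_summary> 100000 electrons at 4 kV (seed 1)
#>   transmitted       1719  ( 1.72%)
#>   backscattered    16751  (16.75%)
#>   absorbed         81530  (81.53%)
#>   lateral exit FWHM: 35.2 nm
```

Roughly 82% of 4-keV primaries end in the film and the beam-spread
function under the film is ~35–40 nm wide: the film protects the specimen,
and the raw image is blurred far beyond the 3-nm spot size. Simulating a
rod-virion micrograph with that measured beam-spread PSF and then
deconvolving shows how much of the blur the pipeline wins back:

```r
psf <- psf_from_exit_distribution(summ, pixel_size = 2, max_radius = 70)
ph  <- rod_virus_phantom(pixel_size = 2, canvas = c(192, 96))
mic <- simulate_micrograph(ph, psf, dose_per_pixel = 5963, mu = 0.02, rng_seed = 7)
raw <- gaussian_smooth(invert_contrast(mic), kernel_size = 9, sigma = 1)
sn  <- half_intensity_width(summ$exit_lateral_profile) / 2.3548 / 2  # px
dec <- lucy_richardson(raw, compound_gaussian_psf(91, sn, 2.5 * sn,
                                                  pixel_size = 2), n_iter = 12)
line <- c(96, 6, 96, 48)  # across the rod's long edge
edge_resolution(extract_edge_profile(raw, line, width = 7))
#> raw (inverted + smoothed) edge resolution: 20.4 nm
edge_resolution(extract_edge_profile(dec, line, width = 7))
#> after 12 Lucy-Richardson iterations:       15.0 nm
```

The charging side of the story, at the reference scan conditions
(31.3 pA, 40 s, 1280×1024):

```r
charging_report(capacitor_model(), beam_spec(4), electrons_override = 30)
#> <charging_report>
#>   capacitance            9.39e-21 F
#>   potential per electron 17.06 V
#>   electrons to reach 400 V: 30 (arithmetic 24)
#>   electrons per pixel    5963
#>   charging fraction      0.50%
#>   internal field         8e+07 V/cm (above threshold)
```

Half a percent of a pixel's dose suffices to charge the spot past the
field-emission threshold — charging is cheap, which is why the contrast
mechanism can operate throughout the scan.

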