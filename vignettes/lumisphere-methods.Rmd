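---
title: "Determining optical properties of photoluminescent turbid slabs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining optical properties of photoluminescent turbid slabs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumisphere)
```

## The measurement problem

Turbid materials — tissue, phantoms, filled polymers, phosphor layers — are
characterized by an absorption coefficient $\mu_a(\lambda)$ and a reduced
scattering coefficient $\mu_s'(\lambda) = \mu_s (1-g)$, where $g$ is the mean
cosine of the single-scattering angle. A single integrating sphere measures
the total hemispherical reflectance $R$ and transmittance $T$ of a slab; an
inverse radiative-transfer model then maps $(R, T)$ back to
$(\mu_a, \mu_s')$.

When the sample is photoluminescent, a broadband (white-light) measurement
fails in a characteristic way: the detector cannot distinguish elastically
scattered photons from wavelength-shifted emission, so $R$ and $T$ are
inflated across the emission band and the inverted optical properties
acquire spurious structure there. Scanning a monochromatic excitation
instead, and recording a *complete emission spectrum per excitation
wavelength*, lets the analysis integrate only the elastic peak — a 10 nm
window around the excitation line — and removes the artifact. This package
implements that full analysis chain, together with a synthetic-measurement
generator that replaces the physical instrument for validation.

## Photon-packet Monte Carlo (`simulate_rt`)

The forward model is a standard photon-packet Monte Carlo for a homogeneous
plane-parallel slab:

* step lengths $s = -\ln u/(\mu_a+\mu_s)$, absorption by weight attenuation
  with the single-scattering albedo per interaction;
* Henyey–Greenstein scattering sampled by the closed-form inverse CDF, with
  the isotropic formula used at $g = 0$ to avoid the division by $g$;
* unpolarized Fresnel reflection/refraction at both faces, resolved
  statistically (the full packet weight reflects or transmits), so weight
  changes only through the albedo and Russian roulette;
* Russian roulette below weight $10^{-4}$ with survival probability $1/10$.

Internally the solver works with $\mu_s = \mu_s'/(1-g)$ and explicit $g$;
lookup tables stay indexed by $(\mu_a, \mu_s')$, the parameterization in
which measurements are interpreted.

Three bookkeeping choices matter:

* **Exact conservation.** Every weight transfer is computed by subtraction
  (`dA = w - w*albedo`), and roulette gains/losses are booked against the
  absorbed tally, so $R + T + A + L$ equals the launched weight to rounding
  error on *every* run — a sharp invariant that catches tally bugs, checked
  to $10^{-10}$ in the tests.
* **Port losses.** The sphere exchanges light with the slab only through a
  25 mm port. Packets are tracked in 3-D; those exiting a face farther than
  `port_radius` from the beam axis, or drifting past a configurable lateral
  bound while inside, are tallied as lost ($L$), not as $R$ or $T$.
* **Specular handling.** The beam enters at 8° from the normal, so its
  specular reflection strikes the sphere wall rather than escaping back
  through an entry port; it is therefore tallied into $R$.

The generator is an explicitly seeded xoshiro256++; a given
`(props, beam, n_photons, seed)` reproduces bit-identical tallies on any
platform. Standard errors for $R$ and $T$ come from the per-photon
contribution variance.

The default beam is a uniform 5 mm disk at 8° incidence, matching the
instrument geometry; `pencil_beam()` gives the normal-incidence,
no-aperture configuration that deterministic slab solvers assume, and is
used for all oracle comparisons. The test suite carries an independently
coded adding-doubling solver (Radau/Gauss quadrature in the internal
angles, Legendre-addition redistribution of the Henyey–Greenstein phase
function, doubling from a thin layer, Fresnel boundary operators); the
Monte Carlo agrees with it within 0.005 in both $R$ and $T$ across the
relevant parameter range.

## Mie theory and the asymmetry factor (`mie_single`, `g_spectrum`)

The anisotropy used by the transport model comes from Lorenz–Mie theory for
the scatterers: zirconia spheres (800 nm diameter) in a silicone matrix.
`mie_single` truncates the partial-wave series at the Wiscombe order
$x + 4x^{1/3} + 2$, evaluates the logarithmic derivative by downward
recurrence, and computes the asymmetry factor analytically from the Mie
coefficients (not by quadrature of the phase function); results are stable
to $10^{-8}$ under five extra terms. The size parameter uses the wavelength
*in the matrix*, $x = \pi D n_{med}/\lambda$, and the relative index
$m = n_p/n_{med}$.

Defaults are constant indices $n_p = 2.15$ and $n_{med} = 1.41$, nominal
literature values for zirconia and silicone; both can be replaced by
tabulated dispersion curves. Polydispersity is supported as a normal
diameter distribution truncated at $\pm 3\sigma$ (21 nodes), with
per-diameter asymmetry factors averaged using scattering-cross-section
weights $Q_{sca}D^2$ — the weighting under which the average $g$ is the $g$
of the bulk phase function.

With these constant-index defaults, the unweighted spectral mean of
$g(\lambda)$ over 320–1000 nm computes to 0.65 for monodisperse 800 nm
spheres. Reaching the often-quoted working value of 0.75 for this system
requires the actual (unpublished) dispersion of both materials and the real
size distribution; with constant nominal indices no reasonable averaging
convention reproduces it. The package reports what the stated inputs give
rather than adjusting inputs to a desired output; `g_spectrum` accepts
measured dispersion tables whenever they are available.

## Integrating-sphere correction (`sphere_gain`, `effective_rt`)

A single sphere does not measure true $R$ and $T$: the sample substitutes
for part of the wall, ports leak, and some first-bounce light reaches the
detector's viewed area directly. The package models this with a first-order
radiation-exchange (Jacquez–Kuppenheim-style) description:

$$M = \frac{1}{1 - \rho_w (1-f) - R_s f_s}$$

is the sphere multiplier with wall reflectance $\rho_w$, total open-port
area fraction $f$ and sample-port fraction $f_s$; a surface of reflectance
$R_s$ closing the sample port raises the average wall reflectance and hence
the gain. The detector signal for light entering through the sample port is
modeled as $\Phi(\delta + M)$, where the direct-view term $\delta$ defaults
to the detector-viewed wall-area fraction; wall-first (normalization-beam)
channels see the gain only. Because both sample and calibration
measurements are normalized by their own normalization-beam channel, the
substitution change of $M$ cancels exactly in the calibration algebra and
the residual measured-space bias is carried by $\delta$ alone — upward for
samples darker than the calibration mirror, as expected for substitution
error. The model was validated against an explicit patch-radiosity linear
solve of the sphere interior.

Default geometry: 150 mm sphere, 25 mm sample port, three 20 mm auxiliary
ports, 6 mm viewed spot, flat barium-sulfate wall reflectance 0.97
(tabulated spectra accepted). Lookup tables built with a sphere apply the
same effective map to every cell, so inversion of measured values is
self-consistent and unbiased.

## Lookup table and inversion (`build_lut`, `invert_rt`)

The forward map is tabulated on a $(\mu_a, \mu_s')$ grid for fixed
$(g, n, d)$. The $\mu_a$ axis is log-spaced (sample absorption spans
roughly $2\times10^{-3}$ to $2\times10^{-1}$ mm$^{-1}$, several decades),
the $\mu_s'$ axis linear. Each cell runs the Monte Carlo with a seed
derived deterministically from the base seed, then applies the sphere
correction. Thickness tunes the usable range — thin slabs lose absorption
sensitivity, thick ones starve the detector — so multiple tables (1, 2,
4 mm) cover the standard sample series; tables serialize to a plain-text
container with full metadata.

Inversion minimizes the Euclidean distance in $(R, T)$: the nearest grid
node seeds damped Gauss–Newton refinement on the bilinear interpolant,
clamped to the grid. Grid nodes invert to themselves exactly. Measurements
outside the convex hull of tabulated $(R, T)$ values (including
non-physical inputs with $R + T > 1$) are flagged `extrapolated` and
answered with the nearest-boundary estimate; near-degenerate double minima
are flagged `ambiguous`; and $|\det J|$ of $(R,T)$ with respect to
$(\log\mu_a, \mu_s')$ is reported, flagging the flat-forward-map regions at
extreme albedo where inversion conditioning collapses.

## Spectral processing (`signal_set`, `compute_rt`)

One measurement consists of seven excitation-resolved scans: calibration
channels CRBR, CNBR (mirror at the port, reflection/normalization beams),
CNBT, CTBT (open port), and sample channels SRB, SNB, STB. Processing:
counts are averaged, time-normalized with the per-band acquisition schedule
(100/50/100/200 ms across 320–1000 nm) and dark-subtracted (negatives
clipped, with a logged count). The elastic signal at each excitation
wavelength is the trapezoidal integral over the 10 nm window centred on the
line; window edges are interpolated so adjacent spectral regions partition
exactly. Reflectance and transmittance follow the substitution algebra

$$R = \frac{S_{RB}\,C_{NBR}}{S_{NB}\,C_{RBR}}\,\rho_{cal}, \qquad
  T = \frac{S_{TB}\,C_{NBT}}{S_{NB}\,C_{TBT}},$$

which cancels lamp drift (any common rescaling of the sample set or of the
calibration set leaves $R$ and $T$ unchanged) and the substitution gain.
$\rho_{cal}$ is the mirror's hemispherical reflectance, supplied as a
two-column table and interpolated linearly. Wavelengths with dead
denominators are flagged and excluded, never divided through.

A 7 nm FWHM excitation line is not fully contained by a ±5 nm window: the
error-function integral gives 90.7% capture, with the remainder in the
neighbouring bands. Because every channel shares the same line shape, the
captured fraction cancels in the ratios above and does not bias $R$ or $T$.

The deliberately wrong broadband mode (`compute_rt_polychromatic`) emulates
a white-light instrument by summing the emission spectra of all excitation
rows before integrating each 10 nm band — under simultaneous illumination
the detector at $\lambda$ sees the elastic light at $\lambda$ plus all
photoluminescence landing there. For a non-luminescent sample the two modes
agree to machine precision; for a luminescent one the broadband $R$ and $T$
are inflated across the emission band and the inverted $\mu_a$ and $\mu_s'$
show localized artifacts, which is precisely the failure mode the
monochromatic method exists to avoid.

## The synthetic phantom generator (`phantom_truth`, `generate_channels`)

The generator emulates the standard validation batch: silicone slabs with
zirconia scatterers at $\mu_s' \in \{2, 4, 6\}$ mm$^{-1}$ at 600 nm and
Rhodamine-6G-like dye at 0–6.66 wt%, in thicknesses of 1, 2 and 4 mm.
Ground truth is parametric:

* $\mu_s'(\lambda) = \mu_{s,600}'\,(\lambda/600)^{-b}$ with $b = 1$ by
  default (the scattering power of ~800 nm dielectric spheres in this band
  is of order unity; only the 600 nm anchor values are specified);
* $\mu_a(\lambda)$ = flat matrix baseline ($2\times10^{-3}$ mm$^{-1}$, the
  floor of the measured range) plus a concentration-linear Gaussian dye
  band at 525 nm, FWHM 35 nm, scaled so the highest concentration reaches
  the top of the measured range ($\approx 0.2$ mm$^{-1}$);
* photoluminescence as a Gaussian emission band at 548 nm (FWHM 40 nm,
  preserving the Stokes shift), with amplitude proportional to the absorbed
  excitation power times the dye's share of $\mu_a$ times `pl_yield`
  (default 0.2), split evenly between the reflection and transmission
  directions.

Channel expectations are built from the sphere model so that the
calibration algebra applied to noise-free output reproduces the forward
engine's effective $R$ and $T$ exactly — a constructed inverse that makes
end-to-end identities sharp test oracles rather than approximate ones.
Poisson shot noise (optionally with a dark rate) is applied per bin on the
expected counts; all randomness flows from one recorded seed.

Two idealizations are deliberate and documented:

* the elastic line is a truncated Gaussian confined strictly inside its
  10 nm window, so neighbouring excitation rows contribute exactly zero to
  each other's elastic integrals;
* emission that would fall under a row's own elastic peak is suppressed —
  the generator assumes perfect elastic/PL separability at every excitation
  wavelength.

Real spectrometer data violate both at the percent level (finite line
wings, elastic/PL overlap near small Stokes shifts), so passing the
machine-precision identities here demonstrates the correctness of the
analysis algebra, not the absence of those instrumental effects.
Photoluminescence is injected at the signal level rather than transported
through the Monte Carlo; this reproduces the contamination mechanism of the
broadband artifact but not reabsorption or inner-filter effects.

## Numerical choices and problem sizes

Acceptance-grade checks run at reduced scale chosen as the smallest sizes
at which each property is decisive: a 20 × 20 table at $10^5$ photons/cell
(round-trip truths at $10^6$), 33 excitation wavelengths for the artifact
reproduction, and shot-noise settings where the Poisson spread is a few
percent of signal. Round-trip accuracy at these sizes is ~3% in $\mu_s'$
and ~5% in $\mu_a$ (median over random interior truths); both improve with
photons per cell and grid density. Inversion tolerances: Gauss–Newton
stops when parameters move less than $10^{-12}$; ambiguity is declared at
residual ties within $10^{-4}$ across non-adjacent cells; the Jacobian
floor defaults to $10^{-6}$.

## Known limitations

* Anisotropy $g$ and refractive index $n$ are inputs, not fitted: $(R, T)$
  alone cannot determine four parameters.
* The sphere model is first-order radiation exchange with a Lambertian
  coating; no geometric ray tracing of port geometry or baffle-free
  specular paths.
* Quantum-yield determination is out of scope; `pl_yield` is a generator
  parameter, not an estimate of the dye's quantum efficiency.
* Layered samples, polarization, and time- or spatially-resolved
  quantities are not modeled.
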