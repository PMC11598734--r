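---
title: "A two-layer radiative-transfer model of leaf reflectance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer radiative-transfer model of leaf reflectance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafrt)
```

## The model

Dicot leaves have two optically distinct photosynthetic tissues. The
palisade mesophyll, just under the adaxial epidermis, is a layer of
densely pigmented columnar cells with few air spaces: it absorbs strongly
and scatters weakly. The spongy mesophyll below it is riddled with
intercellular air spaces whose cell-wall/air interfaces scatter light
intensely. `leafrt` models a leaf as this two-layer slab bounded by two
air interfaces and tracks four light flows at every depth: forward and
backward collimated intensity ($I_C$, $J_C$) and forward and backward
scattered (diffuse) intensity ($I_S$, $J_S$).

### Boundary optics

A collimated beam at external angle $\beta_O$ refracts to
$\beta_I = \arcsin\!\big(\tfrac{n_O}{n_I}\sin\beta_O\big)$ and crosses the
smooth part of the surface with the unpolarized Fresnel transmittance

$$T_c = 1 - \tfrac12\left[\left(\frac{\sin(\beta_O-\beta_I)}{\sin(\beta_O+\beta_I)}\right)^2 +
\left(\frac{\tan(\beta_O-\beta_I)}{\tan(\beta_O+\beta_I)}\right)^2\right],$$

which is symmetric in its two angles, so the same coefficient serves both
crossing directions below the critical angle
$\arcsin(n_O/n_I) \approx 45^\circ$ (for $n_I = 1.415$); beyond it the
leaf-to-air beam is totally reflected. A fraction $F_S$ of the surface is
rough: light meeting it exchanges as diffuse light with the
hemispherically averaged coefficient
$T_s = \tfrac{2}{\pi}\int_0^{\pi/2} T_c(\beta)\, d\beta$, taken with equal
weight in the angle itself (not cosine-weighted — the averaging convention
under which the two directions evaluate to $\approx 0.867$ entering and
$\approx 0.469$ leaving). Diffuse light likewise leaves the leaf with
probability $T_s^{IO}$ regardless of which surface fraction it meets; the
complements are reflected back into the lamina and drive the iteration
below.

### Palisade layer

With $s_P \approx 5\ \mathrm{cm^{-1}}$ and $h \le 80\ \mu m$ the chance of
even a single scattering event in the palisade is below 4%, so the four
flows are attenuated by absorption alone (Beer–Bouguer–Lambert):
collimated flows over the slant path $h/\cos\beta_I$, diffuse flows with
the hemispherical pathlength factor 2. The one scattering effect retained
is a single-backscatter source: the downward flows leak
$s_P(1-f)$ per unit path into the upward hemisphere, and the depth
integral of that leakage, attenuated back to the top of the layer, has the
closed form implemented in `js_add()` (with an analytic
$a_P \to 0$ limit, since the printed form divides by $a_P$ and
near-infrared absorption is essentially zero).

### Spongy layer

The four-flux Kubelka–Munk system is linear in depth. The two collimated
flows decay independently at $(a_{Sp}+s_{Sp})/\cos\beta_I$; the two
diffuse flows form a coupled $2\times 2$ block fed by collimated
scattering, with forward/backward weights $f$ and $1-f$ ($f = 0.5$:
isotropic redistribution). Its eigenvalues are taken from the block's
characteristic quadratic
$\lambda^2 - (L_{33}+L_{44})\lambda + (L_{33}L_{44} - L_{34}L_{43}) = 0$,
which with the standard sign structure reduces to the classical
Kubelka–Munk exponent
$\lambda_{3,4} = \pm 2\sqrt{a_{Sp}\,(a_{Sp} + 2 s_{Sp}(1-f))}$; the
implementation is verified against a generic eigensolver and against an
independent collocation solution of the full boundary-value problem.
Boundary conditions are two-point — downward flows known at the top of
the layer, upward flows at the bottom — and the constants follow in
closed form.

### Iterating internal reflections

Each surface encounter reflects part of the outgoing light back into the
lamina. One iteration is a full pass (surface in, palisade down, spongy,
palisade up, surfaces out); the internally reflected fluxes then become
the entering fluxes of the next iteration, with the collimated
propagation angles swapped because the flows have reversed direction.
Exit totals accumulate over $N$ iterations; reflectance and transmittance
are $R = J_{out}/I_0$ and $T = I_{out}/I_0$. One pass suffices in
strongly absorbed bands (blue, red); in the near infrared the
per-iteration output falls by only a factor of $\approx 0.5$ (diffuse
light is internally reflected with probability $1 - T_s^{IO} \approx
0.53$), so the default $N = 6$ captures all but $\sim$1–2% of the
infinite series there. Raise `N` if that tail matters for an application.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `beta_O1` | 35 | degrees | adaxial incidence angle (instrument geometry) |
| `n_I` | 1.415 | — | refractive index of the leaf interior |
| `F_S` | 0.15 | — | rough-surface fraction |
| `I_0`, `J_0` | 1000, 0 | µmol m⁻² s⁻¹ | incident intensities (results are ratios) |
| `h`, `l` | 35.5, 58.6 | µm | palisade / spongy thickness (pea, moderate light) |
| `s_P`, `s_Sp` | 5, 600 | cm⁻¹ | scattering coefficients |
| `f` | 0.5 | — | asymmetry factor (isotropic) |
| `C_ChA`, `C_ChB`, `C_Car` | 3.19, 2.09, 0.94 | mg cm⁻³ | palisade pigment concentrations |
| `N_SpP` | 0.2 | — | spongy/palisade pigment ratio |
| `N` | 6 | — | internal-reflection iterations |

The defaults are the parameterized pea-leaf set: measured thicknesses and
pigment loads (the palisade concentrations correspond to whole-leaf
averages of 1.39, 0.85 and 0.47 mg cm⁻³ through the two-layer weighting
`average_concentration()`), with $s_{Sp}$ and $F_S$ selected by grid scans
against measured reflectance. Angles are degrees and thicknesses
micrometres at the constructor and configuration file; internally
everything is radians and centimetres (absorption and scattering
coefficients are per cm).

## The synthetic data

Two generators stand in for data that cannot ship with the package.

**Specific absorption spectra** (`fixture_spectra()`). In-vivo specific
absorption curves of chlorophyll a, chlorophyll b and carotenoids are
published as figures, not tables, so the bundled fixture is synthetic:
sums of Gaussian bands at the canonical in-vivo maxima (Soret bands at
430/460 nm, red bands at 668/650 nm, carotenoid bands at 450/480 nm) with
a broad low shoulder across the 550–640 nm window — real leaves absorb
green light appreciably — and zero absorption above 720 nm. Amplitudes
are fixed so the default parameter set yields the canonical reflectance
shape (green maximum, red trough, NIR plateau) at realistic magnitudes.
The fixture reproduces band positions and relative magnitudes, not fine
structure: vibrational shoulders, the red-edge slope of particular
species, and package effects on in-vivo spectra are absent. Quantitative
conclusions about a real leaf therefore require user-supplied spectra
(`read_pigment_csv()`); tests passing on the fixture demonstrate the
transport model and workflow, not any particular pigment library.

**Pseudo-experimental spectra** (`make_pseudo_experimental()`). A forward
simulation plus i.i.d. Gaussian reflectance noise (default sd 0.005,
typical of a leaf-clip spectrometer average), clipped at zero,
seed-reproducible. It emulates measurement noise only — no wavelength
registration error, no baseline drift, no leaf-to-leaf biological
variance — so parameter-recovery results on it are a best case for the
fitting workflow, demonstrating identifiability rather than field
accuracy.

## Numerical choices

- **Quadrature.** Hemispherical averages use adaptive quadrature
  (`stats::integrate`, relative tolerance 1e-9) on the equal-weight
  integral; the leaf-to-air integral runs only to the critical angle,
  where the integrand vanishes identically. Values are cached per
  refractive-index pair and always computed, never hard-coded, so `n_I`
  remains a free parameter.
- **Normal incidence.** The printed Fresnel form is 0/0 at
  $\beta = 0$; below $10^{-6}$ rad the analytic limit
  $1 - ((n_I-n_O)/(n_I+n_O))^2$ is used.
- **Absorption floor.** At $a_{Sp} = 0$ the two diffuse-flow eigenvalues
  coincide at zero and the closed-form constants are singular, so
  $a_{Sp}$ is clamped to $10^{-6}\ \mathrm{cm^{-1}}$ (optical depth
  $\sim 10^{-8}$ over a leaf; outputs are continuous across the floor,
  which a test verifies).
- **Overflow-safe evaluation.** Growing exponentials are anchored at the
  boundary where they are largest ($e^{\lambda (x - h - l)}$ forms), so
  optically thick parameter combinations ($\lambda l > 700$) evaluate
  without overflow.
- **Eigenvalue resonance.** When $(a_{Sp}+s_{Sp})/\cos\beta$ crosses a
  diffuse-block eigenvalue (e.g. near $a_{Sp} \approx 256\ \mathrm{cm^{-1}}$
  at $s_{Sp} = 600$, $\beta = 23.9^\circ$) the particular-solution
  denominator vanishes — a removable singularity of the closed form. The
  solver nudges the affected absorption values by one part in $10^5$,
  far below any parameter uncertainty; a test confirms the flows pass
  smoothly through the resonance.
- **Wavelength grid.** Default 400–800 nm at 1 nm; input spectra are
  linearly interpolated onto it, and wavelengths outside a supplied
  pigment table absorb nothing (with a warning).
- **Degenerate geometry.** Grazing internal angles are rejected; zero
  thicknesses are valid (a zero-thickness smooth leaf reduces exactly to
  a Fresnel reflector, which a test checks).

## Design decisions

- **$R^2$ definition.** `compare_spectra()` uses
  $1 - SS_{res}/SS_{tot}$, not squared Pearson correlation: the
  parameterization workflow judges whether adding a mechanism (e.g. a
  rough-surface fraction) brings the model onto the measurement, and an
  offset-invariant statistic could not see that. Users wanting the
  correlation variant can compute it from the same interpolated series.
- **Grid scans, not gradient fits.** The parameterization procedure is a
  small set of physically ordered one-dimensional scans; `scan_parameters()`
  makes that reproducible and deterministic. A local least-squares
  refinement can be layered on by the user, but is deliberately not the
  default: the coarse grids are part of the procedure being modelled.
- **Faithfulness over conservation.** The palisade equations attenuate
  collimated light by absorption only and credit the backscatter source
  $J_S^{Add}$ without debiting the forward flows. The model is therefore
  not strictly flux-conserving when $s_P > 0$: $R + T$ can exceed 1 by up
  to $\sim$1% near zero absorption. This asymmetry is retained as printed
  rather than "fixed"; energy-conservation tests run with $s_P = 0$,
  where the transport is exactly conservative (to series truncation).
- **Angle bookkeeping.** With abaxial incidence absent ($J_0 = 0$) the
  abaxial external angle defaults to the adaxial one so that the backward
  collimated angle is defined; its coefficients multiply zero flows in
  the first iteration, and after the first angle swap both angles are in
  use. Internally reflected collimated light stays collimated even though
  it cannot exit (its angle is below the critical angle by construction
  here, but the convention matters if spectra are extended).
- **Single pigment ratio.** One scalar `N_SpP` scales the whole palisade
  absorption spectrum into the spongy layer; chlorophylls and carotenoids
  are not given separate ratios, as there is no basis for choosing them
  apart.

## Known limitations

- **Palisade-thickness sensitivity in the NIR.** Because $J_S^{Add}$ does
  not vanish with absorption (its $a_P \to 0$ limit is proportional to
  $s_P(1-f)\,h$), NIR reflectance retains a small dependence on palisade
  thickness: thinning $h$ from 35.5 to 25.2 µm lowers NIR reflectance by
  $\approx 4\times 10^{-3}$ at the default parameters (and exactly 0 when
  $s_P = 0$). Physically the NIR response to anatomy is dominated by the
  spongy layer; this residual is an artefact of the non-conservative
  backscatter source and sets the resolution below which NIR thickness
  effects should not be interpreted.
- **Spongy thinning and green reflectance.** In this model the spongy
  backscatter is monotone increasing in $l$ at every absorption level, so
  thinning the spongy layer alone slightly *lowers* green reflectance
  (by $\le 0.01$ here) while clearly lowering NIR reflectance. Observed
  green increases under joint anatomical thinning are reproduced through
  the palisade term.
- **Slow NIR series convergence.** The per-iteration damping at zero
  absorption is $\approx 0.5$, so the $N = 6$ default truncates
  $\sim$1.7% of the NIR total; doubling $N$ reduces that hundredfold at
  negligible cost.
- **Scope.** No epidermal focusing, polarization, fluorescence, water or
  dry-matter absorption, wavelength-dependent refractive index, or
  roughness model beyond the scalar fraction $F_S$; monocot leaves with
  uniform mesophyll can be approximated with $h = 0$ and `N_SpP = 1`, but
  the parameterization shipped here is for a bifacial dicot leaf.

## Verification problem sizes

The test suite checks the analytic spongy solution against an independent
Crank–Nicolson collocation of the two-point boundary-value problem over
50 random parameter sets spanning $a_{Sp} \in [1, 500]$,
$s_{Sp} \in [0, 1500]\ \mathrm{cm^{-1}}$, $l \in [10, 150]\ \mu m$ and
angles up to $40^\circ$ (agreement to $10^{-5}$ relative); the
backscatter closed form against quadrature of its defining integral over
25 random draws; and parameter recovery of $s_{Sp}$ and $F_S$ on their
selection grids over 20 noise replicates at sd 0.005. These sizes give
stable pass/fail behaviour at sub-minute runtimes and are set in the
tests themselves.
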