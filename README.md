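# leafrt

Analytical radiative-transfer model of reflectance and transmittance
spectra in dicot leaves with distinct palisade and spongy mesophyll
layers, for plant remote- and proximal-sensing work: interpreting
hyperspectral leaf measurements, studying how pigment content, leaf
anatomy and surface roughness shape reflectance indices, and generating
controlled synthetic spectra for method development.

## The model

The leaf is an optical sandwich: air / palisade mesophyll (thickness *h*)
/ spongy mesophyll (thickness *l*) / air. Four light flows are tracked at
every depth — forward collimated *I<sub>C</sub>*, forward scattered
*I<sub>S</sub>*, backward collimated *J<sub>C</sub>*, backward scattered
*J<sub>S</sub>* — and each structural element has its own physics:

- **Boundaries.** Snell's law sets the internal propagation angle
  (β<sub>I</sub> = arcsin(n<sub>O</sub>/n<sub>I</sub> · sin β<sub>O</sub>),
  n<sub>I</sub> = 1.415); unpolarized Fresnel coefficients give the
  collimated transmittance of the smooth surface fraction, while the rough
  fraction *F<sub>S</sub>* exchanges light diffusely with hemispherically
  averaged transmittances T<sub>s</sub> = (2/π)∫ T<sub>c</sub>(β) dβ
  (≈ 0.867 entering, ≈ 0.469 leaving; internal angles beyond the critical
  angle arcsin(1/n<sub>I</sub>) ≈ 45° are totally reflected).
- **Palisade layer.** Weakly scattering (s<sub>P</sub> ≈ 5 cm⁻¹), so flows
  follow the Beer–Bouguer–Lambert law — slant path *h*/cos β<sub>I</sub>
  for collimated light, pathlength factor 2 for diffuse light — plus a
  closed-form single-backscatter source J<sub>S</sub><sup>Add</sup> feeding
  the upward scattered flow.
- **Spongy layer.** Strongly scattering (s<sub>Sp</sub> ≈ 600 cm⁻¹):
  a four-flux Kubelka–Munk linear system solved analytically by
  eigen-decomposition, with the classical exponent
  2√(a<sub>Sp</sub>(a<sub>Sp</sub> + 2s<sub>Sp</sub>(1−f))) governing the
  scattered flows, matched to two-point boundary conditions.
- **Iterations.** Light internally reflected at either surface re-enters
  the lamina and is re-propagated (with the collimated angles swapped);
  exit totals are accumulated over *N* iterations (default 6).
  Reflectance is R = J<sub>out</sub>/I<sub>0</sub>, transmittance
  T = I<sub>out</sub>/I<sub>0</sub>.
- **Absorption.** a<sub>P</sub>(λ) = C<sub>ChA</sub>·a<sub>ChA</sub>(λ) +
  C<sub>ChB</sub>·a<sub>ChB</sub>(λ) + C<sub>Car</sub>·a<sub>Car</sub>(λ)
  from palisade pigment concentrations (mg cm⁻³) and specific absorption
  spectra (cm² mg⁻¹); the spongy layer carries a fraction
  N<sub>Sp/P</sub> = 0.2 of the palisade pigments.

The package also provides the parameterization workflow: comparison
metrics (R² = 1 − SS<sub>res</sub>/SS<sub>tot</sub>, RMSE), grid scans
over parameters such as s<sub>Sp</sub> and F<sub>S</sub>, and a
seed-reproducible pseudo-experimental spectrum generator.

## Worked example

```r
library(leafrt)

params <- leaf_params()           # parameterized pea-leaf defaults
spec   <- simulate_spectrum(params)
spec[spec$wavelength %in% c(450, 550, 670, 760), ]
#>  wavelength reflectance transmittance absorptance
#>         450      0.0553        0.0213    0.923408
#>         550      0.3106        0.1933    0.496117
#>         670      0.0662        0.0367    0.897082
#>         760      0.6561        0.3438    0.000138
```

The spectrum has the canonical leaf shape: low blue and red reflectance
(strong chlorophyll/carotenoid absorption, >84% of light absorbed), a
local green maximum near 550 nm, and a near-infrared plateau where
pigments are transparent and the spongy layer scatters about two thirds
of the light back out (absorptance ≈ 0).

Recovering a scattering coefficient from a noisy "measured" spectrum:

```r
ref <- make_pseudo_experimental(params, noise_sd = 0.005, seed = 42)
scan_parameters(list(s_Sp = c(400, 600, 800, 1000)), params, ref)
#>  s_Sp     R2     RMSE
#>   600 0.9995 0.004799
#>   800 0.9822 0.028519
#>   400 0.9616 0.041857
#>  1000 0.9477 0.048863
```

The generating value s<sub>Sp</sub> = 600 cm⁻¹ ranks first, with an RMSE
at the injected noise level (0.005) — the grid scan is the same workflow
used to parameterize the model against measured pea spectra.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/leafrt.R constants
Rscript inst/cli/leafrt.R simulate --config cfg.yaml --out spectrum.csv
Rscript inst/cli/leafrt.R scan --config cfg.yaml --reference ref.csv \
    --param s_Sp --values 400,600,800,1000 --out scan.csv
Rscript inst/cli/leafrt.R fixtures --out-dir fixtures/ --seed 1
```

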