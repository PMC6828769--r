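---
title: "Viscoelastic flow in a leaky channel and the flat-plate dialyzer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic flow in a leaky channel and the flat-plate dialyzer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jeffreyflow)
```

## The physical problem

A flat-plate hemodialyzer passes blood through narrow rectangular channels
whose walls are semi-permeable cellulose membranes. The trans-membrane
pressure drives plasma water through the walls (ultrafiltration), so the
axial flow rate decays along the channel and the usual Poiseuille law does
not apply. Blood is viscoelastic; this package models it as a Jeffrey
fluid, a linear viscoelastic model with two material times: `lambda1` is
the ratio of relaxation to retardation time, and `lambda2` the
dimensionless retardation time. Setting both to zero recovers a Newtonian
fluid.

The flow domain is the gap between two parallel plates of length $L$,
width $w$ and half-height $a$, with $\delta = a/L \ll 1$ (for dialyzer
geometry $\delta^2 \sim 10^{-8}$). Wall seepage follows Darcy's law: the
wall-normal velocity is proportional to the local trans-wall pressure
difference, with proportionality $L_p/(\mu t)$, where $L_p$ (cm²) is the
membrane's mechanical filtration coefficient, $t$ its thickness and
$\mu$ the fluid viscosity.

## Dimensionless formulation

Lengths are scaled by $L$ (axial) and $a$ (transverse), velocities by
$\tilde Q_i/a^2$ and $\tilde Q_i/(aL)$, and pressure by
$\mu L \tilde Q_i / a^4$ applied to the excess over the outside back
pressure $p_m$. The governing groups are

* $K = L_p L^2/(a^3 t)$ — wall filtration parameter,
* $p_i = a^4(\tilde p_i - p_m)/(\mu L \tilde Q_i)$ — scaled inlet pressure,
* $A = w/a$ — width-to-half-height ratio,
* $\lambda_1$, $\lambda_2$ — Jeffrey parameters,

with the derived decay rate $\xi = \sqrt{3K/(1+\lambda_1)}$. Dropping
$O(\delta^2)$ terms (the lubrication approximation) and expanding all
fields in powers of $\lambda_2$, truncated after first order, gives a
closed-form solution. The zeroth-order pressure satisfies
$p_0'' = \xi^2 p_0$, so

$$p_0(x) = C_1 e^{-\xi x} + C_2 e^{\xi x}, \qquad
  C_{1,2} = \frac{p_i}{2} \pm \frac{\xi}{4AK},$$

and the first-order pressure adds homogeneous modes $C_3 e^{-\xi x} + C_4
e^{\xi x}$ plus a particular part with amplitude
$\alpha = \tfrac{2}{15}\xi^2(1+\lambda_1)$ in $e^{\mp 2\xi x}$. The axial
velocity is a parabolic profile in $y$ driven by $-dp/dx$ with a
$(y^4 - 1)$ viscoelastic correction; the wall-normal velocity is odd in
$y$ and equals $K p(x)$ at the wall. All derived quantities — mean
pressure drop $\Delta p(x)$, wall shear $\tau_w(x)$, flow rate $Q(x)$
(normalized so $Q(0) = 1$), leakage flux $q(x) = -dQ/dx$, fractional
reabsorption, stream function and stagnation point — are exact
consequences of these closed forms; nothing on the evaluation path is
differentiated numerically.

```{r basic}
g <- dimensionless_groups(p_i = 3, K = 0.16, A = 1,
                          lambda1 = 0.1, lambda2 = 0.03)
fld <- flow_field(g)
c(p_mid = pressure(fld, 0.5),
  u_center = axial_velocity(fld, 0.3, 0),
  Q_exit = flow_rate(fld, 1),
  FR = fractional_reabsorption(fld))
```

## A correction to the first-order coefficient

The first-order inlet conditions require $p_1(0) = 0$ and a zero net
inlet-flow correction. Working through the first-order system, those two
conditions fix

$$C_3 = \xi^2 (1+\lambda_1)\left[\frac{p_i \xi}{20AK}
  - \frac{1}{15}\left(3C_1^2 - C_2^2\right)\right],$$

i.e. with a minus sign on the $(3C_1^2 - C_2^2)/15$ term. A published
variant of $C_3$ carries a plus sign there and demonstrably violates
$p_1(0) = 0$; the package's default mode is the derived value, with
`c3_mode = "as_printed"` retained so the violation itself can be
reproduced (the verification oracle reports exactly the two first-order
inlet checks as failing in that mode). Notably, the published closed-form
*exit* quantities — the ultrafiltration rate and the exit mean pressure
drop — agree with the derived-mode solution to machine precision, so the
sign defect is an isolated typo in the coefficient, not an error that
propagates into the device-level results. Both exit quantities are
computed by default from the flow-rate/pressure path of the solution, with
the verbatim hyperbolic closed forms available as `mode = "as_printed"`
cross-checks.

A related choice: the centerline symmetry condition is implemented as
$\partial u/\partial y(x, 0) = 0$ (shear-free centerline), the form the
dimensional problem statement uses and the one the solution's even-in-$y$
profile actually satisfies; a dimensionless restatement of it as an
$x$-derivative appears in some sources but does not constrain the profile.

## The dialyzer case study and the inverse problem

The bundled configuration `rp_kidney.yaml` encodes the published operating
data of the RP disposable flat-plate artificial kidney verbatim: membrane
length 42 cm, thickness 2.59e-3 cm, width 11.6 cm, half-gap 9e-3 cm, eight
blood compartments, 150 mm Hg entrance trans-membrane pressure, viscosity
6.9e-3 dyn s/cm², device inlet flow 160 ml/min and device ultrafiltration
200 ml/hr, plus the Jeffrey parameters $\lambda_1 = 0.1$,
$\lambda_2 = 0.03$ commonly used for blood. Totals are split over the
compartments explicitly (`per_compartment_flow()`), never silently.

The membrane's $L_p$ is not part of the data sheet; it is estimated by
inverting the ultrafiltration relation. The measured dimensionless target
is (25 ml/hr)/(20 ml/min) ≈ 0.0208 per compartment. $Q_A(K)$ is a
combination of $\cosh\xi$, $\xi\sinh\xi$, $\cosh 2\xi$ and
$\xi\sinh 2\xi$, all entire in $K$; `estimate_K()` replaces them by their
Maclaurin series truncated at $K^3$ (order configurable) and takes the
smallest strictly positive real root of the resulting polynomial,
reporting every root and the root of the untruncated equation alongside.

```{r rp}
report <- run_rp_case()
report
```

Redimensionalizing $\Delta p(1)$ with the pressure scale
$\mu L \tilde Q_i/a^4 \approx 1.47\times 10^7$ dyn/cm² (1 mm Hg fixed at
1333.22 dyn/cm², a convention of this package) gives the exit mean
pressure drop above. Two open choices were resolved as follows: the
inverse solve uses the full-precision groups ($p_i = 0.013583$,
$A = 1288.9$) rather than rounded presentation values ($0.013$, $1288$)
seen in some summaries — the difference is within 1% of $K$; and
sweep/streamline illustrations at channel scale use $A = 1$, a flagged
assumption that reproduces the documented stagnation patterns
(no reversal at $p_i = 3, K = 0.16$; stagnation inside the channel at
$K = 0.25$ or $p_i = 4$).

## Verification strategy

The closed forms are verified against independent numerics rather than
against themselves:

* **ODE oracle.** `ode_oracle_pressure()` integrates $p_0'' = \xi^2 p_0$
  and $p_1'' = \xi^2 p_1 + \tfrac{1+\lambda_1}{5}(p_0' p_0'')'$ from the
  inlet conditions with adaptive tolerances (default `rtol = 1e-10`); the
  first-order forcing can be built from the integrated state itself,
  keeping the oracle fully independent of the amplitudes. Closed forms
  agree to better than 1e-8 across the parameter box.
* **Residual oracle.** `system_residuals()` evaluates both perturbation
  orders' momentum and continuity balances and all wall/centerline/inlet
  conditions by central finite differences (step 1e-4) on a 50×50 interior
  grid, at tolerance 1e-6 (inlet quadratures at 1e-10). The first-order
  momentum balance is checked in its once-integrated-in-$y$ form — both
  sides vanish on the centerline, so the forms are equivalent — because
  the differential form requires differencing a finite-difference
  estimate, whose rounding noise ($\varepsilon/h^3 \sim 10^{-4}$) would
  swamp the tolerance in double precision. Halving the step contracts the
  truncation-dominated residuals by the expected factor of about four.
* **Limits.** $\lambda_1 = \lambda_2 = 0$ reproduces the classical
  Newtonian permeable-channel solution with an exactly parabolic profile;
  $K \to 0$ is handled by a dedicated linear-pressure branch (switch at
  $K < 10^{-12}$) because $C_1, C_2$ individually diverge there while the
  solution does not.

## Parameter box of the property suites

The seeded generator (`generate_parameter_fixtures()`, default seed
20231104) samples uniformly over $K \in [10^{-4}, 0.3]$,
$p_i \in [0.01, 5]$, $A \in [1, 2000]$, $\lambda_1 \in [0, 2]$,
$\lambda_2 \in [0, 0.05]$. This box spans both regimes the model is used
in — order-one leakage at channel scale and the small-$K$, large-$A$
dialyzer scale — while keeping $\lambda_2$ small enough that the
first-order truncation is meaningful (identities that hold only to
$O(\lambda_2^2)$ are tested with tolerances scaled accordingly; the inlet
normalization $Q(0) = 1$ happens to hold exactly at this order). The
default suites use 20 such sets on 20×20 to 50×50 grids, sizes at which
the whole test run takes a few seconds.

These are synthetic parameter sets, not measurements: passing them shows
the closed forms solve the stated thin-channel perturbation system and
respect its structure, not that the model captures features of real
dialyzers outside its assumptions (steady creeping flow, rigid walls, a
lumped constant back pressure, no osmotic or solute transport, no
$O(\delta^2)$ or $O(\lambda_2^2)$ effects). The single empirical anchor is
the RP-kidney case study above.

## Known limitations

* Valid for $\delta^2 \ll 1$ and small $\lambda_2$ only; no second-order
  corrections in either parameter are included.
* $\lambda_1$ and $\lambda_2$ are taken as given fluid properties; the
  package fits only the wall permeability.
* Published tabulations of the ultrafiltration rate at larger $K$
  (order 0.01) could not be reproduced from their stated parameters by
  direct evaluation of the closed form; only the monotone increase of
  $Q_A$ with $K$ is asserted about that regime.
* For strongly reversed flows (stagnation far upstream) the first-order
  truncation degrades; diagnostics (`stagnation_point()`) flag the
  reversal but no higher-order correction is attempted.
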