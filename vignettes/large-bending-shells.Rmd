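---
title: "Morphoelastic shells at large bending: model, numerics and the Volvox invagination study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphoelastic shells at large bending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoshell)
```

## The model

A thin axisymmetric sheet of incompressible neo-Hookean tissue (material
constant $C$, thickness $t = \epsilon h$) deforms because its cells change
shape. Morphoelasticity encodes the active shape changes as an *intrinsic
configuration*: stretches $f_s^0(s)$, $f_\phi^0(s)$ and curvatures
$\kappa_s^0(s)$, $\kappa_\phi^0(s)$ along the undeformed arclength $s$,
describing the locally stress-free state. This intrinsic metric is in
general incompatible — it cannot be embedded in three-dimensional space —
so the sheet is residually stressed even at equilibrium.

Classical shell theories assume all radii of curvature are large compared
to the thickness. During invagination that fails: wedge-shaped cells make
the intrinsic meridional radius of curvature comparable to $t$. The
regime is measured by the large-bending parameter
$$\eta(s) = \frac{\kappa_s^0\, t}{2 f_s^0 f_\phi^0},$$
half the intrinsic meridional curvature times the intrinsic thickness;
$|\eta| \to 1$ is the *constriction limit* in which one face of the sheet
contracts to a point (fully wedge-shaped cells).

Averaging the three-dimensional elastic energy through the thickness
under this scaling yields an effective two-dimensional density, quadratic
in the shell strains $e_s = (\tilde f_s - f_s^0)/f_s^0$,
$e_\phi = (\tilde f_\phi - f_\phi^0)/f_\phi^0$ and the alternative
curvature strains
$$K_s = \frac{\tilde f_s \tilde\kappa_s - f_s^0 \kappa_s^0}{(f_s^0)^2
f_\phi^0}, \qquad
K_\phi = \frac{\tilde f_\phi \tilde\kappa_\phi - f_\phi^0
\kappa_\phi^0}{f_s^0 (f_\phi^0)^2},$$
which vanish for pure stretching (an inflated sphere has $K_s = K_\phi =
0$). The moduli of the quadratic form are functions of $\eta$ only
(`shell_coefficients()`); all diverge like $(1-|\eta|)^{-2}$ at the
constriction limit, and at $\eta = 0$ the form reduces to the classical
Hookean shell density with Poisson ratio $1/2$, modulus $E = 3C$,
stretching modulus $4Ct$ and bending modulus $Ct^3/3$, with no
stretch–bend coupling. The package's `model = "classical"` energy is
exactly this $\eta = 0$ form evaluated with the same morphoelastic
strains, so the two models differ only through the $\eta$-dependence of
the moduli.

Two closed-form consequences are used heavily in the tests: the excess of
the large-bending over the classical stretching density is
$\tfrac{Ct}{2}\,\eta^2(2-\eta^2)(1-\eta^2)^{-2}(2e_s+e_\phi)^2 \ge 0$,
and the bending excess factorizes as
$\tfrac{Ct^3}{2}\,\tfrac{\eta^2(3-2\eta^2)}{36(1-\eta^2)^2}
(3K_s+K_\phi)(k(\eta)K_s+K_\phi)$ with $13/5 = k(0) < k(\eta) < k(\pm 1)
= 3$ (`k_eta()`). The function $k(\eta)$ was reconstructed from the
bending moduli themselves,
$k = (\gamma_{ss} - \tfrac13)\,/\,(3\,c_b)$ with
$c_b = \eta^2(3-2\eta^2)/36(1-\eta^2)^2$, because the two possible sign
groupings of its printed closed form differ; the reconstruction is
accepted because it reproduces both endpoint values and agrees with the
independent $K_sK_\phi$-coefficient route symbolically. The resulting
expression is
$$k(\eta) = \frac{\eta\,(6 - 10\eta^2 + 11\eta^4 - 4\eta^6) -
6(1-\eta^2)^2\,\mathrm{artanh}\,\eta}{\eta^5\,(3-2\eta^2)}.$$

### Through-thickness asymptotics

The leading order of the expansion yields the Kirchhoff result — normals
to the intrinsic midsurface remain normal — together with the transverse
profile $Z^0(\zeta) = (1-\sqrt{1-2\lambda_s^0\zeta})/\lambda_s^0$ and the
surface offsets $h^\pm = \tfrac{H^0}{2}(1 \mp \lambda_s^0 H^0/4)$, whose
sum is the undeformed thickness exactly. At next order incompressibility
fixes a correction $Z_{(1)}$ in closed form. The package verifies all of
these numerically rather than assuming them: `leading_order_solution()`
integrates the leading-order ODE system with `deSolve` at tolerance
$10^{-12}$ and checks $Z_{(0)} \equiv Z^0$, $S_{(0)} \equiv 0$, $p_{(0)}
= 1$ and the associated conservation law; `z1_residual_check()`
substitutes the closed-form $Z_{(1)}$ and its analytic derivative into
the first-order incompressibility relation over random strain tuples.
`verify_asymptotics()` runs the whole suite.

### Numerical evaluation of the moduli

Each modulus combines a rational function with a multiple of
$\mathrm{artanh}(\eta)/\eta^n$; the two parts cancel through several
orders at $\eta = 0$, so direct evaluation loses precision there.
Evaluation therefore switches to a frozen Taylor series (order 12, exact
rational constants) for $|\eta| < 10^{-2}$ — or $|\eta| < 0.08$ for
$k(\eta)$, whose cancellation runs through $\eta^5$. An independent
series construction by exact convolution of the elementary expansions of
$(1-\eta^2)^{-2}$ and $\mathrm{artanh}(\eta)/\eta$
(`coefficient_series()`) cross-checks the frozen constants, the parity of
each modulus, and the classical-limit values. $\mathrm{artanh}$ is
evaluated as $\tfrac12\log\big((1+\eta)/(1-\eta)\big)$ with a guard band
$|\eta| \le 1 - 10^{-6}$ before the domain error.

## The invagination scenario

The cell-sheet model of Volvox invagination prescribes piecewise
intrinsic profiles on the unit sphere (all lengths in units of the
preinversion radius $R$, $s = 0$ at the posterior pole): meridional
intrinsic curvature $\kappa_p$ in the posterior, $\kappa_b < 0$ in a bend
region $[s_0-w, s_0]$ of wedge-shaped cells, $\kappa_a$ in the anterior;
meridional stretch $f_p < 1$ posterior of $s_0$ (contracting
spindle-shaped cells) and $f_a$ anterior of it. The defaults are the
early-invagination parameter set $\kappa_p=\kappa_a=1$, $\kappa_b=-2$,
$f_p=0.8$, $f_a=1$, $s_0=1.5$, $w=0.2$, $t=0.15$ (appropriate for
*Volvox globator*); `shell_preset("fig5d")` is the later stage
$\kappa_b=-8.5$, $w=0.5$.

Three modelling choices are conventions, fixed here once and exposed for
override via explicit profile input (`read_intrinsic_profile()`):

- $f_\phi^0 = 1$: the posterior contraction is meridional;
- $\kappa_\phi^0$ steps from $\kappa_p$ to $\kappa_a$ at $s_0$ with no
  bend-region amplification (only the meridional curvature is scaled into
  the large-bending regime);
- each step is smoothed by a $\tanh$ transition of width $\delta = 0.05$,
  small compared with the bend width yet resolvable on the default grid
  (the test suite reports the sensitivity of the profiles to $\delta$).

## Equilibrium by energy minimization

Equilibrium shapes minimize $\mathcal E = 2\pi\int \hat e(s)\, r(s)\,
\mathrm d s$ over the deformed tangent angle $\tilde\psi(s)$ and
meridional stretch $\tilde f_s(s)$, with $\tilde\psi(0) = 0$,
$\tilde\psi(\pi) = \pi$ pinned, pole regularity imposed as zero slope of
$\tilde f_s$, and the closure constraint $\int \tilde f_s
\cos\tilde\psi\, \mathrm d s = 0$ enforced by an augmented Lagrangian.
The inner solver is L-BFGS-B with a hand-coded reverse-mode gradient that
is exact for the discrete objective; the solver's internal quadrature is
trapezoidal (so objective and gradient are mutually consistent), while
the reporting-side `total_energy()` uses Simpson quadrature and the
shape reconstruction a fourth-order cumulative rule. The energy
breakdown stored in a `shell_equilibrium` uses the solver's own scheme
and therefore integrates exactly to the minimized objective. The pole
displacement $d$ is read in the anterior-pole-fixed gauge as
$d = 2 - \int \tilde f_s \sin\tilde\psi\,\mathrm d s$ (positive for
invagination); the gauge is a convention — the reference point of $d$ is
not uniquely fixed by the figure it mimics — but the quantity is
manifestly invariant under rigid axial translation.

Defaults: $n = 401$ uniform arclength nodes for single solves (the
fig5a-scenario displacement changes by $8\times10^{-5}$ relative when
doubling to 801), constraint tolerance $10^{-8}$, gradient tolerance
$10^{-6}$. Large-bending solves refuse intrinsic configurations with
$\max|\eta| > 1 - 0.02$: the expansion loses asymptoticity when
$1-|\eta| = O(\epsilon)$, and $0.02 \approx \epsilon h / h$ at the
study's thickness. The margin is overridable with a warning, since the
later-stage scenario of the study itself approaches it.

Degenerate inputs are handled explicitly: the identity scenario
reproduces the undeformed sphere with energy below $10^{-8} C R^3$; an
intrinsically compatible sphere ($f_s^0=f_\phi^0=f$,
$\kappa^0 = 1/f$) relaxes to the stress-free sphere of radius $f$ to
$10^{-4}$ relative. The azimuthal curvature $\sin\tilde\psi/\tilde r$ at
the poles is replaced by its regularity limit $\tilde\kappa_s$, and pole
nodes carry zero area weight, which removes the $r = 0$ singularity from
the discrete energy.

## Continuation and fold detection

The study sweeps the bend curvature magnitude $k = -\kappa_b$ and records
$d(k)$. `continue_branch()` traces the branch in three phases: an
adaptive natural sweep in $k$ (warm-started solves; a displacement jump
persisting at the minimal step $\Delta k = 0.02$ is the signature of a
fold); a mirrored down-sweep along the post-jump branch that locates the
reverse jump, or the smooth merge with the lower branch when the reverse
jump is below the detector's resolution; and, on request, a traversal of
the unstable middle segment, bisecting at each $k$ the unstable
displacement between the two stable ones via the sign change of the
displacement-constraint multiplier $-\partial E/\partial d$ (every
accepted middle point is verified to be a genuine stationary point).
This local-parameterization strategy replaces a Newton pseudo-arclength
scheme, which would need an assembled Hessian of the ~800-dimensional
discretized problem; the jump/merge locations bound the fold positions
to the sweep resolution, which is all the downstream analysis uses.
Continuation runs use $n = 241$, which resolves the profile smoothing
width $\delta$ with about four cells; fold onsets shift visibly on
coarser grids.

`critical_width()` bisects the bend-region width $w$ for the appearance
of a fold. In this implementation the classical model's branch first
folds at $w_0^* \approx 0.25$ (bracket $(0.2, 0.3)$) while the
large-bending branch remains single-valued up to the constriction cap
for all $w \le 1.2$ and first folds near $w^* \approx 1.4$: continuous
invagination survives over a much larger parameter range in the
large-bending theory, the quantitative form of its stabilizing effect.
The individual onset widths are conventions-dependent (they move with
$\delta$, with the azimuthal-profile choices above, and with grid
resolution), so the package treats the ordering $w^* > w_0^*$, the
single-valuedness below onset and the S-shaped multivaluedness with
hysteretic jumps above it — not the onset values themselves — as the
robust, test-asserted structure.

## What the synthetic scenarios do and do not show

The scenario generator reproduces the geometry of the study's driving
fields: piecewise intrinsic profiles, posterior contraction, a narrow
bend region, quasistatic loading. It does not model cell-level
discreteness, the later inversion stages (anterior thinning and peeling),
contact or self-intersection of deeply invaginated shapes, or dynamic
snap-through — jumps are reported from branch geometry, not simulated in
time. Passing tests therefore validate the elastic theory and its
numerics, not a full account of Volvox inversion.

## Known limitations

- The theory itself loses validity as $|\eta| \to 1$; the solver's
  refusal margin makes this explicit rather than silently extrapolating.
- Fold *positions* are resolved only to the sweep resolution
  ($\Delta k = 0.02$, jump threshold $0.05$ in $d$), and near-onset
  S-loops smaller than that resolution are classified as smooth.
- The energy landscape at large widths supports additional equilibrium
  families (e.g. deeply invaginated states coexisting at small $k$)
  beyond the branch connected to the undeformed sphere; the tracer
  reports the connected branch and one unstable sheet between its folds.
- Self-contact is not detected; strongly invaginated shapes with
  $d \gtrsim 1.9$ may be geometrically self-intersecting.
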