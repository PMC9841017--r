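---
title: "Computing small-angle scattering patterns from hypergeometric series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing small-angle scattering patterns from hypergeometric series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperscatter)
```

## The problem

Small-angle X-ray and neutron scattering (SAXS/SANS) measure the intensity
$I(\mathbf q)$ of radiation scattered by nanoscale structure. Modeling a
measurement means computing, for every detector pixel, the orientation- and
size-averaged form factor $\langle P(q)\rangle$ of the constituent particles
and, for ordered assemblies, a lattice factor $\langle Z(\mathbf q)\rangle$.
Done by direct numerical integration this requires one to five nested
quadratures *per pixel* — prohibitively slow for modern megapixel detectors
and for high-throughput fitting.

This package takes a different route. The rotationally symmetric scattering
amplitude of a $d$-dimensional body of size $R$ is a confluent
hypergeometric limit function,
$$F(qR) = {}_0F_1\!\left(\tfrac{d+2}{2}; -\tfrac{q^2R^2}{4}\right),$$
with $d = 3$ for spheres, $d = 2$ for circular cross-sections and $d = 1$
for slabs/lamellae. This function has (i) a power series with recursively
computable coefficients, (ii) a cosine asymptotic expansion, and (iii)
closed-form averages over the Schulz–Zimm size distribution for every term
of both expansions. All expansion coefficients are **q-independent**: they
are computed once, and the per-pixel work collapses to polynomials and a
handful of cosines and arctangents.

## The three evaluation regimes

Every size-averaged squared amplitude ("factor") is evaluated piecewise:

* **Regime I (series).** $\langle F^2\rangle = \sum_n p_n x^{2n}$ with
  $x = qg$ ($g$ the characteristic half-extent). The coefficients fold in
  the Schulz–Zimm moments $\langle s^{2n}\rangle = (z+1)_{2n}/(z+1)^{2n}$
  ($z = 1/\sigma^2 - 1$) and are built by a pure product recursion — no
  Gamma, factorial or Bessel evaluations. The squared amplitude uses the
  single-sum identity
  ${}_0F_1(a;y)^2 = {}_1F_2(a - \tfrac12;\, 2a-1, a;\, 4y)$, which
  collapses the Cauchy double product into one sum.
* **Regime II (trigonometric closed form).** Squaring the $K$-term cosine
  asymptotic expansion yields terms
  $\cos(2xs + \varphi_j)\,(xs)^{-m_j}$ and $(xs)^{-m_j}$, whose Schulz–Zimm
  averages are closed forms in $\sqrt{\lambda^2 + 4x^2}$ and
  $\arctan(2x/\lambda)$ (the complex moment
  $\langle s^{-m} e^{2ixs}\rangle$ of the Gamma law). For $d = 1$ and
  $d = 3$ the "asymptotic" expansion terminates and the regime-II form is
  **exact** for all $x > 0$; for $d = 2$ it is a genuine asymptotic series.
* **Regime III (Porod).** Dropping the oscillating terms leaves the
  non-oscillating asymptote; for polydisperse spheres it reduces to the
  Porod law $\lim q^4 \bar R^4\langle P\rangle =
  9(z+1)^4/\!\left[2z(z-1)(z-2)(z-3)\right]$, which the package evaluates
  in closed form. Size dispersion is what kills the oscillations: a
  monodisperse model has no regime III (`q23 = Inf`).

The regime boundaries are located automatically at pre-computation time by
scanning for the window in which adjacent evaluators agree (relative to the
non-oscillating envelope) to `boundary_tol` (default $10^{-6}$), subject to
a cancellation guard that rejects series evaluations whose largest
intermediate term exceeds $10^{12}$ times the sum. The boundary itself
belongs to the lower regime.

### Why the $d = 2$ factor uses five asymptotic terms

Two asymptotic terms are exact for $d \in \{1,3\}$ (the third coefficient
vanishes). For $d = 2$ the two-term truncation error crosses $10^{-4}$ of
the envelope only at $x \approx 34$, while the alternating series loses its
last four digits (guard limit $10^{12}$) near $x \approx 31$: in double
precision the two expansions never overlap at $10^{-4}$. The cross-section
factor therefore carries five asymptotic terms (error $< 2\times10^{-5}$
from $x \approx 6$), generated by the same coefficient recursion
$c_k = -c_{k-1}\,[4\mu^2-(2k-1)^2]/(8k)$, $\mu = d/2$. With five terms the
overlap window is wide and the end-to-end $10^{-4}$ target is met with
margin.

## Shape assembly and polydispersity conventions

Anisometric bodies are products of factors evaluated on **pre-computed
orientation nodes** (Gauss–Legendre grids in $\cos\theta$ and $\varphi$),
so that the per-$q$ cost stays a short node sum of closed forms:

* cylinder/disk: axial $d=1$ factor (half-length $L/2$, so that the $qL$
  phase convention reproduces the textbook $\sin(qL/2)/(qL/2)$ rod
  amplitude) times the $d=2$ cross-section; **independent** Schulz laws per
  dimension, and the Regime-I polynomial is assembled with the exact Beta
  moments $\int_0^1 t^{2m}(1-t^2)^k\,dt$;
* biaxial/triaxial ellipsoids: the $d=3$ factor at the direction-dependent
  effective radius $R_{\text{eff}}(\theta,\varphi) = (a^2\sin^2\theta
  \cos^2\varphi + b^2\sin^2\theta\sin^2\varphi + c^2\cos^2\theta)^{1/2}$,
  with a **common shape-preserving scale** polydispersity. A per-semi-axis
  dispersion couples the axes inside $R_{\text{eff}}$ and destroys the
  closed-form Regime-II average, so the common-scale law — physically, a
  particle population of identical shape and dispersed overall size — is
  the package's convention for the ellipsoid class;
* parallelepiped: three independent $d=1$ factors along the body axes,
  with the closed double-factorial direction moments
  $\langle u_1^{2i}u_2^{2j}u_3^{2k}\rangle$;
* cube: a parallelepiped of equal edges with a **common scale**, which
  couples the three sinc factors inside the size average. Products of
  $(1-\cos 2x_is)$ are expanded into single cosines of combined
  frequencies, each a closed-form Gamma moment
  $\langle s^p\cos(\mu s)\rangle$; axes with $x_i < 0.05$ switch to a short
  polynomial to avoid cancellation in $(1-\cos)/x^2$.

Number-weighted averaging of the volume-normalized amplitude is the
default; `weighting = "intensity"` applies the $V^2$ weighting, which for
the Gamma law is exactly a shift of the shape parameter
($\alpha \to \alpha + 2d_V$) and costs nothing.

Orientation-node counts default to 256 (axisymmetric shapes) and
$96\times96$ (triaxial ellipsoids, parallelepipeds, cubes). These were
chosen so that the node quadrature converges spectrally over the intended
$q$-range ($q\,g \lesssim 60$): halving them reproduces the documented
$10^{-4}$ accuracy margin no longer, doubling them changes results by less
than $10^{-8}$.

## Oriented particles

For a cylinder whose axis deviates from the director $\hat x$ by $\delta$
with density $h(\delta)$, the even powers of the axial phase average to
$$\langle (\mathbf q\cdot\mathbf u)^{2n}\rangle = \frac{(2n)!}{4^n}
\sum_{l=0}^n \frac{4^l}{(2l)!\,((n-l)!)^2}\,q_x^{2l} q_y^{2(n-l)}
H_{2l,2n-2l},$$
with the q-independent orientation integrals
$H_{2l,2m} = \langle \cos^{2l}\!\delta\,\sin^{2m}\!\delta\rangle$ over the
measure $h(\delta)\sin\delta\,d\delta$. The longitudinal series is exposed
in its factorized form $\sum_n a_n \sum_l b_{l,n} (q_x^2)^l(q_y^2)^{n-l}$
with pre-computed $a_n$, $b_{l,n}$. The full oriented form factor couples
the axial factor to the cross-section through the transverse component
$q_t^2 = q^2 - (\mathbf q\cdot\mathbf u)^2$ *per orientation node*, which
makes the isotropic limit agree with the 1D orientational average to
$10^{-4}$ — a strictly factorized longitudinal-times-transverse
approximation does not. Below the series radius the coupled polynomial in
$(q_x^2, q_y^2)$ is used; beyond it the phase average runs over the
pre-computed $(\delta, \chi)$ nodes with closed-form size averages.

The distribution family for partially oriented samples is a wrapped
Gaussian cone $h(\delta) \propto \exp(-\delta^2/2w^2)$ on $[0, \pi/2]$; its
order parameter $S = (3H_{2,0}-1)/2$ sweeps from 1 (aligned, $w \to 0$)
through 0 (isotropic) as $w$ grows, covering the headline oriented-pattern
series.

## Ordered assemblies

The unit cell $(a,b,c;\alpha,\beta,\gamma)$ is built in the standard
crystallographic Cartesian frame, rotated so the chosen $(uvw)$ direction
is beam-parallel, and inverted to the $2\pi$-convention reciprocal basis
(duality residuals $< 10^{-10}$). Reflections are enumerated inside a
rigorous index bound $|h| \le \lceil q_{\max} a/2\pi\rceil$ under the
SC/BCC/FCC parity rules or an explicit basis sum, and are closed under
Friedel inversion. The lattice factor is
$$Z(\mathbf q) = 1 + \frac{(2\pi)^3}{V_{\text{cell}}}\sum_{hkl}
|\hat f_{hkl}|^2\, L(\mathbf q - \mathbf q^*_{hkl}),$$
with $L$ a unit-integral 3D Gaussian (or Lorentzian-squared/pseudo-Voigt)
peak and $|\hat f|^2$ normalized per basis atom. The baseline $Z \to 1$ far
from all peaks makes the decoupling correlation term
$\beta(\langle Z\rangle - 1)G(q)$ vanish there; the amplitude prefactor
$(2\pi)^3/V_{\text{cell}}$ is a convention (peak heights trade off against
the width $\sigma_q$), chosen so that the reciprocal-space average of
$Z - 1$ is the mean $|\hat f|^2$. The powder (Debye–Scherrer) average has
the exact closed form of a spherical average of the 3D peak, so 1D curves
need no numerical azimuthal integration. The Debye–Waller factor is
$G(q) = \exp(-\sigma_{DW}^2 q^2)$.

Intensities follow the decoupling approximation
$$I = (\Delta b)^2 \rho_N \langle P\rangle\left[1 +
\frac{\langle F\rangle^2}{\langle P\rangle}(\langle Z\rangle - 1)\,
G(q)\right],$$
with $\beta = \langle F\rangle^2/\langle P\rangle$ clipped to $[0,1]$;
together with $Z \ge$ baseline and $G \in [0,1]$ this forbids negative
intensities, which the code asserts.

## Detector mapping and grazing incidence

Pixel centers map to q-space in the small-angle approximation
$q = \tfrac{2\pi}{\lambda d}(x, y, 0)$ or through the exact elastic map
$q = \tfrac{2\pi}{\lambda}(\sin\vartheta\,x/r, \sin\vartheta\,y/r,
1-\cos\vartheta)$; the two agree to better than $10^{-3}$ below
$\vartheta = 2^\circ$. Patterns can be blurred by a direct-sum PSF
convolution with replicate padding (kernels are small; intensity is
conserved away from the borders).

Grazing-incidence patterns use the four-channel distorted-wave Born
approximation: with Fresnel amplitudes $r = (k_z - k_{z,t})/(k_z +
k_{z,t})$, $t = 2k_z/(k_z + k_{z,t})$ for the film index
$n = 1 - \delta + i\beta$,
$$I_G = |T_i|^2|T_f|^2\left[I(q_1) + |R_i|^2 I(q_2) + |R_f|^2 I(q_3) +
|R_i|^2|R_f|^2 I(q_4)\right],$$
where the channels share the in-plane momentum and carry the four sign
combinations $\pm k_{z,f} \mp k_{z,i}$. $T_i, R_i$ are q-independent and
pre-computed; $T_f, R_f$ vary per detector row. The beam-center row is the
sample horizon, rows below it are shadowed. The $|T_f|^2 = 4$ maximum at
the critical exit angle produces the Yoneda band. In the film frame the
beam-parallel component of $\mathbf q$ is negligible at grazing angles, so
the vertical channel $q_z$ maps onto the second in-plane lattice
coordinate — beam along the $(001)$ cell direction then yields the $(hk0)$
fiber pattern characteristic of supported nanoparticle lattices.
Incident-plane specular and diffuse contributions are out of scope.

## The oracle

The validation reference computes $\langle P(q)\rangle$ by direct nested
quadrature of the closed-form amplitudes over the size law(s) and the
orientation sphere — it shares nothing with the series engine but the
amplitudes themselves. Gauss–Legendre nodes are sized to the largest phase
$q_{\max} g$; level $L$ is certified by a level-$(L{+}1)$ evaluation
(all node counts doubled) on a $q$ subsample, to a default relative
tolerance $10^{-6}$, well below the $10^{-4}$ validation target. Size
integrals are truncated at $\bar R(1 \pm 8\sigma)$, clipped to positive
sizes and renormalized; 1D size averages for the factorizable shapes are
tabulated on oscillation-resolving grids whose density doubles with the
certification level. The five-dimensional parallelepiped case uses the
same deterministic tensor quadrature rather than Monte-Carlo sampling. A
log-normal size family of matched mean and relative width is available in
the oracle only, as a sensitivity check on the distribution-family choice
(it changes polydisperse curves at the percent level).

`oracle_compare()` reports maximum and mean relative deviations, a
per-regime breakdown and wall times of both routes. On the benchmark
fixtures (axial ratios 3–8, $\sigma = 0.1$, 200-point Guinier-to-Porod
grids) the maximum relative deviation is below $2\times10^{-5}$ for every
shape, and the series route — including its pre-computation — is one to
three orders of magnitude faster than the oracle, with the gap growing
with the number of evaluation points because the pre-computation is a
fixed cost (the low-N plateau).

## What the fixtures do and do not show

The presets in `fixture_presets()` (a 3 nm sphere and a 2/4/6 nm triaxial
ellipsoid at $\sigma = 0.08$; an oriented-cylinder series sweeping
$S = 1 \to 0$; 14 nm spheres on a 35 nm FCC lattice; 10 nm spheres on a
22 nm BCC lattice under grazing incidence) reproduce the geometry and
polydispersity of typical self-assembled nanoparticle systems. Passing
tests on them shows that the *computational* claims hold — series,
asymptotics and quadrature agree to the stated precision, symmetries and
limits are exact. It does not show that any particular experimental
material is described by these models: real data add instrumental
resolution beyond the PSF, inter-particle interference beyond the
decoupling approximation, multiple scattering, and size laws that need not
be Schulz–Zimm.

Default test and validation problem sizes (200-point curves,
$64^2$–$256^2$-pixel patterns, $96^2$ orientation grids) are the package's
regression scale, chosen to exercise every regime of every shape; all
engines accept larger grids unchanged.

## Known limitations

* Shapes with non-smooth superball/superellipsoid exponents, dumbbells,
  lenses, octahedra and flexible chains are not implemented.
* Ellipsoid-class polydispersity is a common scale factor, not per-axis.
* Core–shell density profiles are absent: the density is uniform, so the
  contrast enters only through $(\Delta b)^2$.
* The lattice model is a single ideal crystallite orientation (or its
  powder average) with one peak-width parameter; paracrystalline disorder
  of the second kind and finite-size Scherrer broadening are not modeled.
* GISAS covers a single film on a substrate; multilayers and the
  incident-plane specular/diffuse terms are out of scope.
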