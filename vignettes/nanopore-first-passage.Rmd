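---
title: "Methods: drift-diffusion first-passage calculations for charged polymers in nanopores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift-diffusion first-passage calculations for charged polymers in nanopores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porefpt)
```

## The model

A linear biopolymer captured in a nanopore is described by a single
coordinate: the length of chain $x \in [0, L]$ that has passed through the
pore, where $L = N\,l_{aa}$ is the contour length of a chain of $N$ residues at
$l_{aa}$ nm per residue. Its motion is an overdamped drift-diffusion
(Smoluchowski) process in a potential of mean force $U(x)$, measured in units
of $k_BT$:

$$\mathrm{d}x = -D\,U'(x)\,\mathrm{d}t + \sqrt{2D}\,\mathrm{d}W_t .$$

Arrival at $x = 0$ is retraction (escape back to the capture side); arrival at
$x = L$ is translocation. The experimentally observable quantities are the
splitting probabilities $\pi_0$ and $\pi_L$ of the two outcomes and the mean
escape times: conditional ($\tau_0$, $\tau_L$) and unconditional
$\tau = \pi_0\tau_0 + \pi_L\tau_L$. With both boundaries absorbing these are
spatial integrals over $U$:

$$\pi_L(x_0) = \frac{\int_0^{x_0} e^{U(y)}\,\mathrm{d}y}
                    {\int_0^{L} e^{U(y)}\,\mathrm{d}y},$$

and $g(x) \equiv \pi_L(x)\,\tau_L(x)$ solves the stationary backward equation
$D\,e^{U}\left(e^{-U} g'\right)' = -\pi_L$ with $g(0) = g(L) = 0$, giving

$$g(x_0) = \frac{1}{D\,\Phi(L)}\left[\frac{J(L)\,\Phi(x_0)}{\Phi(L)} - J(x_0)\right],
\qquad
\Phi(x) = \int_0^x e^{U},\quad
J(x) = \int_0^x e^{U(z)} \int_0^z e^{-U(y)}\,\Phi(y)\,\mathrm{d}y\,\mathrm{d}z .$$

The retraction branch $\pi_0\tau_0$ is the same construction on the reflected
potential $U(L - x)$ started from $L - x_0$. For a *tethered* polymer one end
is anchored above the pore, translocation is impossible ($\pi_L = 0$ exactly),
the boundary at $L$ is reflecting, and

$$\tau(x_0) = \frac{1}{D}\int_0^{x_0} e^{U(y)}\int_y^L e^{-U(z)}\,\mathrm{d}z\,\mathrm{d}y .$$

These forms are the unique solutions of the backward Kolmogorov equation with
the stated boundary conditions; the package validates them against the
closed-form zero-potential limits and against brute-force trajectory
simulation (below).

## Constructing the potential

`nanopore_fpt()` assembles $U(x)$ as a plain sum of terms on a shared grid.

**Electrokinetic term.** Each residue carries an integer charge (D, E: $-1$;
H, K, R: $+1$; X, denoting a double-stranded base pair or phosphorylated
residue: $-2$; all others 0), plus $+1$ on the chemical N-terminal residue
(free amine) and $-1$ on the C-terminal one (free carboxyl). The charge is
smeared over the pore: a Gaussian of standard deviation
$\sigma_p = L_p / (2\sqrt{2\ln 2})$ per residue, so the pore length $L_p$ is
the kernel's FWHM. Each residue's Gaussian is divided by its own integral over
$[0, L]$ so that the residue contributes exactly $z_i$ elementary charges even
where the kernel is clipped by the domain ends. Electroosmotic flow (EOF) drags
on the chain in proportion to the driving field, so the effective density is
the linear correction $\sigma = m_{\rm EOF}\,\sigma_n + b_{\rm EOF}$: the slope
rescales the polymer's own charge (a geometric factor of the pore) and the
intercept accounts for fixed charge on the pore walls. The work done by the
transmembrane potential $V$ on the threaded charge is then

$$U_E(x) = \frac{V}{V_T} \int_0^x \sigma(y)\,\mathrm{d}y,$$

with $V_T = k_BT/e$ the thermal voltage, so $U_E$ is in $k_BT$ when $V$ is in
mV and $\sigma$ in $e^-$/nm.

**Entropy.** For a free chain both tails gain conformational entropy as they
leave the pore, giving the symmetric logarithmic well
$U_S(x) = \nu[\ln(x/L) + \ln(1 - x/L)]$ with Flory exponent $\nu$. For a chain
tethered a distance $l_t$ above the pore, the entropy comes from the
propagator of a non-self-avoiding Gaussian chain of Kuhn length $b$ with
$n_C = (x - L_p/2)/b$ segments translocated and $n_T = (L - x - L_p/2)/b$ not:

$$U_S(x) = -\ln\!\left[\left(\tfrac{2\pi n_C b^2}{3}\right)^{-3/2}
\left(e^{-3(l_t-\delta)^2/2 n_C b^2} - e^{-3(l_t+\delta)^2/2 n_C b^2}\right)
\operatorname{erf}\!\left(\sqrt{\tfrac{3}{2 n_T}}\,\tfrac{\delta}{b}\right)\right] + C,$$

with $\delta$ a small regularisation distance. The additive constant is fixed
by shifting the minimum over the valid region to zero; every first-passage
observable is exactly invariant to this choice (tested).

**Auxiliary terms.** A constant force $U_F = Fx$ (osmotic/hydrodynamic
pressure), a Gaussian $U_G = E_G e^{-(x - x_G)^2/2\sigma_G^2}$ (a bulky side
chain, $E_G > 0$, or an attractive site, $E_G < 0$), and an erf step
$U_B = E_B \operatorname{erf}[(x - x_B)/\sigma_B\sqrt{2}]$ (membrane-binding
energetics); opposite steps offset in $x_B$ compose into smoothed box
potentials.

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| $l_{aa}$ | nm | 0.4 | length per residue (0.34/bp for ssDNA; 34 for a 100-bp surrogate unit) |
| $L_p$ | nm | 3.5 | pore length = FWHM of the charge-smoothing kernel (VDAC-like) |
| $m_{\rm EOF}$ | — | 0.654 | EOF slope; ~0.1 for solid-state pores, near 1 for biological pores |
| $b_{\rm EOF}$ | $e^-$/nm | $-0.21$ | EOF intercept from pore-wall charge (0 for a neutral lumen) |
| $\nu$ | — | 0.59 | Flory exponent of a self-avoiding chain |
| $b$ | nm | 0.6 | Kuhn length |
| $l_t$ | nm | 0 | tether distance above the pore |
| $\delta$ | nm | $10^{-3}$ | tether-propagator regularisation distance |
| $D$ | µm²/s | 1 | effective diffusion constant in the pore (typically 0.1–10) |
| $V_T$ | mV | 25.693 | thermal voltage $k_BT/e$ at 25 °C |

The EOF defaults were estimated for the voltage-dependent anion channel
(VDAC) with α-synuclein; the default $L_p$ matches that membrane thickness.
The temperature enters only through $V_T$ (and the 4.114 pN·nm conversion
used by `pn_to_kbt_nm()`), both configurable.

## Numerical choices

* **Grid.** All profiles live on a uniform grid of spacing $l_{aa}/2$ with
  both endpoints included. This favours speed over accuracy: quadrature error
  grows when $U$ changes by more than ~1 $k_BT$ per grid interval (for the
  10-kbp surrogate at 34 nm/residue this happens beyond roughly ±10 mV, where
  computed times still track a 1 nm reference grid to ~20%). Any finer grid
  can be passed explicitly.
* **Charge normalisation.** The per-residue normalisation integral is
  evaluated by the trapezoid rule *on the same grid as the profile*, so the
  trapezoidal integral of the density recovers the total polymer charge
  exactly by construction — even when the grid badly under-resolves
  $\sigma_p$, as it does for the 34 nm/residue surrogate. When the grid does
  resolve the kernel, the normalisation converges to the analytic
  $\sigma_p\sqrt{2\pi}$ (tested). A kernel-resolving ("locally refined")
  normalisation was rejected because it breaks exact charge conservation on
  the working grid, which the electrokinetic tilt $U_E(L)$ depends on.
* **Log-space integration.** At high voltage $|U|$ reaches thousands of
  $k_BT$, so $e^{\pm U}$ overflow doubles. Every integral of an exponential is
  a cumulative trapezoid accumulated with a running log-sum-exp; ratios and
  the nested double integrals are combined in log space and exponentiated
  last. This is exactly invariant to additive shifts of $U$ and cannot
  overflow. The same treatment stabilises the tethered entropy near the pore
  wall, where the propagator prefactor diverges while the Gaussian difference
  underflows; at $l_t = 0$ the Gaussian difference vanishes identically and
  its analytic $l_t \to 0$ limit is used instead (the dropped factor is an
  additive constant).
* **Endpoints and clamps.** The free entropy diverges logarithmically at
  $x = 0, L$; endpoint values are replaced by the value half a grid spacing
  inside, preserving the well shape while keeping $e^{\pm U}$ integrable (the
  $x^{-\nu}$ endpoint singularity of $e^{-U_S}$ makes quadrature there
  converge as $O(h^{1-\nu})$ — slow but convergent, checked by grid halving).
  The tethered entropy is only defined on $(L_p/2, L - L_p/2)$; outside, the
  profile is clamped to the nearest valid value plus 25 $k_BT$, an effectively
  reflecting wall for a region the physics makes inaccessible anyway.
* **Injection point.** The initial position is the grid minimum of $U$ within
  a user range, ties broken toward smaller $x$ (deterministic); a degenerate
  range pins $x_0$ to the nearest grid node, and the injection point is
  treated as a delta function. Conditional times are reported as `NaN` with a
  warning when the corresponding splitting probability is below $10^{-12}$.
* **Units.** Voltages in mV, lengths in nm, $D$ accepted in µm²/s and
  converted once ($\times 10^6$) to nm²/s, times reported in seconds.

## Validation strategy

Two independent oracles cross-check the integration engine:

1. **Closed forms.** At $U \equiv 0$ the free case has
   $\pi_L = x_0/L$, $\tau_0 = \frac{L^2}{2D}u\frac{2-u}{3}$,
   $\tau_L = \frac{L^2}{2D}(1-u)\frac{1+u}{3}$,
   $\tau = \frac{L^2}{2D}u(1-u)$ with $u = x_0/L$, and the tethered case has
   $\tau = \frac{L^2}{2D}u(2-u)$. `validate_engine()` sweeps
   $u \in \{0.05, \dots, 0.95\}$ on a 100 nm chain at $D = 1$ nm²/s and
   reports maximum relative errors; the engine agrees to machine-level
   precision there (the leading trapezoid errors of the nested integrals
   cancel in the $g$ combination for polynomial integrands), far inside the
   ~1 % accuracy target appropriate to a design tool.
2. **Trajectory simulation.** `simulate_langevin()` integrates the
   Euler–Maruyama discretisation with the drift interpolated linearly from
   central differences on the grid (C++ core, R RNG, seed-reproducible). A
   step landing beyond a boundary is absorbed; in addition a Brownian-bridge
   within-step crossing test (crossing probability
   $e^{-(b-x)(b-x')/D\,\mathrm{d}t}$ for boundary $b$) catches unobserved
   excursions. Without it, end-of-step detection biases escape times upward
   by $O(\sqrt{\mathrm{d}t})$ — measured at +2.3 % under the test conditions,
   which would not sit reliably within the three-standard-error comparison
   band; with it the residual bias is below the Monte-Carlo noise. The
   reflecting wall (tethered mode) keeps plain end-of-step specular
   reflection, whose smaller bias is handled by a finer step in those tests.
   The test suite compares the engine against 20 random smooth potentials
   ($|U| \le 5\,k_BT$, sums of up to three Gaussian/step terms on a 30 nm
   chain, $10^4$ trajectories, rms step of half a grid spacing) and requires
   agreement of $\pi_0$, $\pi_L$ and $\tau$ within three standard errors.

The oracle emulates the model's own idealisation — one-dimensional motion in
a static potential with a constant diffusion coefficient. Agreement therefore
shows the spatial integration is correct; it says nothing about physics the
model omits (see limitations).

## The dsDNA surrogate

A worked reference case models the escape of 10-kilobase-pair double-stranded
DNA ($L = 3400$ nm, measured $D = 7.10$ µm²/s, charge density magnitude
0.275 $e^-$/nm) from a solid-state pore. Rather than 10 000 individual bases,
the chain is the 100-residue surrogate `A(E)98X` at 34 nm per residue: with
the terminal corrections ($+1$ on A, $-1$ extra on X) it carries exactly
$-100\,e$, and the EOF slope $m_{\rm EOF} = 9.35$ (intercept 0) scales the
mean effective density to $-0.275\,e^-$/nm:

```{r dsdna}
s <- parse_sequence(paste0("A", strrep("E", 98), "X"), laa = 34)
eff <- effective_charge_density(native_charge_density(s, Lp = 10),
                                m_eof = 9.35, b_eof = 0)
total_charge(eff) / s$L
```

Choices this case required that the configuration itself does not fix: the
solid-state pore length is not part of the reference numbers, and 10 nm (a
typical solid-state membrane) is used — it only sets the smoothing width, not
the conserved charge or the mean density. The injection point is forced to
mid-chain ($x_0 = L/2$) through a degenerate injection range: with the
free-chain entropy on, $U$ has no interior minimum at nonzero voltage (the
entropic wells sit at the boundaries), so a full-range minimum search would
start the dynamics on an absorbing boundary. The resulting escape-time curve
is positive and single-peaked, with the peak at sub-mV voltages — the
splitting transition width is set by $V_T/|\Sigma|$ with
$\Sigma \approx 935\,e$ the total effective charge, i.e. hundredths of a mV.
One genuine feature of the *surrogate* (not of uniform DNA): at voltages below
about $-12$ mV the EOF-amplified $+9.35\,e$ charge on the first residue forms
a deep well near $x = 0$ that Kramers-delays retraction, so the escape time
turns back up; the monotone drift-dominated decay is therefore probed over
$|V| \le 10$ mV in the tests.

## Problem sizes in the test suite

Deterministic checks run on 100–500-residue chains (201–1001 grid points) and
complete in milliseconds. Stochastic checks use $10^4$ trajectories per
comparison on a 30 nm chain (the engine-versus-simulator sweep over 20 random
potentials) and 4000–8000 trajectories for the flat-potential and reflecting
cases; these sizes give ~1 % standard errors, matching the precision the
comparisons assert.

## Known limitations

* Charges are integer and pH-independent; no fractional protonation, and no
  post-translational modification beyond the X code.
* The diffusion coefficient is constant in $x$ by design.
* Only the zeroth and first moments of the escape-time distributions are
  computed, not the full distributions.
* The fixed $l_{aa}/2$ grid is chosen for speed; steep electrokinetic tilts
  (more than ~1 $k_BT$ per grid interval) degrade quadrature accuracy, and
  the $O(h^{1-\nu})$ endpoint convergence of entropic integrands is slow.
* The tethered entropy uses a non-self-avoiding Gaussian chain; its additive
  constant is conventional (minimum set to zero), so absolute $U$ values in
  that mode are defined only up to a constant — observables are unaffected.
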