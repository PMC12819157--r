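---
title: "Models and methods behind poreflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poreflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

poreflux models two nonlinearities of ion transport through β-barrel protein
nanopores such as aerolysin: *open-pore rectification* — the asymmetry of the
current–voltage (IV) curve set by the fixed charges lining the lumen — and
*voltage-driven gating* — the abrupt, stochastic collapse of the pore into a
low-conductance state beyond a critical voltage. It also implements the a.c.
ensemble analysis used to quantify gating, a displacement-based ionic-current
estimator for molecular-dynamics-style ion trajectories, and a synthetic-data
generator that closes the loop between simulation and analysis.

## Open-pore electrodiffusion model

The pore is a cylinder of radius $a$ (default 0.7 nm, i.e. a 1.4 nm
constriction) and length $L$ (default 10 nm) in a symmetric 1:1 electrolyte
(default 1 M KCl at 298 K). Rings of fixed charge at axial positions $z_i$
(valence $q_i$, multiplicity $m_i$, e.g. 7 for a heptamer) define a
dimensionless potential landscape per ion species $s$ (valence $z_s = \pm
1$):

$$
W_s(z) = \frac{z_s e V}{k_B T}\Bigl(1 - \frac{z}{L}\Bigr)
  + \sum_i z_s q_i m_i \,\ell_B \frac{e^{-d_i/\lambda}}{d_i},
\qquad d_i = \sqrt{(z - z_i)^2 + a^2},
$$

an on-axis screened-Coulomb (Yukawa) approximation of each ring with Bjerrum
length $\ell_B = 0.7$ nm and screening length $\lambda$ defaulting to the
Debye length of the electrolyte (0.30 nm in 1 M KCl); both are overridable.
The external voltage enters as a uniform field across $[0, L]$ (access
resistance and Donnan edge potentials are neglected — the simplest model
consistent with a localized-charge picture).

The steady-state Nernst–Planck flux for each species follows by exact
quadrature. We impose boundary concentrations in local Boltzmann equilibrium
with the *charge* part of the landscape, $c_s(0) = c_0
e^{-W_{c,s}(0)}$ and likewise at $L$. With that choice

$$
J_s = \frac{D_s c_0\,(e^{z_s e V / k_B T} - 1)}{\int_0^L e^{W_s(z)}\,dz},
\qquad I = \pi a^2 e\,(J_+ - J_-).
$$

When the ring potentials vanish at the pore mouths this is identical to the
textbook Dirichlet-at-$c_0$ expression, but unlike it the current vanishes
*identically* at $V = 0$ for any charge set — with plain Dirichlet
boundaries, a ring near a mouth leaks a spurious equilibrium current. The
familiar limits are exact: with no charges the model reduces to the
Goldman-type ohmic line $I = \sigma \pi a^2 V / L$ with the Nernst–Einstein
conductivity $\sigma = N_A e^2 c_0 (D_+ + D_-)/k_B T$ (about 2.3 nS for the
default geometry, the bulk-limited value of roughly 2 nS quoted for
aerolysin-sized pores).

Rectification is quantified by $\beta = (I_+ - |I_-|)/(I_+ + |I_-|)$ at
$\pm 100$ mV. Two exact symmetries constrain the model and are enforced in
tests: $I(V; \{q_i\}) = -I(-V; \{-q_i\})$ for equal diffusivities, and the
mirror relation $I(V; \text{mirror}) = -I(-V)$, whence $\beta(z; q) =
\beta(L - z; -q)$. Note that a charge set that is *antisymmetric* under the
mirror (positive ring near one mouth, negative near the other) is a bipolar
nanofluidic diode and genuinely rectifies; only a plainly mirror-symmetric
set forces $\beta = 0$.

### Numerics

The landscape is sampled on a uniform grid of 4096 points (512 is the
validity floor; at the default resolution doubling the grid changes the
current by less than $10^{-6}$ relative even for Debye-scale wells). The
integral $\int e^{W}$ uses piecewise-exponential (exponentially fitted)
quadrature — exact when $W$ is piecewise linear — so the neutral-pore ohmic
limit holds to machine precision rather than to the $\mathcal{O}(h^2)$ error
of the trapezoidal rule. Potentials are clipped at $\pm 50\,k_BT$ with a
warning; all exponentials are evaluated with a max-shift to avoid overflow.
An independent finite-difference steady-state solver (central differences,
Thomas algorithm) serves as an oracle in the test suite and agrees with the
quadrature to better than $10^{-4}$ relative on random charged pores.

## Two-state gating kinetics

Gating is modelled at the phenomenological level: each pore is either open
or gated (closed), with voltage-dependent rates

$$
k_\text{close}(V) = A\,\exp\!\bigl((|V| - V_c)/v_e\bigr)
\quad\text{for } |V| > V_c \text{ and matching polarity, else } 0,
$$

and a constant reopening rate $k_\text{open}$ active only when $|V|$ is
inside a reopening window *and* the voltage does not exceed a small release
voltage on the closing side. The exponential form above $V_c$ is a choice
(the functional form is not constrained by the data the package emulates);
the hard threshold and zero opening rate above $V_c$ are the defining
features. Defaults: $V_c = 100$ mV, $A = 1$ s$^{-1}$, $v_e = 40$ mV,
$k_\text{open} = 50$ s$^{-1}$, window 150 mV, release 60 mV — an
aerolysin-wt-like negative gater with closing rates of order 1–10 s$^{-1}$
over the experimental voltage range.

Two of these choices deserve justification. First, *polarity-gated
reopening*: a pore held at a substantial bias of its closing polarity (e.g.
−90 mV for a negative gater) neither closes nor reopens, which is exactly
how the synaptic pulse protocols are designed (a −90 mV baseline "holds"
the state, +110 mV pulses open, −110 mV pulses close). A sign-blind
reopening window cannot reproduce that: the depression pulses themselves
would reopen pores and depression would stall at a half-open plateau.
Second, a *large* $k_\text{open}$: reopening completes within a few tens of
milliseconds once the voltage enters the release region, so by the time a
sweep reaches the $\pm 50$ mV window used for pore counting the ensemble is
fully open — the analysis pipeline's "no gating near $V = 0$" premise.

Each closing event draws a fresh gated-conductance ratio $\epsilon_i$ from a
normal distribution truncated to $(0, 1)$ with mean 0.14 and sd 0.05: the
gated state conducts 14% of the open-pore current on average, with the wide
event-to-event diversity seen in single-pore recordings. The sd is a
placeholder calibrated only by that qualitative diversity; it is exposed as
a parameter.

The ensemble simulator advances all pores with per-step Bernoulli draws,
probability $1 - e^{-k\,dt}$. This is exact (in distribution at the sample
times) while only one rate is active; steps where closing and reopening
compete are subdivided so that $k\,dt_\text{sub} < 0.05$. Rates are averaged
over an 8× refined voltage sub-grid per step, so a hard switch ($V_c$, the
release edge) crossing mid-step is weighted by the fraction of the step it
is active; remaining time-discretization bias is $\mathcal{O}(k\,dt/8)$ and
the sampling rate is the accuracy knob. The mean-field ODE
$\dot p = k_\text{close}(1-p) - k_\text{open}\,p$ (solved with `deSolve`)
is the deterministic oracle; a 2000-pore simulation matches it within the
pointwise binomial band.

## The a.c. analysis pipeline

`analyze()` reproduces the ensemble analysis chain:

1. **Cycle segmentation** at protocol phase zero-crossings, resampling each
   complete cycle onto a 2048-point phase grid.
2. **Pore count** $N_p$ per cycle: the slope of a linear regression of
   ensemble current on the single-pore open-IV current inside $|V| < 50$ mV,
   where no gating takes place. Cycles with non-positive slope or
   $R^2 < 0.5$ are excluded (a numeric proxy for discarding membranes with
   oppositely inserted pores or instability).
3. **Normalization**: cycles are combined by an $N_p$-weighted mean and
   divided by the open-pore current $I_O(\phi)$.
4. **Closed probability** by inverting the two-state conductance relation
   $I/I_O = 1 - p(1 - \epsilon)$ with $\epsilon = 0.14$:
   $p = (1 - I/I_O)/(1 - \epsilon)$. The ratio is ill-defined around the
   origin, so samples with $|V| < 20$ mV are masked (the width is not
   dictated by the underlying experiments; 20 mV is our default and it is
   configurable). Reported $p$ is clipped to $[0,1]$; raw values are kept
   for QC.
5. **Closing rate** $k_X$: the maximum of $dp/dt$ over the rising-$|V|$
   half of each polarity, using a local-quadratic (Savitzky–Golay)
   derivative with a window of 1/64 cycle. The window trades curvature bias
   against noise amplification; at the default study conditions it
   underestimates the true peak slope by a few percent while keeping the
   noise-driven overestimate of a maximum in check. It is exposed in the
   configuration. $k_X$ is reported in s$^{-1}$ on the true time axis and is
   invariant to current gain and pore count by construction.
6. **Rectification factor** from the rising-$|V|$ sweep branches of each
   retained cycle (where pores that reopened near $V = 0$ have not yet
   gated), interpolated at $\pm 100$ mV and $N_p$-weighted.

The simulator→analyzer round trip recovers $p(\phi)$ within three binomial
standard errors, $k_X$ within 15% of the ODE's peak closing flux
$\max_t[k_\text{close}(V(t))(1 - p(t))]$, and $\beta$ within 0.02 of the
generating pore's value, at 26 pores and 50 cycles of a 0.1 Hz, 200 mV
sinusoid.

**Ergodicity.** The time-averaged loop of one pore over 50 cycles is
compared with the ensemble average of 50 pores over one cycle on a common
per-branch voltage grid (24 bins per sweep direction). With sharply
voltage-dependent closing ($v_e$ of a few mV, so the closing phase is nearly
deterministic) the two agree to better than 0.05 in normalized current —
the regime in which a 50-sample average is statistically capable of showing
the equivalence. With shallow voltage dependence the closing phase is
stochastically spread and the per-bin sampling error alone exceeds that
bound; this is a statistical property of the comparison, not a failure of
ergodicity.

**D.c. level segmentation** thresholds the current histogram at the density
minimum between its two highest modes (falling back to the midpoint of the
extreme quantiles), keeps contiguous runs of at least 5 ms as levels, and
reports per-event gated/open ratios. Over 200 synthetic single-pore traces
the grand-mean ratio recovers the generator's 14% within a percentage
point.

## Displacement current from ion trajectories

For framewise ion positions the instantaneous current is

$$
I(t) = \frac{1}{\Delta t\,L_p} \sum_\text{ion} Q_\text{ion}
\bigl[z_\text{ion}(t + \Delta t) - z_\text{ion}(t)\bigr],
$$

summing ions inside the lumen at frame $t$ (defaults $\Delta t = 0.2$ ns,
$L_p = 9$ nm, the β-barrel length; the inclusion rule is configurable to
"inside at both frames"). The average current is the slope of a linear
regression of the cumulative transported charge against time. A single
monovalent ion crossing the full barrel carries exactly one elementary
charge ($\bar I \cdot T = e$, a telescoping identity used as an exact test).
The synthetic generator runs biased random walks in a slab extending one
pore length beyond each lumen end with periodic reinjection; wrap jumps then
occur far outside the lumen and never contaminate counted displacements.
Since ions are uniform over the slab of width $W$, the expected current is
$(n_+ v_+ - n_- v_-)\,e/W$ — equivalently, (expected lumen occupancy)
$\times\, e v / L_p$.

## What the synthetic data do and do not emulate

Emulated: nonlinear open-pore IV curves from the transport model; stochastic
voltage-dependent two-state switching with heterogeneous gated conductances;
multi-pore ensembles; additive Gaussian measurement noise (default 2–5 pA,
a typical amplifier noise floor at kHz bandwidths); and the published
forcing protocols (2 Hz / 200 mV triangles, 0.1 Hz / 200 mV sinusoids,
±110 mV pulse trains with 10 ms waits at a −90 mV baseline).

Not emulated: capacitive/RC membrane transients, baseline drift, 1/f and
flicker noise, sub-conductance ladders beyond two states, pore insertion
and loss during a recording, pH and temperature dependence, and the
absolute conductances of specific mutants. Passing the closed-loop tests
therefore demonstrates the internal consistency of simulator and analyzer
under idealized recording conditions, not performance on raw bench data —
on real traces the pore-count QC and the mask and window widths would be
the first knobs to revisit.

## Problem sizes and reproducibility

All stochastic components take an explicit integer seed and are
bit-reproducible given it. The shipped tests and the acceptance script use
desk-scale sizes chosen to keep every quantity's sampling error comfortably
inside its tolerance: 200 single-pore d.c. traces (4 s at 5 kHz each), 26
pores × 50 cycles for the a.c. round trip (0.1 Hz sampled at 500 Hz — the
per-step closing probabilities stay below 0.05 there), 2000 pores for the
Monte-Carlo/ODE comparison, 500 pores for the synaptic pulse protocols, and
20 random charged pores for the symmetry and oracle sweeps.

## Known limitations

- The transport model is strictly 1D on-axis: no radial structure,
  dielectric self-energy, ion–ion correlations or specific binding, and no
  access resistance. Absolute conductances of real mutants are not expected
  to be reproduced; positions and signs of rectification trends are.
- The gating model is phenomenological; it does not simulate the underlying
  mechanical bistability. `suggest_polarity()` maps a charge configuration to
  a likely gating polarity, but it is a documented heuristic hook (sign of
  the position-weighted net lumen charge), not an established relation.
- Eq-style displacement currents assume unwrapped coordinates; reading real
  MD trajectory formats is out of scope.
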