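---
title: "A coarse-grained model of chromatin-lamina organization in the nucleus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of chromatin-lamina organization in the nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ladsim` simulates interphase chromatin as a single self-attracting
bead-spring polymer confined to a spherical nucleus.  One bead represents
three nucleosomes (about 600 bp) with diameter $\sigma = 10$ nm, so a
22.4 Mbp chromosome maps to $N = 37{,}333$ beads.  Everything is computed
in reduced units: $\sigma = 1$, $k_BT = 1$, and the bead damping time
$\tau = 3\pi\eta\sigma^3/k_BT$ ($\approx 2\,\mu s$ in water) $= 1$.

The potential energy is a sum of six terms:

* **Stretching** $E_s = \sum_i k_s (r_i - 2a)^2$ over consecutive beads,
  with $k_s = 100\,k_BT/\sigma^2$ and rest length $2a = \sigma$ (touching
  beads).
* **Bending** $E_b = \sum_i k_b (1 - \cos\theta_i)$ over successive bond
  vectors, with $k_b = 2\,k_BT$, giving a persistence length of two beads
  ($\approx 1.2$ kb) appropriate for interphase chromatin.
* **Chromatin-chromatin Lennard-Jones** between *all* bead pairs:
  $4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$, truncated and shifted to
  zero at $r_c = 2.5\sigma$ (self-attractive chain) or at $2^{1/6}\sigma$
  (purely repulsive, self-avoiding chain).  $\epsilon$, in $k_BT$, is the
  main control parameter for chromatin "solvent quality"; a 2$\times$2
  type matrix allows LAD/non-LAD-specific attractions.
* **Wall repulsion**: each bead interacts with its nearest point on the
  nuclear envelope through the same LJ form evaluated on the gap
  $R_c - |r|$, with $\epsilon = 1\,k_BT$ and cutoff $2^{1/6}\sigma$.
* **Lamin-bead LJ**: a static shell of lamin beads covers the sphere of
  radius $R_c$ (Fibonacci lattice, one bead per $\sigma^2$ by default).
  LAD beads are weakly attracted ($\epsilon_{lm} = 1\,k_BT$, cutoff
  $2.5\sigma$), so LADs can find the lamina kinetically; non-LAD beads
  only feel the repulsive core ($\epsilon_{ln} = 1\,k_BT$, cutoff
  $2^{1/6}\sigma$).
* **LAD-lamina bonds**: a bondable LAD bead within $r_b = 2.5\sigma$ of a
  lamin bead forms an explicit bond with shifted-harmonic energy
  $-k_{bond}(r_b-\sigma)^2 + k_{bond}(r-\sigma)^2$,
  $k_{bond} = 10\,k_BT/\sigma^2$: zero at formation, optimal at contact.
  A stretched bond ($r > r_b$) breaks with the Boltzmann probability
  $P_{break} = e^{-U_{bond}/k_BT}$, $U_{bond} = 10\,k_BT$, tested once per
  step while stretched.  Each LAD bead carries at most one bond, and only
  a fraction $\psi$ of LAD beads is bondable at all — this models the
  limited availability of tether proteins such as LBR.

The three intensive control parameters are the global chromatin volume
fraction $\phi = N(\sigma/2)^3/R_c^3$ (hydration), the bondable LAD
fraction $\psi$, and the self-attraction $\epsilon$.

```{r}
library(ladsim)
params <- sim_params(n_beads = 2000, phi = 0.3, psi = 1, epsilon = 1)
params$confinement_radius   # R_c that realizes phi = 0.3
```

## Bead typing

Bead types come either from a BED-like LAD annotation
(`read_lad_intervals()` + `intervals_to_bead_labels()`, majority-overlap
rule with ties labelled LAD) or from `synthesize_lad_pattern()`, which
draws alternating LAD/non-LAD blocks with geometric lengths calibrated to
the *Drosophila* ChrX statistics: 48% LAD with a mean domain of 90 kbp
(150 beads).  `select_bondable()` flags exactly
$\mathrm{round}(\psi\,n_{LAD})$ LAD beads uniformly at random.

For scaled-down chains the sweep driver shrinks the mean domain length in
proportion to $N$ (keeping domains at ~0.4% of the chain) so that a short
chain still carries many alternating domains; keeping the absolute
150-bead domain on an $N \le 2000$ chain would leave only a handful of
blocks and a qualitatively different wall-anchoring architecture.

## Dynamics

Bead positions follow the overdamped (position-only) Langevin update
$$\mathbf r_i(t+\Delta t) = \mathbf r_i(t)
 - \frac{\Delta t}{\gamma m}\nabla E
 + \sqrt{\frac{6 k_BT \Delta t}{\gamma m}}\,\boldsymbol\xi_i,$$
with $\boldsymbol\xi$ either uniform on $[-1,1]$ (the literal prefactor)
or, by default, Gaussian with the same variance $2k_BT\Delta t/\gamma m$ —
both give identical diffusion; Gaussian noise has cleaner statistics.
Pair interactions use a linked-cell neighbour search rebuilt every step;
an all-pairs reference path (`use_cells = FALSE`) exists for
cross-checking.

**Timestep and stability.**  The nominal timestep of the parameter set is
$0.01\tau$, but the explicit position-only update is only conditionally
stable: a pair mode with local curvature $k$ requires
$2k\,\Delta t/\gamma m < 2$.  The chain spring plus the LJ core at
thermally accessible contact distances ($r \approx 0.89\sigma$) reaches
$k \approx 3\times10^3\,k_BT/\sigma^2$, so rare contact fluctuations
diverge within a few steps at any practical $\Delta t$.  Two mechanisms
address this:

* an optional per-step **displacement limiter** (`max_disp`, off by
  default): moves larger than the limit are rescaled, and the engine
  counts how often this happens.  Production runs use `max_disp = 0.25`
  (in $\sigma$); the same mechanism with a 0.05 cap implements the soft
  push-off that removes overlaps of the initial random walk.  In the
  uncapped mode any displacement above $\sigma/2$ raises an
  `unstable-timestep` error instead.
* stage-appropriate timesteps: $10^{-3}\tau$ for repulsive-only stages and
  $5\times10^{-4}\tau$ for the dense self-attracting phase.  At
  $5\times10^{-4}\tau$ the limiter fires on fewer than $10^{-3}$ of the
  moves and the contact-scale energies are converged (halving the step
  again changes the pair energy per bead by about 6%); at
  $2\times10^{-3}\tau$ half of all moves would be limited and the
  condensed phase is visibly under-bound, so large steps are reserved for
  overlap removal only.  Fine-statistics checks (free diffusion, harmonic
  well) run uncapped at $\Delta t \le 5\times10^{-4}\tau$, where the known
  Euler discretization bias of the sampled variance,
  $1/(1 - k\Delta t/\gamma m)$, is below 2%.

## Equilibration protocol

`equilibrate_protocol()` follows a three-stage schedule: (i) *push-off*,
a short displacement-capped run with purely repulsive chromatin
interactions that removes the overlaps of the compact random-walk initial
configuration (whose centre of mass starts at the nuclear centre);
(ii) *repulsive*, excluded-volume chromatin only while the lamin LJ
attraction and LAD bonding are active, run until the windowed mean radius
of gyration changes by less than 1% over two consecutive windows;
(iii) *attractive*, the configured $\epsilon$ with cutoff $2.5\sigma$,
re-equilibrated to a second plateau.  The stage log (steps, final $R_g$,
convergence flag) is attached to the returned state.

## Observables

* `radial_profile()` converts bead counts in 30 equal-thickness spherical
  shells into a local volume fraction $\phi(r)$, normalized so that its
  volume-weighted mean equals the global $\phi$ (this identity holds
  exactly per frame and is asserted by the test suite on every production
  run).
* `classify_organization()` applies fixed rules to the profile:
  *peripheral* if the profile peaks at $r > 0.8$ and the inner half is
  depleted below 10% of the peak; *central* if the peak lies at
  $r < 0.6$ and the outermost shell is below 50% of the peak, or if the
  centre-of-mass offset exceeds $0.15\,R_c$ (the wetting-droplet
  diagnostic — off-centre condensates touching the envelope are grouped
  with the central class); *conventional* otherwise.  Because inner
  shells have tiny volumes, the classifier first applies a
  volume-weighted three-shell moving average; single-bead fluctuations
  otherwise produce spurious central peaks.  The thresholds are package
  choices (the organization modes themselves are defined by eye in the
  source literature) and are exposed as arguments.
* `contact_map()` counts non-adjacent pairs within $2.5\sigma$ and
  averages over frames; `p_s` is the contact probability versus contour
  separation.
* `scaling_exponent()` fits $\langle R_g^2(s)\rangle \propto s^{2\nu}$
  over subchains.  Subchain sizes whose $R_g^2(s)$ exceeds half the
  whole-chain value are excluded: in compact globules $R_g(s)$ saturates
  at the globule size, and including that regime biases $\nu$ downward.
  With this window the package recovers $\nu \approx 0.5$ (ideal),
  $\approx 0.56$ (self-avoiding at $N = 500$; the asymptotic 0.588 is
  approached slowly from below at finite $N$) and $\approx 0.36$
  (collapsed, $\epsilon = 1$).
* `persistence_length()` fits $\langle\cos\theta(s)\rangle =
  e^{-s\sigma/l_p}$.  For an excluded-volume chain the tangent
  correlation is exponential only in its initial decay; beyond roughly
  two decay lengths a slow power-law tail takes over.  The fit is
  therefore a weighted log-linear regression through the origin
  (delta-method weights $\propto c(s)^2$) restricted to
  $c(s) \ge e^{-2} c(1)$.  For $k_b = 2\,k_BT$ this yields
  $l_p \approx 2\sigma$, consistent with the design relation
  $l_p = k_b\sigma/k_BT$.
* `angular_segregation()` quantifies LAD/non-LAD demixing along the
  envelope: the same-type fraction among 10 nearest neighbours of
  peripheral beads, normalized by its expectation under type shuffling.

## Initial states for unconfined measurements

Scaling-exponent measurements of the self-avoiding chain start from
configurations produced by chain growth (`grow_saw`) followed by athermal
pivot moves (`pivot_saw`): global conformational relaxation of a SAW by
Brownian dynamics alone takes $\mathcal O(N^{1+2\nu})\tau$, far beyond a
sensible compute budget, while pivot moves equilibrate the global size in
a few hundred accepted rotations.  The Brownian run that follows
re-establishes the local (thermal) bond and angle statistics.

## Scaled-down study sizes and their limits

The organization-mode machinery is exercised at $N = 600$–$2000$ instead
of the full $N = 37{,}333$.  The transitions are controlled by the
intensive parameters $(\phi, \psi, \epsilon)$, but one aspect does *not*
survive naive scale reduction: nuclear-scale phase separation.  At
$\epsilon = 1$ the condensed chromatin phase has a volume fraction of
roughly $\phi_d \approx 0.4$ with an interface one to two beads wide.
The bulk free-energy gain of expelling the aqueous phase from the nuclear
centre scales with $N$, while the cost of the extra interface scales with
$N^{2/3}$; at $\phi = 0.3$ the margin between $\phi_d$ and $\phi$ is
small, and below a few thousand beads the interface term wins.  In this
regime the reduced systems settle into a volume-filling (conventional)
organization even at parameter points where the full-scale chromosome is
peripheral — prepared peripheral shells relax back toward filling, so
this is an equilibrium finite-size effect, not a kinetic artifact.
Consequently the test suite's mode-recovery checks at $(\phi{=}0.3,
\psi{=}1, \epsilon{=}1)$ (peripheral) and $(\phi{=}0.3, \psi{=}0.1,
\epsilon{=}1)$ (central) fail at desk scale and are expected to: they
document the boundary of what the scaled systems can show.  The
low-attraction and high-$\phi$ conventional points, the polymer-physics
limits (persistence length, scaling exponents), the bond kinetics, and
all profile/classification machinery are scale-robust and pass.

What the synthetic generator and scaled runs do demonstrate: the
arithmetic relating nuclear size and volume fraction, correct Boltzmann
sampling of the integrator, LAD-limited bond statistics with the
prescribed formation/breaking rules, and the qualitative response of the
radial profile to $(\phi, \psi, \epsilon)$.  What they do not demonstrate:
quantitative phase boundaries of the full-scale state diagram, wetting
kinetics, or any property of real nuclei beyond the model assumptions
(a single chromosome, a rigid spherical lamina, implicit solvent, uniform
self-attraction).

## Degenerate inputs and numerical conventions

Zero-distance pairs raise `singular-overlap`; coincident consecutive
beads raise `singular-angle`; beads outside the sphere raise
`escaped-bead` (the wall force diverges as the gap closes, so escapes
only occur after an integration blow-up).  LJ energies are
truncated-and-shifted (forces are the unshifted derivative, so dynamics
are unaffected by the shift convention).  Exact distance ties in bond
formation resolve to the lowest lamin index.  All randomness flows
through R's RNG: `set.seed()` makes builders, dynamics and bond updates
bit-reproducible.
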