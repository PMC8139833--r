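# ladsim

Coarse-grained Brownian-dynamics simulation of chromatin organization in
the cell nucleus.

Interphase chromatin in many cells is not uniformly distributed: it can
line the nuclear envelope (peripheral organization), fill the nucleus
(conventional), or condense in the interior (central).  `ladsim`
implements a minimal polymer model that reproduces these modes and the
transitions between them: a single chromosome is a bead-spring chain (one
bead = 3 nucleosomes ≈ 600 bp, diameter σ = 10 nm) confined to a sphere
of radius R_c lined with static lamin beads.  Three intensive parameters
control the organization:

* **ϕ** — global chromatin volume fraction, `ϕ = N (σ/2)³ / R_c³`
  (nuclear hydration);
* **ε** — depth of the chromatin–chromatin Lennard-Jones attraction in
  k_BT (solvent quality / self-attraction), cutoff 2.5 σ;
* **ψ** — fraction of lamina-associated-domain (LAD) beads allowed to
  form explicit bonds with the lamina.  Bonds form within r_b = 2.5 σ
  with energy `−k_bond(r_b−σ)² + k_bond(r−σ)²` (k_bond = 10 kT/σ²) and
  break, once stretched beyond r_b, with Boltzmann probability
  `exp(−U_bond/kT)`, U_bond = 10 kT.

The chain has spring constant k_s = 100 kT/σ², bending stiffness
k_b = 2 kT (persistence length 2 beads ≈ 1.2 kb), and evolves by
overdamped Langevin dynamics with damping time τ = 3πησ³/kT ≈ 2 µs.
Bead types come from a BED-like LAD annotation or from a synthetic
generator calibrated to the *Drosophila* ChrX statistics (48% LAD, 90 kbp
mean domain).  Analysis tools compute radial volume-fraction profiles
ϕ(r), classify the organization mode, and measure contact maps / P(s),
subchain scaling exponents, persistence length and angular LAD
segregation.  A sweep driver tabulates state diagrams over (ϕ, ψ, ε).

The package is aimed at polymer/nuclear-organization modelling: anyone
who wants a self-contained, scriptable implementation of the
confined-chain + dynamic-lamina-bond model without setting up a general
MD engine.

## Worked example

Build a 600-bead nucleus at ϕ = 0.3 with all LADs bondable and strong
self-attraction, equilibrate with the two-stage protocol (repulsive, then
attractive), and classify the result:

```r
library(ladsim)

res <- run_single(phi = 0.3, psi = 1, epsilon = 1, n_beads = 600,
                  seed = 1, production_steps = 30000,
                  window = 15000, max_windows = 4)
res$call
#> <organization_call> conventional | com offset 0.012 R_c | peak at r = 0.88
round(res$bond_count)
#> [1] 311
```

About half the beads are LADs and nearly all of them are bonded to the
lamina (`bond_count`).  The radial profile peaks near the envelope
(`peak at r = 0.85`, the bonded LAD layer); at this reduced chain length
the nuclear centre does not empty, so the run classifies as
`conventional` — see the vignette
(`vignettes/chromatin-lamina-model.Rmd`) for why nuclear-scale phase
separation needs chains much longer than a few thousand beads, and what
the scaled-down systems can and cannot reproduce.  `plot(res$profile)`
draws ϕ(r) with the global ϕ as a reference line.

Polymer-physics limits come out of the same engine, e.g. the persistence
length of the repulsive chain:

```r
fit <- persistence_length(confs)  # confs: frames of an unconfined run
fit$persistence_length
#> [1] 2.063
```

A thin command-line wrapper with `build` / `run` / `sweep` / `analyze` /
`validate` subcommands lives in `inst/cli/ladsim.R`.

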