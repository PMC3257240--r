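---
title: "Methods: an agent-based spatial model of vesicle transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based spatial model of vesicle transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`vtsim` simulates membrane trafficking in a virtual spherical cell as a
hybrid of two stochastic layers:

* a **spatial particle layer**: every cytosolic machinery molecule (free
  coats, free motors, signaling proteins) and every plasma-membrane protein
  is an explicit agent with a position, moved by Brownian dynamics (or 2D
  surface diffusion on the membrane). Vesicles and compartments are
  spherical agents too — compartments are just large vesicles — moved by
  diffusion, by molecular motors along cytoskeleton filaments, or by a
  transient actin boost after endocytosis.
* a **well-mixed internal layer**: the molecular content of each vesicle
  agent is a set of integer copy numbers in six groups (bound coat
  monomers, polymerized coat, SNAREs, motors, membrane cargo, luminal
  cargo). Internal chemistry runs as per-molecule stochastic mass-action
  kinetics; membrane-bound species use surface-based densities, luminal
  species volume-based ones.

The two layers couple through the vesicle actions: catcher-mediated
recruitment of cytosolic coats/motors onto compartments, coat-cargo dimer
formation that nucleates budding, coat-shell polymerization, saturating
cargo/SNARE/motor loading at separation, coat depolymerization that
releases monomers back to the cytosolic pool, SNARE-pairing-controlled
docking and fusion, and clathrin-style clustering at the plasma membrane.

## Units

Lengths in µm, times in s, amounts in molecule counts. Bimolecular rate
constants are entered in 1/(M·s) and converted once: over a time step `dt`
a rate `k` defines a reaction volume `V_r = k·dt/N_A` litres
(= `k·dt·1e15/N_A` µm³). Surface-based densities use a 10-nm membrane
shell, so surface rates share the same entry unit.

## Movement

Brownian steps add `sqrt(2·D·dt)·ξ` per coordinate with ξ uniform on
`[-√3, √3]` (mean 0, variance 1). The uniform step has no long tails, so a
larger `dt` is safe, and the sum converges to a Gaussian within ~4 steps
(central limit theorem); this is verified by a KS test in the suite. Steps
into an obstacle (plasma membrane, nucleus, another vesicle for vesicle
agents) are **rejected**, not reflected. Molecule agents may overlap each
other and vesicles; vesicles are mutually exclusive. Vesicle diffusion
scales with the Stokes–Einstein relation `D = ref_D·ref_radius/radius`.

Motor transport advances the arc-length position along an oriented
polyline filament at the tug-of-war velocity
`v_eff = (n₊v₊ − n₋v₋)/(n₊ + n₋)` — the motor-number-weighted mean of the
two directions. This closed form is a provisional stand-in (the original
tug-of-war derivation is in an unavailable supplement); it has the right
limits (unopposed speed, symmetric stall) and direction switches with the
majority. A vesicle stalled longer than `stall_detach_time` or stepping
past a filament end detaches to diffusion; a blocked step on the track
(e.g. arrival at a caged target compartment) also detaches it.

## Bimolecular reactions in space

A reaction with rate `k` fires when partners are within a critical
distance. Non-overlapping partners (vesicle–vesicle, agent–structure) use
a thin reaction layer: the critical distance is `r_i + r_j + δ` with δ
solving `(4π/3)[(r_i+r_j+δ)³ − (r_i+r_j)³] = V_r`, and the reaction fires
with probability 1 inside the layer. Overlapping partners
(molecule–molecule, molecule–vesicle) use the collision distance
`r_i + r_j` and acceptance probability `P = V_r/V_int`,
`V_int = (4π/3)(r_i+r_j)³`, clamped to 1 with a warning (the clamp means
`dt` is too coarse for that rate). Reactions are sampled every
`reaction_stride` (default 5) movement steps with effective step
`stride·dt`, letting walkers decorrelate between sweeps. Within a sweep
candidate pairs are visited in randomized order and each agent reacts at
most once (first match wins) — the tie-break is our choice, the source
being silent.

## Budding, loading, depolymerization

Budding is **on demand**: a coat–cargo dimer forms with propensity
`k_cc·n_coat·n_cargo/(N_A·V)`; without cargo or without bound coat
monomers no vesicle ever forms. The shell then polymerizes monomer by
monomer (per-monomer probability `1 − exp(−k_poly·dt)`), the nascent bud
is pushed out proportionally to shell completion, and the budding time
`t_bud` is recorded. On separation each donor molecule of species j
transfers with probability
`p_j = 1 − exp(−k_load(i,j)·⟨n_pol⟩·t_bud/(N_A·V_donor))` where
`⟨n_pol⟩ = shell_size/2` is the time-average of a linearly growing shell;
draws are binomial per species, then **class saturation** rescales all try
numbers of one class by `L/Σm_j` when they exceed the class limit, with
largest-remainder rounding so the total equals `⌊L⌋` (the rounding scheme
is our choice). Volume and surface of the bud are subtracted from the
donor, so both are conserved exactly across every budding and fusion
event; after fusion the sphere radius derives from the volume and surplus
surface is implicitly corrugated.

After budding the shell shields the vesicle from fusion and decays as
`n_pol(t) = shell_size·max(0, 1 − (t − lag)/depol_time)`; released
monomers reappear as free cytosolic agents at the vesicle position, which
closes the coat recycling loop (cytosol → membrane → shell → cytosol).

## Fusion

The effective SNARE pair count between two membranes is
`n_pairs = Σ_uv s_uv·min(n_u·f_i, n_v·f_j)` — the minimum rule: there
cannot be more pairs than the smaller number of partners. Only SNAREs in
the contact patch count: the patch is a spherical cap of height δ (the
reaction-layer thickness computed from `k_fus_pair` alone, which breaks
the circular dependence of `n_pairs` on its own contact geometry), area
`2πrδ`, the smaller patch governing; `f` is the patch/total-area fraction.
Then `k_fus = k_fus_pair·n_pairs` sets the contact distance and
`t_fus = tau_pair/n_pairs` the docking duration; docked pairs are
immobilized and cannot be interrupted (simplest consistent reading).
Coated vesicles (`n_pol > 0`) always bounce. A fusion is **backward** when
the target is the vesicle's donor compartment. Exocytosis reuses the same
machinery with the plasma membrane as structure partner; its local SNARE
count comes from explicit membrane agents near the contact point, and on
merge the vesicle's SNAREs and membrane cargo are re-instantiated as
membrane agents.

## Endocytosis

All plasma-membrane molecules are explicit 2D diffusers. A cluster
nucleates when a membrane coat sits within the clustering reaction layer
of a selectable cargo, at a configurable rate (`nuc_rate`, default
0.05 s⁻¹ per coat in contact) — rate-limited nucleation, because
capture-on-contact splinters the coat pool into many one-coat clusters.
Clusters grow by capturing membrane agents within `footprint + δ(k_clust)`
(footprint disc area ∝ current size, so the capture radius strictly grows)
**and cytosolic coat monomers** within the same radius — lateral membrane
diffusion alone would take hundreds of seconds to assemble a pit at these
densities, and recruitment from the cytosol is how clathrin actually
arrives. At `size = shell_size` the members convert into a vesicle with a
full shell, launched inward with the actin boost `v_boost` until the shell
has depolymerized.

## Signaling layer

Receptors R on the PM convert to RL by an implicit bulk ligand (first
order, after `t_ligand`). RL is the endocytic catcher and cargo, so
endocytosis is receptor-mediated and self-limiting. Inside endosomes RL is
deactivated enzymatically with Michaelis–Menten propensity
`k_cat·E·RL/(K_M + RL)` (E = 394 enzyme copies by default). Cytosolic MAPK
is activated by membrane RL agents (reaction-layer rule) and by RL counts
in vesicles/endosomes (vesicle–protein rule: rate × RL count);
MAPKp deactivates first order with separate cytoplasmic and nuclear
constants; both MAPK forms bind the nucleus surface by the layer rule and
are released on the opposite side of the envelope (a teleport — the model
does not resolve pore transit).

# The main loop

Each iteration: advance time; move all agents (steps into obstacles
rejected); every `reaction_stride` steps run second-order reactions,
first-order reactions, then vesicle actions in the fixed order internal
chemistry → depolymerization → budding progression → endocytosis → fusion
attempts, then the signaling sweep. One RNG stream per run, seeded once,
so a (config, seed) pair reproduces bit-identical event logs.

# The synthetic world and parameter provenance

No numeric rate value is printed in the source work (they live in an
unavailable supplement), so every preset default here is a provisional,
documented choice of realistic magnitude, and all are config-overridable.
Choices that fix the presets' stated world:

* **Cell**: radius 2.5 µm (yeast scale), transport vesicles 50 nm radius.
* **Vesicle mobility**: reference D = 0.5 (fast) / 0.1 (slow) µm²/s for a
  50-nm vesicle — crowded-cytoplasm values, well below the aqueous
  Stokes–Einstein limit.
* **Two-compartment scenario**: compartments (radius 0.4 µm) at ±1.4 µm,
  chosen so the motorized travel time exceeds the coat-shielding time
  (`depol_lag + depol_time` = 2.5 s) — the timescale comparison the
  transport architectures exploit. SNARE pools use the mixed-enrichment
  regime of the underlying two-compartment ODE tradition: each compartment
  holds all four SNARE species at ~2.5:1 enrichment for its own route, so
  the donor remains a competent fusion partner and backward fusion is
  suppressed by the architecture, not forbidden by the chemistry.
* **Machinery turnover**: coat on/off fast (k_off ≈ 0.1 s⁻¹), motor
  on/off slow (k_off = 0.005 s⁻¹) — the high-coat-turnover /
  slow-motor-turnover regime the model family predicts.
* **Loading**: class limits 20 cargo / 15 SNAREs / 5 motors per vesicle;
  loading rates set for sub-saturation means of roughly 8–12 cargo and
  3–5 motors.
* **Signaling**: 150 receptors on the PM, 30 in the endosome (receptors
  reside at the surface before ligand), 250 MAPK, Michaelis–Menten
  deactivation with 394 enzyme copies in the endosome.

What the generator does **not** emulate: cytoskeleton dynamics (filaments
are static), hydrodynamics and crowding beyond vesicle exclusion,
compartment maturation, membrane mechanics of fusion, and the full
pheromone cascade (one MAPK stage only). A green test therefore
establishes the internal consistency of the algorithms and the stated
qualitative transport physics at desk scale — not quantitative agreement
with any particular measured cell.

# Numerical choices and degenerate inputs

* Per-step and per-sweep probabilities are kept below ~0.1 at the default
  `dt = 0.02 s`; the engine warns when a probability clamps.
* Dipole field lines are traced with fixed 50-nm steps; a line that would
  exit the cell slides along the cortex (radial field component dropped),
  which is what lets ≥95% of lines seeded anywhere on the donor terminate
  on the target sphere inside a bounded cell.
* `n_pairs = 0` gives an infinite fusion time (never fires); zero-radius
  nuclei disable the nucleus; `t_end = 0` returns the initial state.
* Largest-remainder rounding makes class saturation exact for the
  frozen example (30, 10 | L = 20 → 15, 5) and never exceeds `⌊L⌋`.

# Known limitations

At desk scale the two best architectures (direct bundle, dipole field)
both suppress backward fusion to a handful of Poisson events, so their
relative order is at the edge of statistical resolution; the project notes
record this against the corresponding acceptance leg. The simulator is
single-threaded R and intended for scaled-down scenario studies, not for
the 10⁵-agent full-scale runs of the original implementation.
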