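---
title: "Geometric prediction of bridging waters: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric prediction of bridging waters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquabridge)
```

## The model

Crystallographic surveys of protein-bound water show remarkably narrow
geometry: the water-oxygen to polar-atom contact distance peaks at 2.73 Å
(σ ≈ 0.09 Å) against oxygen and 2.87 Å against nitrogen, while the distance
between two protein atoms bridged by the same water is 4.61 Å with a much
broader σ of 0.48 Å, and the X~i~–water–X~j~ angle centres on 111° (σ =
16.7°). aquabridge exploits exactly this asymmetry: it **fixes the two
hydrogen-bond leg lengths at their ideal values and lets the angle float**.

For an eligible pair of polar sites X~i~, X~j~ the locus of points at
distance d~i~ from X~i~ and d~j~ from X~j~ is a circle perpendicular to the
X~i~–X~j~ axis. With triangle sides (d, d~i~, d~j~) and Heron's formula for
the area A, the circle has radius r = 2A/d and its centre lies on the axis
at √(d~i~² − r²) from X~i~. Every perimeter point is an exact ideal-distance
water position; the azimuth is the one remaining degree of freedom.

The azimuth is chosen from the sites' hydrogen-bonding direction vectors:
the X–H axis for donors, sp2/sp3 lone-pair axes for acceptors (computed
relative to the placed hydrogen for dual-role groups). The midpoint of the
closest approach of the two direction lines is projected onto the circle
plane and pushed radially to the perimeter. When a site offers several
direction vectors, every combination is evaluated and the one whose
perimeter point shows the smallest summed angular deviation from the two
vectors wins; measuring the deviation at the placed point (rather than at
the raw midpoint) makes the choice robust when noisy direction vectors run
nearly parallel, and is identical for exact geometry.

Hydrogens are attached with rigid water geometry (O–H 0.96 Å, H–O–H
104.45°). Two acceptors: both hydrogens aim at the partners, symmetric about
their bisector. Two donors: the water's lone pairs face the donors, the
hydrogens sit in the perpendicular plane. Mixed pairs produce exactly two
saved orientations: the hydrogen serving the acceptor is fixed on the ideal
direction and the second hydrogen's azimuth is scanned in 1° steps so a lone
pair faces the donor; the mirror image about the X~i~–O–X~j~ plane (or, for
two dual-role sites, the swapped role assignment) is the second variant.

## Eligibility, energy gate and posterior mode

A site pair is considered only if its separation lies strictly inside
3.65–5.57 Å (the ±2σ window of the bridged-pair distance distribution);
strict mode narrows this to the ±1σ window 4.13–5.09 Å. Separations above
d~i~ + d~j~ (possible in the upper window tail for two oxygens, where
5.46 < d < 5.57) admit no exact construction and are skipped rather than
approximated — the package never emits a water that violates the ideal
distances.

Each constructed water is scored against both partners with a 12–10
directional hydrogen-bond potential,

E = ε · (6(d₀/d)¹⁰ − 5(d₀/d)¹²) · cos²θ~don~ · cos²θ~acc~,

with well depth ε = −5 kcal/mol at ideal geometry, a 3.5 Å radial cutoff,
angular terms clamped at 90°, and the total clamped to be non-positive
(steric repulsion is handled separately). The exact functional form of the
original packing program's force field is not public; this standard
directional form is a package choice, every parameter is exposed, and no
validation quantity depends on the absolute energy scale — only on geometry
and on threshold monotonicity. A water is retained when **both** legs reach
the acceptance threshold E~min~ (−2 kcal/mol by default; −4 and −5 as the
stricter presets; a `sum` gate is available as a flag). A geometric clash
filter (≥ 2.4 Å from every heavy atom except the two partners) runs before
scoring.

`solvate_structure()` applies this to every eligible pair of a fixed
structure (posterior mode) and collapses waters closer than 1.0 Å to the
lower-energy one. `build_solvated_rotamers()` runs the same construction
across rotamer pairs during packing: each accepted water is duplicated onto
both bridged rotamers as a solvated copy kept alongside the unsolvated
original; waters bridging to ligand or fixed atoms solvate only the
amino-acid rotamer.

## Packing engine

The packing layer is intentionally small: a bundled backbone-independent
rotamer library (most frequent conformers per residue, coarse frequencies,
plain-text and swappable), side chains grown by internal coordinates,
Goldstein dead-end elimination, and a single-flip Metropolis chain with a
geometric cooling schedule (default 2000 steps, 10 → 0.05 kcal/mol),
reproducible by seed. Pairwise energies combine a soft-core Lennard-Jones
steric term (r~min~ 3.4 Å, ε 0.1, capped) with the hydrogen-bond credit of
attached waters; when both rotamers of a bridge carry duplicate copies each
contributes half of the bridge energy, so the physical water is counted
once. Full force-field parity with any production packing program is
explicitly out of scope; the engine's correctness targets are oracle-based
(exhaustive enumeration on toy problems), not benchmark parity.

Dual-role details that the geometry analysis leaves open were fixed as
follows: rotatable hydroxyls (Ser/Thr/Tyr) are sampled at 60° staggered
torsions and locked to the orientation with the best summed hydrogen-bond
energy to neighbouring polar sites (first position on ties — deterministic);
histidine carries its single hydrogen on NE2 by default, making ND1 the
acceptor; sulphur is never a polar site. Ligand atoms are typed from bonded
geometry (carbonyl vs hydroxyl vs ether oxygen; amine vs aromatic nitrogen)
with element-based fallbacks and a logged warning for unknown groups.

## What the synthetic fixtures emulate

The validation data for this package are generated, not downloaded. The
generator runs the construction in reverse: a water position is chosen
first, then carbonyl-like acceptor fragments and amide-like donor fragments
are built around it whose direction vectors aim exactly at the planted
oxygen at exactly the ideal leg distances. Forward solvation must therefore
reproduce the planted water to machine precision, which is the package's
strongest self-check. Bridging angles are drawn from Normal(111°, 16.7°),
truncated so the implied pair distance stays within the ±1σ core
(4.13–5.09 Å) — planted bridges are meant to be unambiguous positives for
the ±2σ eligibility criterion. Positional noise is applied as one rigid
N(0, σ) translation per chemical fragment and per water: refined crystal
structures restrain bond lengths and angles, so coordinate uncertainty
displaces groups rather than scrambling their internal frames; per-atom
independent noise at 0.3 Å would put ~17° of angular error on a 1.4 Å bond
frame, which no refined structure shows.

What the fixtures do **not** emulate: electron-density-dependent water
selection, anisotropic or correlated lattice noise, alternate conformations,
genuine chemical diversity of binding sites, or water networks deeper than
one shell. Passing the fixture suite therefore demonstrates the correctness
of the geometry, gating, matching and packing machinery — not the absolute
recovery rates attainable on real crystallographic spheres, which depend on
a curated experimental dataset and a full force field and are documented in
the README as an optional external workflow.

A known quantitative limit, on purpose: with 0.3 Å rigid-fragment jitter the
pair-distance perturbation has σ ≈ 0.42 Å, so roughly 8% of planted bridges
drift out of the eligibility window (or past the d~i~ + d~j~ bound) and
cannot be rebuilt. Recovery at a 1.4 Å cutoff then plateaus near 92–95%
depending on the seed, even though the positional deviations of the
rebuilt waters concentrate near the jitter scale (median ≈ 0.45–0.50 Å).
We report this rather than widening the window, because the window is part
of the method.

## Numerical choices and degenerate inputs

* Closed-ball convention for all radius filters (a distance exactly at the
  cutoff is inside); eligibility windows use strict inequalities as printed.
* Alternate locations resolve to the highest occupancy, ties to file order.
* Symmetry expansion applies all tabulated space-group operators plus
  lattice translations in a −2..2 cube — sufficient for 20 Å neighbourhoods
  at protein-crystal cell sizes; the operator table is plain text and
  extensible.
* Parallel direction vectors (no unique closest approach): the midpoint of
  the origins' mutual projections is used and flagged.
* Midpoint projecting onto the circle centre: a 1° perimeter scan minimises
  the summed angular deviation; without site information a fixed in-plane
  axis is used. Both are deterministic.
* Degenerate tangency (d = d~i~ + d~j~) yields the single axis point, r = 0.
* Matching is greedy by ascending pair distance with ties broken by
  predicted index; a maximum-cardinality mode (igraph) is available and used
  as the oracle in tests. Statistical fits go through `MASS::fitdistr()`,
  with closed-form moment identities as independent checks.
* Simulation sizes in the tests and the acceptance script (1000 random
  construction instances, 100 seeded fixtures per condition, toy packing
  problems under 1000 assignments, 10⁵-draw fits) were chosen so the whole
  validation runs in a couple of minutes on one core while keeping
  binomial/standard-error margins well below the asserted tolerances.

## Limitations

Only first-shell, geometrically constructible bridging waters are predicted;
second-shell waters (water-only partners) are out of scope by construction,
and water-water partnering during packing is available behind a flag but off
by default. Protonation is fixed (no pKa model, no His/Asn/Gln flip search
beyond the configurable default), metals are not coordinated, and the
bundled rotamer library is deliberately small — users with richer libraries
can drop them in as plain-text files.
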