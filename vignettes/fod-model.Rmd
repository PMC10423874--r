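---
title: "The fuzzy-oil-drop model in oildrop: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzy-oil-drop model in oildrop: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oildrop)
```

## The model

The fuzzy-oil-drop (FOD) model idealises a water-soluble globular protein
as a spatial "drop" of hydrophobicity: maximal at the geometric centre of
the molecule (the hydrophobic core) and decaying to near zero at the
surface, where polar residues face the solvent. `oildrop` quantifies how
closely a real structure follows this ideal.

Every residue is reduced to one **effective atom** — the centroid of its
side-chain heavy atoms (CA for glycine and for residues whose side chain
was not resolved) — carrying an **intrinsic hydrophobicity** $H^r \in
[0,1]$ determined by its amino-acid type.

Three aligned per-residue distributions, each normalised to sum 1, are
compared:

* **T (theoretical)**: a 3D Gaussian is fitted around the unit
  (`orient_unit()` + `encapsulate()`), and
  $T_i \propto \exp\!\big(-\tfrac{x_i^2}{2\sigma_x^2}
  -\tfrac{y_i^2}{2\sigma_y^2}-\tfrac{z_i^2}{2\sigma_z^2}\big)$
  evaluated at the oriented effective-atom positions.
* **O (observed)**: pairwise distance-damped hydrophobic interactions,
  $O_i \propto \sum_{j \ne i} (H_i + H_j)\, w(r_{ij}, c)$, where $w$ is a
  sigmoid polynomial that falls from 1 at contact to 0 at the cutoff
  $c = 9$ Å (`contact_weight()`).
* **R (reference)**: the uniform distribution $1/N$ — "no core at all".

Agreement is measured by Kullback–Leibler divergence (base 2, bits) and
summarised by the **relative distance**

$$RD = \frac{D(O\|T)}{D(O\|T) + D(O\|R)} .$$

$RD = 0$ means O reproduces the Gaussian ideal exactly; $RD = 1$ means O
is indistinguishable from the flat reference. $RD < 0.5$ classifies the
unit as possessing a hydrophobic core.

The **FOD-M** extension acknowledges environments other than bulk water
(membranes, large binding partners, nucleic acids). The target
distribution is blended toward its inverse,

$$M_i(K) \propto T_i + K\,(T_{\max} - T_i),$$

and the **environment parameter** $K^\* = \arg\min_K D(O\|M(K))$ measures
how far the best-matching field is displaced from the pure polar-water
field: $K = 0$ is micelle-like, $K > 1$ is typical of strongly
non-aqueous (e.g. membrane-like) structuring. Because $K = 0$ is always in
the search grid, $D(O\|M(K^\*)) \le D(O\|T)$.

## Assessment modes

A single fitting function, `fod()`, returns a classed object with
`print()`, `summary()`, `coef()` (RD and K), `fitted()` (M at $K^\*$),
`residuals()` and `plot()` methods. The published analysis style uses it
in several modes, all available through `analyze()`:

* **complex / individual chain / domain** — the Gaussian spans exactly the
  residues being assessed (`status_individual()`; domains are user-supplied
  residue ranges, since domain boundaries come from external annotation).
* **chain as a component of the complex** — the Gaussian and the pairwise
  interactions span the *whole* complex; T and O are then restricted to
  the chain and renormalised (`status_in_context()`). This asks whether
  the chain participates in the complex-wide core, not whether it has one
  of its own.
* **fragment** — any sub-profile of an existing fit (disulfide-delimited
  fragments, catalytic sets, interfaces) is sliced out, renormalised and
  re-scored (`fragment_status()`). Applied to the full index this
  reproduces the unit's status exactly, which the tests assert.
* **interface** — residues whose effective atom lies within the
  interaction cutoff (9 Å by default) of another chain
  (`interface_selection()`); their fragment status on the complex profile
  says whether the contact region joins the shared core.
* **cross-form** — the bound-form interface residues evaluated on the
  unbound structure's profile (`cross_form_status()`), with identity
  mapping on (chain, residue number, insertion code) and optional
  per-chain offsets for renumbered depositions.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 9 Å | range of the hydrophobic interaction; also the default interface criterion |
| `contact` | sigmoid | damping form; a linear ramp is provided for sensitivity checks |
| `pad` | 0 Å | extra half-extent before dividing by 3 to get sigma |
| `sigma_floor` | 1 Å | smallest allowed half-extent (degenerate, e.g. planar, clouds) |
| `k_max`, `k_step` | 10, 0.01 | K search grid; `k_rounded` reports one decimal for table comparison |
| `scale` | `"kd"` | intrinsic hydrophobicity scale, min–max normalised to [0,1] |

Per axis, $\sigma = \max(\text{extent}/2 + \text{pad},\,
\text{floor})/3$: the molecular surface sits near $3\sigma$, where the
Gaussian is close to zero. The centre is the bounding-box midpoint of the
*oriented* cloud rather than the centroid — encapsulation is about
geometric extent, and computing it in the intrinsic (principal-axes) frame
makes T exactly invariant under rigid-body motion of the input, a property
the test suite checks to 1e-9.

Two conventions in the published FOD line of work are not printed in full
detail and were fixed here as package design choices:

* **Hydrophobicity scale.** The default is the Kyte–Doolittle hydropathy
  index min–max normalised to [0,1], shipped as a plain TSV and swappable
  via `fod_params(scale=)` or any two-column file. Absolute RD values
  shift with the scale; the classification logic does not depend on which
  calibrated scale is used.
* **Form of M(K).** The normalised linear blend above satisfies all the
  contracts the statistic needs ($M(0)=T$ exactly; $K \to \infty$
  approaches the normalised inverse field; uniform T is a fixed point for
  every K) and is isolated in `m_profile()` so it can be swapped.

## Numerical choices

* Profiles are floored at 1e-12 and renormalised before any divergence, so
  Gaussian-tail underflow can never produce a zero denominator inside the
  KL sum. `kl_divergence()` itself refuses genuine zero-support
  violations.
* The K search is a dense grid, not a derivative method: the objective can
  be extremely flat near the optimum, and a grid is deterministic. Ties go
  to the smallest K, so a uniform T (where every M(K) equals T) reports
  K = 0.
* Principal-axes orientation fixes eigenvector signs by making the
  largest-magnitude component positive and flipping the third axis if the
  determinant is negative; the Gaussian is even in every coordinate, so
  sign choices cannot affect T. Near-degenerate eigenvalues (almost
  spherically symmetric clouds) make the axes themselves ill-conditioned;
  extents, and hence T, remain stable in practice but exact axis labels
  may swap.
* Alternate locations keep the highest occupancy (ties: first in file);
  only the first coordinate model of multi-model (e.g. NMR) entries is
  used; waters, ligands and nucleic-acid chains are excluded from the
  profiles and logged in the unit's `skipped` field.
* PDB coordinates carry three decimals, so a write/read round trip is
  exact to 0.001 Å; amino-acid types (and therefore H) round-trip exactly.

## The synthetic generator

`synthesize_unit()` draws effective-atom positions from the 3D Gaussian
with configurable sigmas (default 14 × 11 × 9 Å for n = 300, giving a
protein-like packing once a 3.5 Å minimum spacing is enforced by
rejection), then assigns hydrophobicity by mode: `ideal_micelle` rank-maps
H onto the scale range so the innermost residue is most hydrophobic,
`inverted_micelle` reverses it, `uniform_h` is constant, and `mixed`
permutes the ideal values at random. Each target H is snapped to the
nearest amino acid of the active scale, so fixtures are valid PDB files
whose hydrophobicities survive a round trip unchanged.
`synthesize_complex()` places chains a controlled gap apart, so interface
existence is dictated by the gap against the cutoff, and
`gen_profile_pair()` manufactures (T, O) pairs with a known K for
parameter-recovery checks.

These units emulate the *statistical* structure the model assumes — a
centric hydrophobic gradient, its inversion, or its absence — not real
protein geometry: there is no backbone, no secondary structure, no
side-chain packing, and hydrophobicity correlates perfectly (or
anti-correlates) with the radial coordinate. Passing tests on them shows
the estimator and pipeline behave correctly on inputs with known ground
truth; it does not by itself validate conclusions about any particular
real protein, for which deposited structures must be analysed.

The generator defaults are the package's fixed study conditions: with
n = 300 and the default sigmas, ideal micelles must fall below the
RD = 0.5 threshold and inverted micelles above it in at least 95% of 100
seeds, an assertion in the acceptance-level tests (in practice the two
forms separate with a wide margin; `scripts/acceptance.R` reports the
medians). Problem sizes in the test suite (80–300 residues, 100-seed
sweeps, K grids of 1001 points) keep a full run around half a minute while
leaving the statistical assertions well-powered.

## Limitations

* RD is a descriptive statistic; no significance test is attached, and the
  0.5 threshold is a convention, not an estimated decision boundary.
* Absolute RD and K values depend on the hydrophobicity scale, the contact
  function and the sigma convention; comparisons are most meaningful
  within one parameterisation.
* mmCIF input is not supported (PDB only); structures with only CA atoms
  are analysed with CA effective atoms and a warning.
* No membrane-specific field construction beyond the K-blend; no
  solvent-accessibility weighting; no automatic domain decomposition.
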