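---
title: "Fragment assembly of excited-state properties: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment assembly of excited-state properties: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmfcc)
```

## The model

The package targets a chromophore (a fluorophore such as a thiazole-orange
derivative) bound inside a structured RNA, where the electronic excitation
is localized on the chromophore but measurably perturbed by the surrounding
ribonucleotides. The working assumption of every formula here is **local
excitation**: the dominant electronic reorganization on absorption stays
within the chromophore and its immediate contacts. When that assumption
fails (charge-transfer states, stacked chromophore dimers), no two-body
truncation is reliable and the method should not be used.

Under local excitation, the excitation energy of the complex is assembled
from small fragment calculations:

* the **one-body** term $\omega_m$: the chromophore alone, computed in the
  point-charge field of every other atom of the system (a QM/MM
  calculation);
* **two-body corrections** $\omega_{mj}-\omega_m$ for every residue $j$
  whose closest-contact distance to the chromophore is at most
  $\lambda_{2B}$: the change in the excitation when residue $j$ is moved
  from the MM field into the QM region together with the chromophore.

$$\omega = \omega_m + \sum_{j,\ R_{mj}\le\lambda_{2B}} (\omega_{mj}-\omega_m)$$

The identical pattern, applied componentwise, assembles the transition
electric dipole moment and the excited-state atomic forces on the
chromophore; the oscillator strength is
$f = \tfrac{2}{3}\,\omega\,|\boldsymbol\mu|^2$ in atomic units, with
$\omega$ converted from eV to hartree first — the conversion is the reading
under which the shipped benchmark rows reproduce their printed $f$ values
to four decimals.

If the chromophore is covalently part of the chain (residue $m$), the
one-body term is replaced by the local conjugate-cap combination: the three
capped fragments centred at $m-1, m, m+1$ minus the two concaps at $m-1$
and $m$, with two-body corrections restricted to residues outside
$[m-2, m+2]$ (the window already covered by the local fragments).

Ground-state total energies use the molecular-fractionation combination:
capped residues ($i = 2..N-1$ within each chain) minus concaps
($i = 2..N-2$), plus two-body terms $\tilde E_{ij}-\tilde E_i-\tilde E_j$
for non-neighboring pairs in contact, minus a charge–charge
double-counting correction. Chains of one or two residues carry no
cap/concap structure and contribute a single whole-chain embedded fragment.

## Fragmentation conventions

**Cut site.** The backbone is severed at the C3′–O3′ ester bond. The
package groups each ester oxygen with the residue whose phosphate it
esterifies (the downstream residue), so a whole-residue subset always has
its boundary exactly at severed C3′–O3′ bonds. PDB files following the
standard convention (O3′ stored with the upstream residue) are regrouped on
reading; the author numbering is preserved for writing. Backbone bonds are
detected geometrically (a cross-residue C3′/O3′ pair within 1.8 Å), so
chain breaks and non-covalent ligands simply contribute no bond. Atom-name
dialects (`C3`, `C3*`, `C3'`) are normalized to the primed form.

**Link atoms.** Each severed valence is saturated by a hydrogen on the
original bond axis: 1.09 Å from a kept C3′, 0.96 Å from a kept O3′. The
placed hydrogen, its anchor, and the replaced atom (with coordinates) are
recorded as provenance in every fragment.

**Index ranges.** The concap sum runs $i = 2..N-2$; for a three-residue
chain it is empty and the single capped fragment *is* the whole chain, so
the assembly collapses to one calculation. Terminal residues simply omit
the missing cap.

**Pair enumeration.** Same-chain ground-state pairs require a sequence
separation $j \ge i+3$ (nearer pairs are already inside the cap/concap
species); pairs in *different* chains are non-neighboring at any index
separation and are enumerated purely by distance. This cross-chain
extension is what lets a non-covalent ligand participate in the
ground-state two-body sum. All thresholds are closed ($R \le \lambda$).

## Embedding and charges

Background charge sets contain one point charge per atom outside the QM
region, except the atoms replaced by link hydrogens, which are **excluded,
not redistributed** (the exclusion is logged per fragment). Charge models
come in two forms: force-field-style templates keyed by residue and atom
name (each template residue must carry an integral total charge), and
per-atom tables keyed by serial for ESP-style charges fitted to one
structure.

**Double counting.** The interaction of a QM-treated ground-state pair is
counted once by its explicit two-body term and once more at the MM level
through the embedding fields of the one-body species. The package therefore
(a) evaluates the two-body triples $\tilde E_{ij}, \tilde E_i, \tilde E_j$
*without* embedding charges, so their difference isolates the bare pair
interaction, and (b) subtracts the MM Coulomb interaction of each
enumerated pair once ($E_{dc}$). This concrete reading makes the assembly
an exact identity for a strictly pairwise energy model (verified to
1e-10 hartree by the mock-engine oracle below); it is isolated behind
`double_counting_correction()` so an alternative convention is a
one-function change.

## The mock engine

`mock_engine()` is a closed-form engine whose purpose is to make every
assembly formula testable *exactly*, not to approximate electronic
structure:

* ground state: per-element self-energies, plus an internal residue-pair
  Coulomb term scaled by `alpha_g`, plus **half** of the
  fragment–background Coulomb interaction. The half is a symmetric
  partition: each interaction is shared between the two fragments that see
  it, so summing embedded fragments counts it exactly once — the property
  that makes the ground-state combination close algebraically.
* excitation: $\omega_0$ plus $\alpha\sum q_p/d_p$ over environment atoms
  inside the QM region and $\beta\sum q_p/d_p$ over background charges
  ($d_p$ = distance to the chromophore centroid), plus an optional
  collective term $\tau\,(\sum |q_p|/d_p)^2$ over the QM environment.
* transition dipole: $\boldsymbol\mu_0 + \gamma \sum_p q_p
  (\mathbf r_p - \mathbf r_c)/d_p^2$ over QM-region environment atoms only
  (the background field deliberately leaves the mock transition density
  unpolarized; this is the reading under which the dipole assembly is an
  exact identity while its two-body corrections stay non-trivial).
* forces: the analytic gradient of the mock excited-state energy with
  respect to the chromophore atoms, cross-checked against central
  differences to 1e-6 hartree/bohr in the tests.

Link hydrogens are zero-charge QM atoms; for embedded tasks the engine
restores the charge of each replaced atom to the background at its original
position. With that single rule a fragment's electrostatic footprint is
exactly its source residues, and the excitation, dipole, force and
ground-state assemblies all reproduce the brute-force whole-system mock
values identically once the threshold covers every residue. With
$\alpha \ne \beta$ (preset `preset_pairwise()`) the two-body corrections
are non-zero, so the oracle exercises real cancellation, not trivial
zeros. `preset_nonadditive()` sets $\alpha=\beta$ and $\tau>0$: the
assembly error is then a genuine three-body residual that shrinks
monotonically as $\lambda_{2B}$ grows, reproducing the qualitative
convergence behaviour of the real method.

## The toy generator

`make_toy_complex()` builds a pseudo-RNA chain of five-atom residues
(O3′, P, C3′ and two side-group atoms; consecutive residues joined by a
1.43 Å C3′–O3′ bond) plus a rigid seven-atom toy chromophore, by default in
its own chain about 12 Å below the backbone. Requested contact distances
are realised by repositioning one side-group atom of the contact residue
toward the nearest chromophore atom, verified to 0.05 Å; the backbone is
never deformed, so bond-length invariants hold for every generated
structure. A seeded jitter (±0.03 Å on side-group atoms) makes different
seeds give distinct but reproducible geometries.

What the toys emulate: the bookkeeping and geometry that the fragmentation
and assembly layers depend on — named cut-site atoms, backbone topology,
per-residue integral charges, controllable contact shells, a cationic
ligand. What they do not emulate: chemistry. Residues are minimal
templates, the chromophore is a rigid ring, and no generated structure is a
meaningful conformer. Consequently, passing the oracle suites demonstrates
that the *combination formulas and bookkeeping* are exact, and says nothing
about the accuracy of any particular electronic-structure method on real
RNA — that is what the shipped published benchmark tables are for.

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `lambda_2b` | two-body contact threshold | Å | 4 (converged in the published benchmark) |
| `lambda_fs` | truncated full-system QM-region threshold | Å | 4 |
| link lengths | H–O3′ / C3′–H cap bonds | Å | 0.96 / 1.09 (fixed) |
| `state_index` | excited-state ordinal passed to engines | — | 1 (lowest state; no cross-fragment state tracking is attempted) |
| `embedded` | EE-GMFCC vs plain GMFCC | — | `TRUE` (decomposition forces `FALSE`) |

Unit policy: coordinates are Å throughout the structure layer; Coulomb
arithmetic converts to bohr internally (1 Å = 1.8897259886 bohr); energies
are hartree internally, excitations eV (1 hartree = 27.211386245988 eV),
wavelengths from $\lambda = 1239.84193\,\mathrm{eV\,nm}/E$.

## Numerical choices and degenerate inputs

* Alternate locations resolve to the first conformer; insertion-coded
  residues are distinct residues in file order.
* Distance thresholds are closed; monotonicity of neighbor sets in the
  threshold is a tested invariant.
* Coincident charges raise a singularity error rather than returning Inf.
* The decomposition refuses electrostatically embedded inputs (provenance
  error): the embedding field folds many-body electrostatics into every
  two-body term and obscures the per-residue contribution.
* Assemblies require a result for every enumerated fragment and fail with
  the missing labels listed; there is no silent partial assembly.
* Engine results are validated on parse: $\omega$ must agree with
  $(\tilde E' - \tilde E)$ to 1e-6 eV when both energies are present.
* Note on the shipped decomposition benchmark: one published row (G29 at
  the TD-HF level) prints a shift of −68 meV that is inconsistent with its
  own printed excitation energies (3.141 vs 3.309 eV, i.e. −168 meV); the
  package always recomputes shifts from the energies, so it reports
  −168 meV for that row.

## Problem sizes used in the test suite

The oracle suites run on an 8-residue toy complex with contacts at
2.5/3.4/4.5/5.5 Å (47 atoms, 9 residues) and on 3–9-residue variants for
boundary cases; the whole suite is pure arithmetic and completes in well
under a minute. These sizes were chosen because every assembly identity
checked is exact at any size, so larger toys add cost without adding
discrimination.

## Known limitations

* Single-residue chromophores only; multi-residue or covalently branched
  chromophores are out of scope.
* No protonation or structure repair: hydrogens present in the input are
  kept verbatim, missing ones are not added.
* No three-body or higher QM corrections (the electrostatic embedding is
  expected to absorb most of them in practice).
* No state tracking across fragments: `state_index` is taken at face
  value in every fragment, which can mix states if the ordering changes
  between the one-body and a two-body species.
* Excited-state geometry optimization with the assembled forces is not
  provided.
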