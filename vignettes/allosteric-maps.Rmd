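---
title: "Allosteric signalling and probing maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric signalling and probing maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokit)
```

allokit quantifies allosteric communication in a protein: how a point
mutation or a small ligand bound at one site changes the conformational
free energy felt at every other residue. This vignette is the package's own
account of the model, its tunable parameters, the numerical conventions, and
what the synthetic test structures do and do not demonstrate.

## The harmonic model

The protein is reduced to its C-alpha trace. Residues closer than a cutoff
(default 10 Å) are joined by harmonic springs of uniform stiffness
`k0 = 1` (model units), giving an anisotropic elastic network whose
3N × 3N Hessian has, for each contact (i, j), the off-diagonal block
\(-(k_{ij}/d_{ij}^2)\, r_{ij} r_{ij}^\mathsf{T}\) with \(r_{ij}\) the bond
vector, and diagonal blocks that make every block row sum to zero. The
directional (anisotropic) form is required rather than a scalar
Gaussian-network Laplacian because the downstream stiffness formula consumes
the per-residue *3-vectors* of each normal mode. Eigendecomposition of the
Hessian yields normal modes \(e_\mu\); six zero-eigenvalue rigid-body modes
are discarded (see *Numerical conventions*).

## Per-residue free energy of a perturbation

Each residue i feels each retained mode through a local stiffness
(elastic-work) coefficient

\[\varepsilon_{\mu,i} = \sum_{j} \lvert e_{\mu,i} - e_{\mu,j} \rvert^2 ,\]

with j running over the contact neighbours of i in the network. Integrating
the quadratic allosteric potential over the Gaussian mode amplitudes gives a
per-residue partition function whose constant prefactors cancel in any
ratio, so the free-energy response to a perturbation P needs only the
stiffness ratio:

\[\Delta g_i^{(P)} = \tfrac{1}{2} k_B T \sum_\mu
  \ln \frac{\varepsilon_{\mu,i}^{(P)}}{\varepsilon_{\mu,i}^{(0)}} .\]

The allosteric *modulation* subtracts the chain mean,
\(\Delta h_i = \Delta g_i - \langle \Delta g \rangle\), removing the
background shift every perturbation induces; by construction every profile
the package returns has `mean(dh)` equal to zero to machine precision. The
mean is the plain residue-count-weighted average over the processed chain
(one chain per run).

Three perturbation kinds realise the generic mutation/binding picture:

* **up** — substitution by a bulky residue: every contact of the mutated
  residue is stiffened by `alpha_up` (default 2).
* **down** — substitution by the smallest, Gly-like residue: every contact
  of the residue is removed *except* its sequential backbone contacts (a
  glycine still has a backbone; this also keeps the chain connected).
* **probe** — a small ligand bound to a three-residue segment: contacts of
  the three residues are stiffened by `alpha_bind` (default 2) and the three
  pairwise contacts within the segment are added where absent.

These spring-level rules are this package's concrete realisation of the
verbal definitions in the literature; `alpha_up` and `alpha_bind` are
config-exposed so alternative parameterisations can be swapped in.

The *modulation range*
\(\Delta h_i^{(m\downarrow\uparrow)} = \Delta h_i^{(m\uparrow)} -
\Delta h_i^{(m\downarrow)}\) is the dynamic range of signalling attainable
by mutating position m, and is antisymmetric under reversing the
substitution direction — exactly, because the package computes the reverse
direction as the negation rather than re-deriving it.

## Maps and fingerprints

`compute_asm()` scans every position m and stacks the N modulation-range
profiles into the N × N Allosteric Signalling Map (rows: perturbed
position; columns: responding residue; up-only and down-only maps are
selectable). `compute_apm()` scans every consecutive three-residue segment
into the (N − 2) × N Allosteric Probing Map. Rows are computed with the
same code path as the standalone profile functions and are bit-identical to
them. A position whose down mutation would disconnect the network yields a
row of `NA` (serialized as the `NA` sentinel, never as fake zeros).

`make_fingerprint()` masks entries that are either *proximal* — minimum
C-alpha distance from the row's perturbed residue(s) strictly below `d_min`
— or *weak* — |Δh| not exceeding `h_min`. The defaults `d_min = 12` Å and
`h_min = 0.1` kcal/mol are this package's operational choices (the
literature gives no universal numbers) and are recorded in every map's
provenance. The weak-signal comparison is deliberately non-strict
(`<=`), so the degenerate setting `h_min = 0` masks exactly the
exact-zero entries while `d_min = 0` masks nothing; both rules are monotone
in their threshold. Maps above ~1200 residues are best inspected through
`zoom_map()`, which extracts contiguous blocks with labels and provenance
intact.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 10.0 | Å | contact distance of the elastic network |
| `k0` | 1.0 | model | uniform native spring constant |
| `alpha_up` | 2.0 | — | stiffening factor of an up mutation |
| `alpha_bind` | 2.0 | — | stiffening factor of probe binding |
| `kBT` | 0.593 | kcal/mol | thermal energy (≈ 298 K); sets the output scale |
| `rigid_tol` | 1e-8 | relative | rigid-mode eigenvalue cut |
| `neighbors` | "contacts" | — | j-set of the stiffness sum |
| `eps_floor` | 1e-12 | — | floor under stiffness before the log ratio |

Free energies are reported in kcal/mol. Because \(\Delta g\) depends only on
eigenvectors, a uniform rescaling of all spring constants leaves every
profile at numerical zero — one of the package's standing self-checks.

The `neighbors = "all"` switch sums the stiffness over every other residue
instead of contact neighbours. It is provided because the defining sum can
be read either way; the contact reading is the default since the elastic
work is exerted by the *surrounding* residues and an all-pairs sum would be
cutoff-independent. Eigenvalues never enter the stiffness (the formula
contains no \(\lambda_\mu\)); an optional `mode_weighting` flag scales
eigenvectors by \(1/\sqrt{\lambda_\mu}\) for exploration and defaults off.

## Numerical conventions

* **Rigid-mode cut.** Modes with eigenvalue below `rigid_tol` times the
  largest eigenvalue are dropped. A connected, non-collinear network has
  exactly six; a disconnected network is reported as an error naming its
  components, while degenerate geometries (collinear beads) only message.
* **Under-constrained residues after a down mutation.** A residue kept by
  only its two backbone springs resists no displacement perpendicular to
  both bond vectors, so the perturbed network gains one exact-zero mode (two
  at a chain terminus). Mode counts of the native and perturbed states then
  differ after the rigid cut. The package pairs states by ascending
  eigenvalue rank *from the stiff end* and excludes the excess softest
  modes of the larger state, with a message; a mismatch larger than six
  still errors. This convention keeps the down scan defined at every
  position while perturbing the pairing least, since the discarded modes
  are precisely the (near-)floppy ones the rigid cut already treats as
  non-thermal.
* **Stiffness floor.** Entries below `eps_floor` are floored (and counted)
  before the log ratio to avoid −Inf from numerically null stiffness.
* **Degeneracy.** Within a degenerate eigenvalue subspace the per-mode
  stiffness is basis-dependent; near-degenerate pairs (relative gap below
  1e-6) are reported via a message. Generic structures — and all toys used
  for stiffness-level assertions — are non-degenerate.
* **Identity short-circuit.** A perturbation that leaves the network
  unchanged (e.g. `alpha_up = 1`) returns an exactly zero profile without
  touching the eigensolver.
* **Determinism.** The scientific core is seed-free; randomness exists only
  in the synthetic-structure generators, which are seeded and bit-for-bit
  reproducible.
* **Indexing.** Residue positions are 1-based throughout, the R convention;
  file I/O preserves author numbering and labels rows/columns with
  chain + residue number.

## Structure input and the quality filter

`read_structure()` accepts PDB (via bio3d) and mmCIF. For mmCIF the package
carries a small name-mapped `atom_site` loop reader, so AlphaFold-style
column orderings parse identically to their PDB counterparts. Alternate
locations keep the highest occupancy (ties: first altloc identifier);
residues without a C-alpha are skipped with a warning; multi-chain files
require an explicit chain because the engine is single-chain by design.

AlphaFold-style models store the per-residue pLDDT confidence (0–100) in
the B-factor field; `extract_plddt()` lifts it out and rejects off-scale
values. The quality filter then applies the published selection rules with
*strict* comparisons, read literally from their prose ("lower than",
"shorter than", "larger than", "more than"):

* a residue is low-confidence (LCR) when pLDDT < 70 (70.0 itself is
  confident);
* fail when the LCR percentage reaches 10% (prokaryotes) / 20%
  (eukaryotes) — eukaryotes are looser because of their larger disordered
  regions;
* fail when the longest consecutive LCR run reaches 15 / 25 residues;
* fail when the first 20 residues are all LCR (a low-confidence signal
  peptide); chains shorter than the window are checked over their full
  length;
* fail when the chain is not strictly larger than 50 residues; browsing
  eligibility additionally demands more than 100.

Exact-boundary structures (10% exactly, a run of exactly 25, N = 50,
N = 100) therefore *fail* the corresponding gate. The comparisons live in
one place (`apply_filter()`), so a different boundary convention is a
one-line change, and the kingdom presets are data with full override.

## What the synthetic structures show — and what they do not

`make_helix()` uses canonical alpha-helix C-alpha geometry (1.5 Å rise,
100° twist, 2.3 Å radius); `make_two_domain()` joins two compact seeded
random coils with an extended linker as a minimal long-range-signalling
testbed; `make_random_coil()` provides generic non-symmetric geometry for
oracle comparisons; `make_plddt_profile()` builds piecewise-constant
confidence tracks for exhaustive filter truth tables.

These toys exercise every code path and every algebraic invariant of the
engine (null perturbations, scale and rigid-motion invariance,
antisymmetry, mean-centring, shape contracts, brute-force equivalence on
small networks against an independently coded double-loop oracle). They do
not emulate real protein contact topology, secondary-structure packing, or
realistic pLDDT autocorrelation, so passing them validates the
*implementation* of the model, not the biological accuracy of its
predictions on any particular protein. Problem sizes in the shipped checks
(50-residue helices for null tests, 30-residue toys for scans, a
100-residue full signalling map, 25 random small networks for the oracle)
were chosen as the smallest structures on which every property is
non-trivial.

## Known limitations

* Single chains only: signalling across protomer interfaces in oligomers
  needs the assembled complex and is out of scope.
* The mutation model is generic up/down — no amino-acid-specific
  energetics.
* One perturbation site per profile; combined multi-site perturbations are
  an extension point, not a feature.
* The dense eigensolver makes whole-map scans practical up to roughly a
  thousand residues; beyond that, compute maps once and explore them with
  `zoom_map()`.
* Normal modes of a harmonic C-alpha model are the cheapest description of
  the dynamics; replacing them with covariance modes from atomistic
  simulation is a known refinement outside this package's scope.
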