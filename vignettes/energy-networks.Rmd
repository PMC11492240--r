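---
title: "Interaction-energy residue networks: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-energy residue networks: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reinet)
```

## The model

Residue networks built purely from geometry (contact maps, COM distance
thresholds) treat a salt bridge and a grazing van der Waals contact as the
same edge. The premise of this package is that the *physical strength* of an
interaction is the better edge weight: two residues are close in the network
when they exchange a lot of nonbonded energy, wherever their centres of mass
happen to sit. The analysis pipeline is

1. pairwise residue nonbonded energies per trajectory frame,
2. an undirected graph with edge cost `1 / mean(|E|)` per pair,
3. all-pairs shortest paths (Dijkstra) and per-residue column averages,
4. normalisation, peak/mean ratios, and cross-structure comparison through a
   global sequence alignment.

Two classical distance-based networks (frame-averaged COM contacts at 8 Å;
single-snapshot atom contacts at 3.5 Å with inverse-connectivity costs) are
implemented alongside so the three constructions can be contrasted on the
same trajectory with the same path analysis.

The interpretation of the profile rests on one assumption: residues whose
average shortest-path length is small are tightly coupled to the rest of the
structure, so perturbing them (mutation, ligand binding) is expected to be
more disruptive. Catalytic residues tend to sit at the profile minimum;
residues whose profile value stands far above the mean (peak/mean ratio ≫ 1)
are weakly coupled outliers and candidate mutation sites.

## The energy terms

For atoms $i \in A$, $j \in B$ at distance $r_{ij}$:

$$E^{LJ}_{ij} = \varepsilon_{ij}\left[\left(\tfrac{r^{min}_{ij}}{r_{ij}}\right)^{12}
  - 2\left(\tfrac{r^{min}_{ij}}{r_{ij}}\right)^{6}\right] S(r_{ij}), \qquad
E^{elec}_{ij} = \frac{C\, q_i q_j}{\epsilon\, r_{ij}}\,\varphi(r_{ij})$$

with Lorentz–Berthelot-style CHARMM combination
$\varepsilon_{ij}=\sqrt{\varepsilon_i \varepsilon_j}$,
$r^{min}_{ij} = r^{min}_i/2 + r^{min}_j/2$, and
$C = 332.0636\ \mathrm{kcal\,\mathring{A}/(mol\,e^2)}$. Distances are in Å,
charges in elementary charges, energies in kcal/mol throughout.

$S(r)$ is the CHARMM switching polynomial
$(r_c^2-r^2)^2 (r_c^2 + 2r^2 - 3 r_{on}^2)/(r_c^2-r_{on}^2)^3$, equal to 1
below $r_{on}$ and 0 beyond $r_c$ and $C^1$-continuous at both ends. The
defaults $r_{on} = 10$ Å, $r_c = 12$ Å match common CHARMM36/NAMD production
settings; both are exposed in `nb_params()`.

**Electrostatic cutoff scheme.** Production simulations usually treat
electrostatics with particle-mesh Ewald, but a lattice sum cannot be
decomposed into per-residue-pair contributions. Pair energies therefore use
a cutoff scheme, selectable via `nb_params(elec_scheme=)`: `"shifted"`
(default) multiplies by $(1-(r/r_c)^2)^2$, `"switched"` reuses $S(r)$, and
`"truncated"` cuts abruptly. The choice is recorded in every serialized
energy matrix; the shifted default is this package's own convention for a
smooth, per-pair-decomposable approximation, not a claim about how any
particular production run treated long-range electrostatics.

**Exclusions.** Atom pairs one or two bonds apart (1-2, 1-3) are excluded
from the sums; pairs three bonds apart (1-4) use per-type Lennard-Jones
override parameters when the parameter table provides them and an
electrostatic scale factor (`scale14_elec`, default 1.0 per CHARMM36).
Hydrogens participate fully. Pair classes are derived from the PSF bond
graph by breadth-first search; a property test checks this classification
against an independent shortest-bond-path search on random bond graphs.

**Prefilter.** Residue pairs whose minimum atom–atom distance stays above
`cutoff + 2 Å` in every retained frame are skipped. The 2 Å margin makes
the filter superset-safe: it can only reduce cost, never change a result,
because any skipped pair is beyond the cutoff in every frame and would
contribute exactly zero.

**No periodic imaging.** Minimum-image corrections are not applied: residue
pairs within 12 Å of each other inside a solvated protein are unaffected by
box images in any reasonably sized box. Users post-processing wrapped
coordinates should unwrap the protein first.

## Network construction rules

- COM network: mass-weighted centres, distances averaged over frames *then*
  thresholded (averaging first is the stated convention; the alternative —
  thresholding per frame and averaging the indicator — would yield a
  contact-frequency network with different semantics). The boundary is
  inclusive: an averaged distance of exactly 8 Å is an edge.
- Atom-contact network: built from one snapshot (conventionally the final
  one, via `get_frame()`), strict `< 3.5 Å` boundary. The connectivity from
  A to B divides the raw contact count `c` by `I`, the atom count of the
  *source* residue. The normalisation direction is an assumption made here
  and stated prominently: dividing by the source residue's atom count
  reproduces the intended asymmetry (`c/I` vs `c/J`), and both directions
  recover the same raw count, which a unit test asserts.
- Energy network: edge cost `1/mean|E|`; pairs with mean |E| below
  `min_energy` (default `1e-8` kcal/mol) get no edge rather than a
  near-infinite cost dominated by floating-point noise. Attractive and
  repulsive interactions of equal magnitude receive identical costs by
  construction.

## Path analysis choices

- Costs must be strictly positive; Dijkstra (via igraph) is exact there. An
  independent Floyd–Warshall implementation lives in the test suite and the
  acceptance script, never in the package path.
- Self-distances are excluded from the per-residue average ("to all the
  *others*"); including the zero diagonal would merely scale every value by
  $(N-1)/N$ and is not exposed.
- For directed networks the profile averages *incoming* path lengths
  (column convention); `direction = "out"` exposes row averaging as a
  sensitivity check.
- Unreachable pairs are excluded from averages and counted per residue. A
  residue unreachable from everywhere gets `Inf` and a warning; if more than
  10% of ordered pairs are unreachable the profile errors, since a dense
  residue network that disconnected signals a degenerate input rather than
  a meaningful profile.
- `normalize_profile()` divides by the mean of finite values by default, so
  normalised profiles have mean 1 and the peak/mean ratio is invariant under
  it (and under any uniform edge-cost scaling — a tested invariant).
  Min–max normalisation is available when a bounded [0, 1] scale is needed;
  it errors on degenerate (constant) profiles.

## Alignment and comparison

Cross-structure comparison refuses raw profiles: path lengths from different
network types carry different units (Å, inverse connectivity, mol/kcal), so
only same-method-normalised profiles of same-semantics networks are
compared. Residue pairing uses Needleman–Wunsch global alignment with affine
gaps (Biostrings backend; BLOSUM62, gap open 10, extend 0.5 by default — a
widely used global-alignment default, all configurable and echoed into the
outputs). Traceback ties are resolved deterministically by the backend, so
repeated runs give identical alignments; score optimality is asserted
against exhaustive enumeration of all alignments for short sequences.
Columns where either side has a gap contribute nothing to the mean absolute
difference and are reported explicitly so plots can show residues without a
partner.

Modified residues map to `"X"` during sequence extraction unless an explicit
mapping (e.g. `c(MSE = "M")`) is opted into — alignment robustness without
silent chemistry assumptions.

## What the synthetic systems emulate — and what they do not

`make_toy_system()` generates few-atom "residues" with known charges,
Lennard-Jones types, bond chains and jittered multi-frame coordinates, and
writes them through the same PDB/PSF/parameter/XYZ formats the production
readers parse, together with a JSON sidecar of exact per-frame pair energies
from a deliberately naive double-loop oracle that shares no code with the
vectorised energy module. Trajectory noise is isotropic per-atom Gaussian
jitter: no physical dynamics, no solvent, no secondary structure. Passing
tests therefore demonstrate that the arithmetic, bookkeeping (exclusions,
1-4 overrides, switching, cutoffs) and graph analysis are correct — they do
not validate the biological interpretation of connectivity profiles on real
proteins, which requires real trajectories.

`make_hub_system()` emulates the one structural feature the method is
supposed to detect: a few residues interacting much more strongly with the
rest of the structure than typical residues do, as a catalytic triad does.
Hub atoms carry zero Lennard-Jones well depth so their pair energies are
exactly linear in the hub charge scale; the scale is solved from one cheap
matrix evaluation so that every hub pair's mean |E| exceeds
`hub_strength_factor` times the median non-hub pair energy by construction.
With factor 10 the hub is recovered as the connectivity minimum essentially
always; with factor 1 no ordering is guaranteed (negative control). The
geometry (19 residues on a 6 Å Fibonacci sphere, hubs at the centre, 2 atoms
per residue, 3 frames, 0.05 Å jitter) keeps every residue pair inside the
nonbonded cutoff while spacing atoms far enough apart that the geometry is
valid on the first draw.

Generator defaults (2–8 atoms per residue, charges within ±0.5 e, well
depths 0.05–0.2 kcal/mol, r_min/2 of 1.2–2.0 Å, 5 Å residue spacing, 0.1 Å
jitter, 3 frames) are chosen once to resemble heavy-atom-scale protein
parameters at interaction distances where all code paths (switching region,
cutoff, exclusions) are exercised; they are not tuned per test.

## Numerical and degenerate-input choices

- Energies are exactly zero at and beyond the cutoff (enforced, not just
  small), so the prefilter and the energy terms agree exactly.
- Coincident atoms (r = 0) raise a singularity error rather than returning
  ±Inf; the generator rejects geometries with any distance below 0.5 Å and
  redraws from the same seeded stream (bounded retries), keeping outputs a
  pure function of the seed.
- Non-finite profile values written to a PDB B-factor column become the
  sentinel 999.99 with a warning; finite values are clamped to the
  fixed-width column range.
- The problem sizes run by default — toy systems of ≲ 50 atoms, 200 random
  graphs of ≤ 50 nodes, 100 hub replicates of 20 residues — are the scales
  at which every property is checked exhaustively against oracles; the same
  code paths handle real protein systems, where the energy stage dominates
  cost as roughly N²/2 candidate pair evaluations per frame.

## Known limitations

- Per-pair electrostatics are a cutoff approximation; absolute energies will
  differ from lattice-sum totals, though the network topology is driven by
  short-range pairs where the schemes agree well.
- Solvent-mediated coupling is invisible: the pair energies see only the
  protein atoms supplied.
- The atom-contact normalisation direction (`c/I` vs `c/J`) is a documented
  assumption (see above).
- Only the first model of a PDB is read; CIF/mmCIF, CMAP and bonded energy
  terms, and free-energy estimates are out of scope.
- Headline biological findings on real proteases (catalytic-triad minima,
  mutation-site peaks) require hundreds of nanoseconds of trajectory and are
  not reproducible from this package's synthetic systems; the package
  reproduces the *method*, with every computational property checked against
  independent oracles.
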