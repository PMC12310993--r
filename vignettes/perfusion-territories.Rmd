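---
title: "Supply-and-demand perfusion territories and the steady 1D network solve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supply-and-demand perfusion territories and the steady 1D network solve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfterra)
```

## The model

`perfterra` estimates how blood flow distributes over a segmented
cerebrovascular tree by coupling the tree to the tissue it must supply,
instead of inferring the split from vessel radii alone.

The inputs are (a) a centerline network — ordered 3D points with per-point
radii, organised into segments between junctions, with the internal carotid
and basilar arteries marked as inlets — and (b) a tetrahedral tissue mesh
whose elements carry a tissue class. Three stages follow.

**1. Tessellation.** Source points are all vessel outlets plus every
centerline point within `d_max = 3` mm of the nearest element centroid (a
stand-in for perforating arteries, which leave large vessels directly).
Each element goes to the source minimising Euclidean distance over
propagation speed, $\|x - p_i\|/c_i$, with territories constrained to grow
over connected tissue only. Speeds are uniform by default, and the
assignment is invariant to rescaling all of them; it depends on source
*positions* only, never radii.

**2. Demand.** Territory demand is mass times regional cerebral blood flow:
$Q_i = \rho \sum_{j \in R_i} v_j\,CBF_j$, with $\rho = 1.04$ g/mL and CBF
0.8 / 0.2 / 0.5 mL·min⁻¹·g⁻¹ for gray / white / remaining tissue (a uniform
0.5 table is available to probe the influence of the regional contrast;
on territories the size of a major artery's the difference is small because
gray and white matter average out).

**3. Steady 1D solve.** Within each segment the 1D momentum balance —
rigid wall, flow constant along the segment by continuity, uniform
cross-section equal to the segment average $S = \pi \bar r^2$ — loses its
convective term $\partial_z[(1+\delta)Q^2/S]$ and axial diffusion
$\nu\,\partial_z^2 Q$ identically, leaving
$dp/dz = \rho N Q / S^2$ with $N = -8\pi\nu$: Poiseuille's law, i.e. a
per-segment conductance $g = \pi \bar r^4 / (8 \mu L)$. The steady problem
is therefore *exactly* a sparse linear nodal system and no time-marching is
performed; the profile parameter $\delta = 1/3$ is kept in
`fluid_constants()` for completeness but cannot enter the steady solution.
Inlets are pinned to the mean aortic pressure (93.33 mmHg, assuming
negligible loss between the aorta and the ICA/BA); outlet-source demands
are withdrawn at their outlet nodes; perforator demands within a segment
are lumped and withdrawn at the segment's arclength midpoint, realised by
splitting the segment into two half-length edges (a zero-length virtual
branch — the internal pressure drop of a finite virtual branch would be
unobservable in any reported output). Junctions impose pressure continuity
and mass conservation only. Blood constants: $\rho = 1.06$ g/cm³,
$\mu = 0.04$ g/cm/s.

Reported outputs are the relative flow ratios of the six major cerebral
arteries, measured at their M1/A1/P2 segments, the inlet split over
LICA/RICA/BA, and optionally the per-territory inlet contribution fractions
obtained from a flow-weighted mixing solve (useful where communicating
arteries let two inlets supply one territory).

The comparator model (`murray_flows()`) splits the same total demand over
the outlets by cubic radius weights and solves the same network with no
perforator sinks.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `d_max` | 3 | mm | perforator-source capture distance |
| speeds $c_i$ | 1 (uniform) | — | tessellation weights |
| CBF gray/white/other | 0.8 / 0.2 / 0.5 | mL/min/g | demand per tissue mass |
| $\rho_{tissue}$ | 1.04 | g/mL | territory mass |
| inlet pressure | 93.33 | mmHg | Dirichlet boundary |
| $\mu$, $\rho_{blood}$ | 0.04, 1.06 | CGS | conductances |
| centerline spacing | 0.5 | mm | resampling target |
| sweep grid | 0–1 by 0.05 | mm | 21 truncation variants |
| atlas `min_count` | 10 | patients | probability-map support cut |

Geometry is in mm throughout; the solver converts internally to CGS
(1 mmHg = 1333.22 dyn/cm², 1 mL/min = 1/60 cm³/s) because the fluid
constants are conventionally quoted in CGS.

## Numerical and design choices

**Connectivity-constrained tessellation.** The exact Euclidean rule is
evaluated first (dense source-to-centroid distances, ties broken to the
smallest source id — ties have measure zero for generic geometry). Each
source then keeps the connected component of its cell containing its
lowest-cost element; orphaned elements are regrown onto adjacent
territories in increasing Euclidean-cost order. This reduces *exactly* to
the Euclidean rule whenever cells are connected — true on convex domains —
and enforces connected territories in folded geometry, where a gyrus
Euclidean-close to a source across a sulcus must not be captured by it.
An accumulated-geodesic front (Dijkstra over centroid hops) was rejected
because hop-path lengths exceed Euclidean distances by direction-dependent
factors on any mesh, so it would *not* reduce to the Voronoi rule even on
convex domains.

**Adjacency notion.** "Connected" defaults to sharing a mesh node
(`connectivity = "vertex"`); sharing a triangular face (`"face"`) is
available. Vertex adjacency is the closest discrete analogue of continuum
connectedness: under face adjacency, thin slivers of a convex Voronoi cell
are occasionally attached to their cell only through an edge and would be
severed spuriously.

**Element location.** An element is represented by its centroid, both for
the 3 mm source rule and the tessellation cost; sub-element resolution is
not meaningful at the mesh sizes involved.

**Summation order.** Per-element demands are computed once and summed in
ascending element order everywhere, so per-territory sums and their total
are reproducible and partition the total demand to within the
non-associativity of floating-point addition (in practice ≤ 1e-12
relative; often exact).

**Solver conditioning.** The nodal system is solved for pressure
*deviations* from the mean inlet pressure, so the unknowns live on the
scale of the pressure drops (∼dyn/cm²) rather than the absolute pressure
(∼10⁵ dyn/cm²); flows are formed from the deviations directly. This keeps
rounding noise — and with it spurious left/right asymmetry on symmetric
networks — near 1e-15 relative. Junction conservation is verified to
1e-10 relative after every solve.

**Mean segment radius** is the arclength-weighted (trapezoidal) average of
point radii, not a plain point average: pre-resampling centerlines have
uneven spacing. The same quantity drives truncation. The Murray outlet
radius is the mean over the distal-most 1 mm of the outlet segment
(configurable to the terminal-point radius); the choice is a convention,
stated here because it is not uniquely determined by the model.

**Truncation.** A segment is removable when its mean radius falls below
the threshold and its label is neither protected (the M1/A1/P1/P2
measurement segments and their parents) nor excluded (vessels known not to
perfuse the meshed tissue, e.g. ophthalmic); segments that lose every path
to an inlet go with it. Loop segments are only removable on their own
merits — removal of one branch cannot orphan them, since they remain
reachable around the loop — and segments touching an inlet are never
removed. Downstream orientation is fixed by breadth-first search from the
inlets; for loop segments whose ends are equidistant the orientation is
arbitrary but fixed (smaller endpoint id proximal).

**Sensitivity statistics.** Per artery, the sweep reports deviations of
the flow ratio from the *median* across the grid (the median resists the
large excursions that appear as truncation approaches 1 mm) with the
population (n-divisor) standard deviation — a descriptive statistic over a
fixed grid, not a sample estimate. Failed variants are flagged and
excluded rather than fatal.

**Atlas counting.** A cohort member labelling a voxel with several
arteries (overlap territories) contributes one count to each; an exclusive
single-label mode is the alternative input form. Ties in the majority map
go to the fixed artery order MCA, ACA, PCA and are flagged. Registration
to the template is out of scope; inputs must be pre-registered.

**Disconnected components.** Territories and demands are still computed
for a vessel tree disconnected from all inlets (the diseased-patient
situation); only the pressure solve refuses, naming the component's
segments.

## The synthetic phantoms

`make_phantom()` builds deterministic test geometry: a single segment, a
Y, a dyadic tree, and a circle-of-Willis-like network (`toy_cow`) with
three inlets, the six measurement segments, ACoA/PCoA collaterals with
variant toggles (absent communicating arteries; an LMCA disconnected from
every inlet), and distal branches reaching into a labeled box tissue
phantom. The tissue phantom is a structured lattice split into six
tetrahedra per cell, built on the x ≥ 0 half and mirrored, so left/right
symmetry is exact to the bit; interior-node jitter (never boundary nodes,
so the domain stays convex) is available. The box is convex and coarse
(1440 elements by default) by design: the tessellation's equivalence to
the brute-force Voronoi rule is only provable on convex domains, and the
phantom exists to make that and the conservation/symmetry properties
testable in seconds. What the phantoms deliberately do not emulate:
cortical folding (no geodesic-vs-Euclidean contrast is exercised), realistic
vessel tortuosity and calibre distributions, image noise, or registration
error — so passing tests demonstrate the algorithms' contracts, not
clinical accuracy on real anatomy.

Problem sizes used by the test-suite and the reproduction script: 1440
tissue elements, ≈650 source points, 21-variant sweeps; these keep every
end-to-end check within seconds to a couple of minutes on one CPU while
staying inside the element-count regime where the convex-oracle equivalence
is exercised meaningfully.

## Known limitations

* The steady formulation is exact for steady boundary data; pulsatile
  flow, compliant walls and stenosis minor losses are out of scope.
* Junctions carry no Bernoulli or minor-loss terms.
* Secondary collateral recruitment (leptomeningeal flow) is not modelled:
  demands are fixed by geometry, not by flow adequacy.
* Uniform propagation speeds are a modelling choice; flow-dependent speeds
  would couple tessellation and solve and are not implemented.
* The probability atlas assumes co-registered label volumes; no
  registration quality control is performed.
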