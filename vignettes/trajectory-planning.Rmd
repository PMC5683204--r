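---
title: "Connectional damage scoring for surgical trajectory planning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectional damage scoring for surgical trajectory planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroplanr)
```

## The problem and the model

Resecting or traversing brain tissue that is strongly embedded in the
individual's functional and structural networks ("eloquent" tissue) risks
cognitive, motor or language deficits. `neuroplanr` quantifies that risk
for a candidate surgical access path by combining two network views of the
same brain:

* a **functional connectivity** (FC) matrix — statistical similarity of
  regional activity time-series, signed, roughly in [−1, 1];
* a **structural connectivity** (SC) matrix — streamline counts between
  regions from tractography, nonnegative integers;

both defined over the same atlas parcellation (in clinical use, typically
the 70-region Desikan–Killiany atlas).

Every grey-matter region `k` receives its **node strength** (unsigned
weighted degree) in each network as an eloquence score:

$$\mathrm{FCGM}_k = \sum_{j=1}^{N} |\mathrm{FC}(k,j)|, \qquad
  \mathrm{SCGM}_k = \frac{\sum_{j=1}^{N} |\mathrm{SC}(k,j)|}{L_k},$$

where $L_k$ is the region volume in mm³. The volume divisor removes the
bias that a large region collects more streamline endpoints merely by
being large; its units make SCGM a fibre density (fibres/mm³). Node
strength is the simplest centrality that respects edge weights; other
centralities (betweenness, eigenvector) are deliberately out of scope.

A white-matter fibre `p` is scored by the regions it intersects,
$\mathrm{ROIs}_p = \{GM_1, \dots, GM_m\}$: its functional and structural
scores are the arithmetic means of the member regions' FCGM and SCGM. A
fibre that intersects no region scores 0 and is flagged `unassigned`
rather than dropped, so streamline indices remain stable identifiers
through the whole pipeline.

Two conventions deserve comment:

* **Diagonal zeroing.** The FC diagonal is an artefactual self-correlation
  of 1.0 and SC self-loops are meaningless, so `connectivity_matrix()`
  forces the diagonal to zero on load. With that convention the node
  strength sum over *all* `j` and over `j ≠ k` coincide, removing an
  ambiguity in the summation range.
* **Intersection, not endpoints.** Fibre–region assignment uses *every*
  region the streamline passes through, not only the regions of its two
  endpoints. Endpoint counting is how an SC matrix is built (out of scope
  here); the fibre score is explicitly defined over intersected regions.

## Trajectory model and tissue extraction

The access path between entry and target is the volume swept by a sphere
of radius `r` moving along the segment — a **capsule** (cylinder with
hemispherical caps). We implement membership analytically: a point is
inside iff its distance to the closed segment is ≤ `r`. The sampled
sweeping-sphere construction survives as an independent test oracle, and a
flat-capped cylinder is available behind `cap = "flat"` for users who
prefer a blunt tube end. The default radius is 5 mm, a typical working
channel.

`extract_tissue()` counts every labeled voxel whose **centre** lies in the
tube (no partial-volume weighting — simple and exactly checkable against a
brute-force scan) and every streamline with at least one resampled vertex
inside. Streamlines are resampled to a uniform arc-length step of half the
shortest voxel edge before any voxel lookup, so a sparse two-vertex
polyline cannot skip voxels or slip through a tube between its vertices.
Candidate points are pruned to the tube's axis-aligned bounding box first;
the pruned result is bit-identical to the full scan (tested).

The four **raw damage components** of a tube weight the intersected
volumes and fibres by their scores:
$\mathrm{FCGM}_{path} = \sum_k V_k\,\mathrm{FCGM}_k$ (and analogously
SCGM), $\mathrm{FCWM}_{path} = \sum_p \mathrm{FCWM}_p$ (and analogously
SCWM). All four are nonnegative and non-decreasing in the radius.

## Entry-point search and the risk map

Candidate entries form a lattice of 10 mm pitch on five faces of an
axis-aligned box — the bounding box of all labeled voxels expanded by a
10 mm margin; the sixth (base) face, by default at minimal z (inferior,
where the head rests), contributes no interior entry points, though its
edges survive as members of the adjacent faces. When the pitch does not
divide an edge the lattice is centred along that axis. For a 100 mm cube
this yields exactly 521 unique points (602 surface lattice points minus 81
base-interior points).

Every entry is evaluated as a tube to the target. Because the four raw
components live on incommensurate scales, each is min–max scaled *across
the entries of that search*:

$$X' = \frac{X - X_{\min}}{X_{\max} - X_{\min}},$$

with the degenerate case $X_{\max} = X_{\min}$ mapped to all zeros so a
constant component cannot perturb the ranking. The total damage is
$T_{score} = \mathrm{FCGM}'_{path} + \mathrm{SCGM}'_{path} +
\mathrm{FCWM}'_{path} + \mathrm{SCWM}'_{path} \in [0, 4]$. Consequences
worth knowing:

* normalisation is **per target and per search** — rerunning on a subset
  of entries changes the normalised values (asserted in tests);
* the scores are ordinal within a search; magnitudes are not comparable
  across subjects or targets. A display-only scale factor is available for
  colour mapping but never affects ranking.
* dominance monotonicity holds: if one entry's four raw components all
  exceed another's, its T_score is at least as large.

The optimal entry minimises T_score; ties are broken by shorter
entry–target distance, then lexicographic entry coordinates, so results
are exactly reproducible. Identical inputs give byte-identical risk-map
CSVs. The NIfTI risk-map export paints the voxel nearest each entry with
its T_score and every other voxel with the sentinel −1, so a green-to-red
colour map can mask the background.

## Trajectory evaluation metrics

For head-to-head comparison of two trajectories, `compare_trajectories()`
reports: **path length** — the distance from the target to the first
tissue point encountered marching from the entry (the outer boundary of
the labeled parcellation stands in for the cortical surface, since the
package takes no surface mesh); **Euclidean distance** between the two
entry points (straight-line chord, the simpler reading of distance "over
the box"); **angular distance** between the two trajectory directions
through the target (clamped arccosine, degrees); and each trajectory's
damage, normalised against a completed search for the same target so both
are on the same scale.

## The phantom generator

No public dataset pairs FC, SC, a parcellation and a tractogram, so the
package ships a seeded generator that emulates all four inputs with known
ground truth. Default geometry is a 64³ grid at 2 mm isotropic voxels —
the resolution class of a typical diffusion acquisition and large enough
that a full search is a realistic workload while keeping test runtimes in
seconds. The brain is an ellipsoid (semi-axes ¾ of the half
field-of-view) partitioned into 8 angular sectors about the z axis; the
sector boundaries are rotated half a wedge so the +x axis lies mid-sector
and the layout is mirror-symmetric in x. Streamline bundles are jittered
polylines between region centroids, with endpoint jitter
rejection-sampled so every endpoint stays in its intended region — which
makes the generated SC matrix *exactly* the endpoint-count matrix of the
generated tractogram. FC is symmetric clipped-Gaussian baseline noise
(σ = 0.1) with hub rows/columns replaced by high-magnitude edges.

The **planted-hub scene** (`make_planted_hub_scene()`) is the package's
behavioural benchmark: region 1 (the +x sector) is made a hub whose
functional and structural node strengths are guaranteed ≥ 3× every other
region's — the FC baseline is analytically damped if the sampled noise
would violate the margin, and the bundle plan (five 10-streamline bundles
radiating from the hub against one 4-streamline distractor) enforces the
structural side. Two candidate trajectories of mirrored — hence exactly
identical — geometry enter from the +x and −x box faces. The target sits
on the mirror plane at (0, 10, 0) rather than at the origin: the origin
is the singular apex where all sectors meet, so every tube ending there
would graze the hub and "avoiding the hub" would be undefined; 10 mm off
the apex (twice the tube radius) lets non-hub trajectories clear the hub
wedge entirely. The generator verifies the construction by direct
computation (equal intersected GM volumes, strictly greater hub-side
functional damage) and refuses to return a scene that violates it.

What the phantom does *not* emulate: realistic cortical folding, partial
volume at tissue boundaries, curved fibre geometry, distance-dependent FC
structure, or measurement noise in tractography. Passing tests therefore
demonstrate the correctness of the scoring, extraction and search
machinery — not clinical validity on real data.

## Numerical choices

* Resampling step: half the shortest voxel edge (1 mm at default
  resolution) for both fibre–voxel assignment and tube membership;
  marching for path length uses the same step, and its tests compare
  against a 10× finer independent march.
* Membership comparisons use `≤` on exact doubles; no epsilon is added at
  the capsule boundary. Voxel lookup rounds to the nearest voxel centre.
* Asymmetric connectivity beyond 1e-8 is symmetrised by averaging with a
  warning; NaN or negative structural entries are hard errors.
* Matrix round-trips are preserved to 1e-8; streamline coordinates are
  stored as float32 (TCK/TRK), exact to ~1e-5 mm at brain-scale
  coordinates, tested at 1e-4 mm.
* Problem sizes in the test suite: unit tests run on 32³ phantoms;
  end-to-end property checks use the default 64³ scene, 20 random tubes
  for the extraction oracle and 10 seeds for the hub-avoidance search.

## Known limitations

* No tissue-deformation (brain-shift) modelling: scores refer to the
  preoperative configuration, appropriate for small/medium lesions.
* No vessel avoidance and no constraint regions beyond the excluded base
  face.
* T_score magnitudes are search-relative; the method ranks trajectories,
  it does not predict deficit severity.
* The cortical boundary used for path length is the parcellation's outer
  voxel boundary, one voxel coarser than a surface mesh.
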