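# neuroplanr

Connectivity-weighted eloquence scoring and risk mapping for neurosurgical
trajectory planning.

Choosing an access path to a brain lesion is usually guided by heuristics —
shortest path, avoidance of visibly eloquent cortex. `neuroplanr` adds an
objective, patient-specific criterion: the *connectional* cost of a
trajectory, derived from the individual's functional (resting-state fMRI)
and structural (tractography) brain networks. It is aimed at researchers in
surgical planning and connectomics who have an atlas parcellation, FC/SC
matrices and a whole-brain tractogram for a subject, and want to rank
candidate entry points by the network damage their path would cause.

## Model

Let `FC` and `SC` be the N×N functional and structural connectivity
matrices over the atlas regions (diagonal zero). Each grey-matter region
`k` receives its node strength (unsigned weighted degree) as an eloquence
score:

    FCGM_k = Σ_j |FC(k, j)|
    SCGM_k = Σ_j |SC(k, j)| / L_k        (L_k = region volume, mm³)

A white-matter fibre `p` intersecting regions `ROIs = {GM_1 … GM_m}`
inherits the mean score of its members:

    FCWM_p = mean_{i ∈ ROIs} FCGM_i ,    SCWM_p = mean_{i ∈ ROIs} SCGM_i

A candidate trajectory is a capsule-shaped tube of radius `r` (default
5 mm) between an entry point and the target. The tissue inside it
accumulates four raw damage components:

    FCGM_path = Σ_k V_k·FCGM_k      SCGM_path = Σ_k V_k·SCGM_k
    FCWM_path = Σ_p FCWM_p          SCWM_path = Σ_p SCWM_p

where `V_k` is the intersected volume of region `k` and `p` ranges over
intersected fibres. Entry points are enumerated on a 1 cm grid over the
five open faces of a box enclosing the head (the base face rests on the
skull). Each component is min–max scaled across the entries of the search
and summed into the total damage

    T_score = FCGM′_path + SCGM′_path + FCWM′_path + SCWM′_path ∈ [0, 4],

whose minimiser is the proposed entry. The per-entry `T_score` painted over
the box is the risk map.

## Worked example

A phantom with one planted connectivity hub, and the full search for a
target near its centre:

```r
library(neuroplanr)

ph  <- make_planted_hub_scene(seed = 1)   # region 1 is the hub
gm  <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
head(gm, 3)
#>   label      fcgm         scgm
#> 1     1 5.1158591 8.646929e-04
#> 2     2 1.0869861 6.909895e-05
#> 3     3 0.9417069 1.729386e-04

fib  <- compute_fiber_scores(ph$tractogram, ph$parcellation, gm)
rmap <- exhaustive_search(ph$scene$target, ph$scene$box, ph$parcellation,
                          ph$tractogram, gm, fib, radius = 5)
rmap
#> <risk_map> 720 entries, radius 5.0 mm; optimal entry (57.0, 55.0, -55.0)
#> with T_score 0.0656
```

Region 1's node strength (`fcgm` 5.12) dwarfs the others — it is the hub.
The search evaluated all 720 entry points of the 1 cm grid; the optimum
approaches from the opposite octant and its tube intersects no hub voxel.
Comparing the straight-through-the-hub trajectory ("routine") with the
search optimum ("proposed"):

```r
compare_trajectories(ph$scene$entry_hub,
                     unlist(rmap$entries[rmap$optimal, 1:3]),
                     ph$scene$target, ph$parcellation, ph$tractogram,
                     gm, fib, risk_map = rmap)
#>   path_length_a path_length_b euclidean_mm angular_deg damage_a damage_b
#> 1            47          40.6         71.1        51.3     1.61   0.0656
```

The proposed entry cuts the damage score from 1.61 to 0.066 with a
comparable path length — the behaviour the method exists to produce.
`write_risk_map(rmap, ph$parcellation, "risk")` exports the full table as
CSV and a colour-mappable NIfTI volume (non-entry voxels carry the
sentinel −1).

A command-line front end with `phantom` / `scores` / `tube` / `search` /
`compare` subcommands is installed at
`system.file("cli", "neuroplan.R", package = "neuroplanr")`.

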