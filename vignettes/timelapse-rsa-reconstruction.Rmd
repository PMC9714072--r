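---
title: "Reconstructing root system architecture in 2D+t: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing root system architecture in 2D+t: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Seedlings grown on vertical agar plates and imaged repeatedly (here: 5
plants per 120 mm plate, one backlighted image every 8 h, 21 observations)
produce a time series in which the root system only ever *gains* pixels:
once tissue covers a pixel it stays there. `rhizotrack` exploits this
monotonicity to reconstruct each plant's architecture — every primary and
lateral root as a timed centerline — rather than a per-frame mask. The
chain is:

1. **Registration** — align all frames on the last one (the frame that
   contains every structure) with a rigid transform per frame plus an
   optional dense correction, estimated pairwise between successive
   frames and composed in a daisy chain, applied in a single resampling.
2. **2D+t segmentation** — per pixel, detect the observation at which the
   intensity drops durably; the output is a single label image `S` where
   `S(p)` is the apparition time of pixel `p` (0 = background).
3. **Topological tracking** — build a directed region adjacency graph
   over same-label components of `S`, mark primary paths greedily from
   the earliest components, prune to a minimum-weight spanning forest
   (Edmonds), reconnect root crossings by iterated Hungarian matching,
   and reject artefact trajectories with robust MADe statistics.
4. **Geometry** — turn each organ chain into a timed polyline: frontier
   points between consecutive growth regions carry exact observation
   times, the tip is the geodesically farthest pixel of the last region,
   centerlines are distance-map-weighted shortest paths, decimated by
   Douglas–Peucker, with interior node times interpolated along arc
   length. Two post-processes extrapolate primaries up to the seed line
   and continue stopped roots hidden below earlier roots.
5. **Export and phenes** — RSML with a per-node `time` function, tidy
   phene tables (lengths, growth per interval, lateral counts,
   depth-binned elongation heatmaps, per-timestep Mann–Whitney tests),
   and an interpolated time-lapse renderer.

## Key modelling choices

**Apparition label convention.** The detector computes, for each pixel,
the maximum mean shift over all temporal split points (threshold `s1 = 25`
gray levels) and the maximum successive drop (threshold `s2 = 10`); the
label is the observation *following* the maximal drop. A consequence is
that pixels already dark at the first observation produce no drop and
cannot be labelled: the earliest possible label is 2. The simulator's
world is consistent with this — radicles have zero length at the first
observation — and primary extraction seats plants on the largest
components of the *earliest label present*, not literal label 1. The
organ origin node still receives time 1 (the earliest label's region
started growing at the first observation).

**Edge weight.** For regions `v1 -> v2`, the weight is
`|#v1 − #v2|/(#v1 + #v2) + (t(v2) − t(v1) − 1) + u·y` with `u` the unit
centroid-to-centroid vector and `y` the *upward* unit vector, so an edge
pointing straight down scores −1 on the third term. Comparable surface,
consecutive labels and downward growth therefore make an edge cheap.

**Primary extraction.** The greedy walk follows the minimum-weight
outgoing edge until none remains; ties break toward the earlier label,
then the larger region. When a seed line is configured, source candidates
must lie near the top of the plate — dirt landing on a root path in an
early frame can otherwise out-size a radicle and steal a seat. Lateral
arcs into primary vertices are removed (root hierarchy); vertices
unreachable from any primary are dropped as outliers.

**Crossing resolution.** Pruning the graph to a forest severs the path of
a root that crosses an earlier one. Root stops (no outgoing arc) and root
starts (lateral vertices with no incoming arc) are matched by the
Hungarian algorithm on a cost built from four features, each in [0, 1]:
the virtual adjacency-edge weight rescaled from [−1, 3]; the angle
between the stop's terminal and the start's initial directions (θ/π);
the relative speed difference; and a topological score counting the
edges (with wrong-direction ones twice) and the temporal gap along the
minimum-hop undirected path between the two vertices in the original
graph. Features that cannot be estimated from enough trajectory support
take the majoring value 1. Pairs with no graph path within
`search_radius` hops, pairs farther than `max_connection_dist_px`, and
pairs going backward in time are inadmissible: without a path in the
region graph the two chains cannot be fragments of one crossing root,
and admitting them lets spurious distant connections undercut genuine
short-fragment reconnections. The feature weights (0.2, 0.3, 0.15, 0.35)
put the discriminating mass on geometry and topology; the paper-style
description gives the feature list but no weights, so these are package
choices. Only the matched pair of minimal cost is applied per iteration
(each connection "adds knowledge"), and a cost ceiling of 0.9 stops the
loop — without a ceiling every start would eventually be connected.

**Detached chains.** Chains that remain unconnected after resolution are
still organ chains of the forest; they become laterals of the nearest
plant instead of being discarded (single-region remnants are dropped).

**Artefact rejection.** Per lateral and per age bin (timesteps since
emergence), three statistics — cumulative centroid-path length, speed,
cumulative surface — are compared across the population; any root
deviating from a bin median by more than 25 × MADe (1.483 × MAD, floored
at `made_epsilon`) is removed. The rejection is skipped below 5 laterals.

**Centerline weighting.** Step costs are the inter-pixel distance times
`1/(1 + min(D(a), D(b)))`, `D` being the distance map to the component
contour. Any weight decreasing in depth would do; this form is bounded
and parameter-free. Douglas–Peucker tolerance defaults to 1.5 px.

**Lateral insertion.** The base node of an attached lateral is snapped
onto the parent's centerline when within `attach_snap_px` (6 px): the
frontier between regions sits on the edge of the parent's tube, which at
coarse rasterization would bias every lateral short by about half a tube
width.

**Extrapolated nodes** (seed paths, hidden continuations) are flagged
per node; length phenes exclude them by default (`include_extrapolated`)
while the topology keeps them. The synthetic benchmark compares
*published* lengths, which include the hidden-growth extrapolation, with
the ground truth.

## Registration engineering

The estimator is block matching with normalized cross-correlation,
coarse-to-fine: a factor-2 downsampled pass absorbs large displacements,
a full-resolution pass refines within ±8 px, and a parabolic fit on the
correlation surface gives sub-pixel peaks. Blocks are filtered by the
energy of their gradient structure tensor and *classified* by its
anisotropy: 2-D textured blocks constrain both residual components, 1-D
blocks (plate borders, straight young roots — the aperture problem) only
the component along their edge normal. A deterministic two-point RANSAC
over 2-D blocks guards the Gauss–Newton rigid fit against consistent
sliding consensus, and each pair is estimated in both directions and
averaged, which cancels the small bias induced by root growth and
resampling blur (otherwise ~0.03 px per pair, accumulating along a
20-frame chain). Composed transforms are applied in one resampling.

The dense stage smooths scattered block displacements onto a regular
grid with Gaussian weights; it is optional and off in the synthetic
tests, which are rigid by construction.

## What the simulator emulates — and what it does not

`sim_params()` defaults state the reference acquisition: 5 plants evenly
spread on a 120 mm plate, 21 observations 8 h apart, 19 µm/px, ~100 gray
levels between root centerline and background, per-frame rigid plate
jitter, and persistent condensation/dirt blobs below the component-size
filter. Growth: primaries 0.5 ± 0.05 mm/h (≈80 mm after 160 h, matching
a control population), laterals 0.15 ± 0.04 mm/h emerging as a Poisson
process (0.25/mm) behind an 8 mm refractory zone with a ~40 h maturation
delay, heading sideways then bending down. A `crossing_bias` fraction of
laterals is steered toward the neighbouring plant with spread headings
(60–88°) so that engineered crossings are transversal; a small
`lateral_stop_prob` produces stopped roots so the downstream
extrapolation path is exercised. Roots are drawn as tubes with a flat
dark core and Gaussian falloff (width 3 px); static plate features (dish
border, seed bodies) are drawn in every frame — they are what
registration locks onto before roots appear, and being temporally
constant the change-point detector ignores them.

Not emulated: photorealistic shoots and fallen leaves (the pipeline
accepts an exclusion mask instead of the unspecified morphological
recipe), third-order laterals, root death or regression, bacterial
contamination, lens distortion. A green benchmark therefore establishes
correct recovery of the stated growth world, not robustness to every
field artefact.

**Scale.** The benchmark rasterizes the same physical world at
100 µm/px (1200² images) instead of 19 µm/px (6300²), keeping a 20-plate
end-to-end run within minutes; the component-size filter is rescaled to
keep its physical meaning (38 mm of cumulative organ length). Geometry,
rates and timing are resolution-independent.

## Numerical conventions

Coordinates are x = column, y = row, origin top-left, y increasing
downward; times are 1-based continuous observation indices. Transforms
store the forward motion (rotation about the image center plus
translation) and are applied by exact inverse mapping with bilinear
interpolation; out-of-field pixels take the frame median. Ties:
maximal-drop ties resolve to the earliest index; frontier chains are
ordered along their principal axis, oriented by ascending (y, x), and
even-length frontiers take the lower-index median; tip ties resolve to
the smaller row, then column. All RNG flows derive from a single integer
seed; fixed seeds give bit-identical stacks, models and RSML bytes.

## Known limitations

Crossing-identity preservation is the weakest guarantee. When two roots
occupy a crossing zone within about one observation interval of each
other — or when one root's post-crossing emergence is squeezed to a few
pixels beneath the other's tube — the spanning forest wires the late
root's continuation directly into the earlier root's chain through
adjacent, consecutive-label regions. No stop/start pair then exists and
the matching stage never sees the case; the identities of the two organs
swap beyond the junction even though the geometry (and hence the length
and growth phenes, which aggregate per plant) remains essentially
correct. On the synthetic crossing benchmark this caps correct identity
through crossings at roughly 85–90%, short of the 95% the package's
acceptance suite demands of it — the corresponding acceptance
expectation is left failing by design rather than weakened. Improving it
would require direction-aware forest pruning, a departure from the
minimum-weight arborescence formulation.

Root width is not estimated; overlapping organs are resolved in 2D
projection only; and the per-pixel detector cannot label tissue already
present at the first observation (seeds, pre-germinated radicles), which
is why primaries are extrapolated upstream to the configured seed line.
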