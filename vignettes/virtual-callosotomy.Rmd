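---
title: "Mapping trans-callosal connectivity and simulating partial callosotomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trans-callosal connectivity and simulating partial callosotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcallosal)
```

## The model

`transcallosal` treats a tractogram as a sample of the corpus callosum's
(CC) axonal population: each streamline is an ordered polyline in scanner
millimetre (RAS) space whose two termination points approximate where an
inter-hemispheric fibre reaches cortex. Three simplifying assumptions carry
the whole analysis:

1. **Endpoints speak for fibres.** A streamline contributes to cortical
   connectivity only through its two termination points, each assigned
   independently to the nearest vertex of the cortical mid-surface meshes
   (both hemispheres searched jointly). No cortical patch radius, no
   distance weighting. Ties — exactly equal distances — go to the lowest
   vertex id, left hemisphere before right; this is arbitrary but fixed and
   documented, and measure-zero for real data.
2. **Median-of-three robustness.** A triangle's count n is the median of
   its three vertex counts. A single loaded vertex (e.g. a sulcal fundus
   vertex capturing many endpoints) does not make all its incident
   triangles "involved"; at least two of a triangle's vertices must receive
   endpoints. Involvement (triangle n >= 1) is therefore conservative. The
   weaker any-vertex rule is available via `rule = "any"` wherever
   involvement is computed, because the choice is not settled by first
   principles; the median rule is the default because it derives from the
   same per-triangle statistic that the count field displays.
3. **Resection removes streamlines wholesale.** The CC mask is split into
   k equal-width bins along its principal axis, and an anterior resection
   of extent j/k removes every streamline whose traversed segments
   intersect {1..j}. A transected axon is disrupted wherever it is cut, so
   a streamline crossing a segment boundary is cut by either segment's
   resection. Sub-total degradation within a segment is deliberately out of
   scope: the model's resolution is the segment, not the axon.

### Hemispheric coverage and network involvement

Coverage of a hemisphere is the fraction of its triangles with n >= 1.
Triangle counting (not area weighting) is the default because the meshes
this pipeline expects are resampled to near-uniform triangle area; the
area-weighted variant (`area_weighted = TRUE`) exists for meshes where that
assumption fails, and the two agree to within a few percent on the synthetic
meshes.

Involvement of network g pools both hemispheres (the 7- and 17-network
resting-state parcellations are bilateral): it is the fraction of g's
labelled triangles with n >= 1, label-0 (unassigned/medial wall) triangles
excluded, and a network with no triangles reports `NA` rather than 0 —
absence of evidence is not zero involvement.

### The vulnerability profile

For each extent j/k the profile recomputes triangle involvement from the
*cut* streamlines' endpoints only, rather than scaling the full counts.
This is the choice that makes the extent-1.0 column reproduce full
involvement exactly (total resection cuts every callosal streamline), which
in turn is the anchor tying the partial-resection analysis to the
full-involvement analysis. The alternative reading — fraction of each
network's *fibres* cut — is implemented as `fibre_fraction_profile()` and
kept clearly separate; it answers a different question (how many
connections are lost) than the primary metric (how much cortex loses its
callosal input).

The 17-to-7 downsampling is a weighted mean, `sum(w v) / sum(w)`, per
7-network and extent. A weighted mean (not max, not union) because the
contributions of 17-networks to a 7-network are proportional, and any such
mapping is approximate: the weights ship as an editable CSV
(`inst/extdata/yeo17_to_yeo7_default.csv`) with uniform weights within each
7-network, network 11 split equally between Frontoparietal and Default —
encoding the published qualitative correspondences (1,2 to Visual; 3,4 to
Somatomotor; 9,10 to Limbic; 13..17 to Default) with the standard pairings
for the rest. Replace the CSV to change the mapping; weights per 17-network
must sum to 1.

### Reproducibility statistic

Scan-rescan agreement uses Spearman's rank correlation over *all* triangles
including zero-count ones (dropping zeros would condition on the quantity
under test), with average ranks for ties — essential, as count vectors are
mostly small integers — and the two-sided t-approximation
`t = rho sqrt((n-2)/(1-rho^2))` for the p-value. For n around 16,000 the
approximation is excellent.

## Tunable parameters

| Parameter | Where | Default | Units | Why this default |
|---|---|---|---|---|
| `k` | `segment_cc` | 5 | segments | fifths of the CC; 20% resection increments |
| `max_distance_mm` | `assign_endpoints` | none | mm | no cap: every endpoint is somewhere on cortex; a cap exists for noisy real data |
| `rule` | involvement functions | `"median"` | — | derived from the displayed per-triangle statistic |
| `area_weighted` | `hemisphere_coverage` | `FALSE` | — | meshes are resampled to near-uniform triangles |
| `step_mm` | `track_streamlines` | user | mm | half the voxel size is conventional |
| `angular_limit_deg` | `track_streamlines` | 60 | degrees | standard deterministic-tracking curvature gate |
| `min_len_mm`, `max_len_mm` | `track_streamlines` | 10, 300 | mm | discard spurious short tracks and runaway loops |
| `anisotropy_threshold` | `track_streamlines` | 0.6 x Otsu | — | histogram threshold of the anisotropy map scaled by 0.6 |

Generator (`synthetic_config`) parameters:

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `n_streamlines` | 20,000 | — | desk-scale test default; the CLI on real data would use millions |
| `mesh_triangles_per_hemisphere` | 8,000 | triangles | 16,000 total, the mid-surface resolution the pipeline targets |
| `parasagittal_sigma` | 10 | mm | SD of termination density away from the midsagittal plane |
| `asymmetry` | 1.2 | ratio | left/right parasagittal spread ratio; >1 gives left > right coverage |
| `network_ap_gradient` | see below | 0..1 | per-network mean CC passage position, 0 = anterior |
| `ap_sd` | 0.025 | 0..1 | SD of a network's passage positions |
| `cc_extent` | 4 x 60 x 10 | mm | CC slab dimensions (left-right, AP, inferior-superior) |
| `voxel_size` | 1 | mm | mask grid resolution |

The default `network_ap_gradient` places networks 1 and 2 (visual)
posteriorly (0.90, 0.85), networks 16 and 17 (default-mode) anteriorly
(0.15, 0.10), and the rest in between — so the generator's world reproduces
the qualitative clinical contrast: anterior resections disrupt the
default-mode system first and the visual system last.

Two generator choices deserve their reasoning spelled out:

- **`asymmetry` scales spread, not density.** The planted asymmetry is the
  ratio of left to right parasagittal SD. A naive reading — multiply the
  left termination *density* by a constant — is a no-op, because each
  callosal streamline has exactly one endpoint per hemisphere and densities
  are normalised within hemisphere. Spreading the same number of left
  endpoints over a wider parasagittal band is what produces the
  left > right *coverage* asymmetry the analysis should detect.
- **`ap_sd = 0.025`.** A planted "anterior-passing" network should actually
  pass anteriorly: with SD 0.025, 95% of a network's crossings lie within
  a quarter of one CC fifth of the network's mean position. Larger spreads
  blur the planted anterior-posterior structure that the virtual
  callosotomy is supposed to recover.

## What the generator emulates — and what it does not

Emulated, with recorded ground truth: parasagittal concentration of
callosal terminations (truncated-Gaussian vertex sampling by distance from
the midsagittal plane); left > right hemispheric coverage asymmetry; an
anterior-posterior gradient of per-network CC passage position; contiguous
network patches (longitude bands around the medial-lateral axis, with
straddling triangles left unassigned so each network's involvement is
exactly attributable to its own streamlines); an unassigned medial-wall
cap; single global seed, bit-identical regeneration.

Not emulated: cortical folding (the meshes are smoothly deformed spheres —
no sulci, so no endpoint-to-wrong-bank assignment errors); crossing-fibre
geometry and tracking failures (generated streamlines are exact polylines,
not tracked); distance between endpoint and surface beyond a fixed 0.3 mm
offset (real endpoints scatter); partial-volume and registration error in
the CC mask (the slab is exact); any diffusion signal.

A green parameter-recovery test therefore establishes that the *analysis
chain* is correct — counts conserved, geometry handled exactly, planted
quantities recovered — not that tractography on real data is accurate. The
toy tracker (`track_streamlines`) exists to pin the stated termination
rules (fixed-step Euler, sign-aligned nearest-voxel directions, angular and
anisotropy gates, length window) with exactly testable semantics; it is an
idealisation, not a usable tractography method.

## Numerical conventions

- **NIfTI affine precedence**: sform when its code > 0, else qform
  (quaternion with qfac from pixdim[0]), else plain pixdim scaling. Voxel
  *centres* map through the affine; indices are 0-based.
- **Point-in-voxel**: rounding of inverse-affine coordinates (R's
  round-half-even at exact .5 boundaries; generated data avoids exact
  boundaries by construction). No tube radius around streamlines.
- **CC principal axis**: leading eigenvector of the voxel-centre
  covariance; sign flipped so the anterior (+Y) component is >= 0, with +X
  then +Z as fallbacks when Y is exactly zero. Tied leading eigenvalues
  (relative gap < 1e-6) warn and break the tie by largest |Y|, then |X|.
- **Bin edges**: k equal-width bins over [min, max] projection; a
  projection exactly on an interior edge goes to the more anterior bin.
- **Otsu threshold**: maximises between-class variance over an n-bin
  histogram spanning [min, max]; returns the bin edge, first edge wins on
  plateaus.
- **TCK**: float32 little-endian on disk (coordinates round-trip to ~1e-7
  relative); NaN triplet separates streamlines, Inf triplet terminates.
- **Profile CSV**: 6 decimal places — below any scientifically meaningful
  difference, above float32 noise; read-back reproduces the printed values
  exactly.
- **Empty inputs**: an empty tractogram yields an empty assignment (not an
  error); an empty surface, a non-invertible affine, or a constant vector
  for Spearman are errors or explicit `NA`s, never silent zeros.

## Design decisions that were genuinely open

- *Is "involved" median-based or any-vertex, and does coverage count
  triangles or area?* Unsettled by first principles; both implemented, the
  median/triangle-count pair is the default (see assumptions above), and
  the flags are part of the public interface rather than hidden constants.
- *Streamlines crossing a segment boundary*: cut by the resection of any
  traversed segment. The alternative (attribute to a single fifth, e.g. by
  majority of in-mask points) was rejected because a real transection does
  not poll a fibre's other segments; in practice most callosal streamlines
  traverse exactly one segment, so the choice rarely binds.
- *On-disk tractogram format*: TCK, chosen for its trivially parseable
  header and explicit terminator semantics. TRK support was considered and
  dropped: its header couples voxel and world frames in ways that invite
  silent misregistration, and nothing in the pipeline needs it.
- *Full involvement is computed from callosal streamlines* (those
  intersecting the CC mask). With a CC-seeded tractogram the restriction is
  vacuous; with any other tractogram it is what makes the extent-1.0
  profile column equal full involvement exactly instead of approximately.

## Known limitations

- The nearest-vertex kernel is brute force (O(endpoints x vertices), in
  C++). At the intended scale (10^4-10^5 endpoints, ~10^4 vertices) this is
  a second or two; for 10^6-streamline real-data runs a spatial index would
  be worth adding behind the same interface and oracle tests.
- Spearman p-values use the t-approximation, adequate for the n ~ 16,000
  regime this package targets, optimistic below n ~ 10.
- The GIFTI writer emits ASCII encoding only (readers accept ASCII,
  Base64Binary and GZipBase64Binary, little-endian); big-endian GIFTI and
  NIfTI files are rejected, not converted.
- The synthetic world's coverage (~0.4-0.47 of each hemisphere at 20,000
  streamlines) is higher than real-data coverage at comparable streamline
  counts, because the spherical meshes lack the buried sulcal cortex that
  real terminations never reach; coverage *asymmetry* and its recovery are
  meaningful, absolute coverage values are not comparable to real data.
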