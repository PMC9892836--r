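---
title: "Mapping in-transit melanoma metastases onto lymphatic drainage sectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping in-transit melanoma metastases onto lymphatic drainage sectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itmap)
```

## The scientific problem

In-transit metastases (ITM) of cutaneous melanoma are skin and subcutaneous
recurrences arising between the primary tumor and its regional lymph-node
basin, presumed to spread along dermal lymphatic vessels. On the distal
lower extremity, anatomical studies have mapped four distinct lymphatic
vessel bundles, each draining a longitudinal sector of the skin:
posterolateral, posteromedial, anterolateral, and anteromedial, with the
toes draining into the anteromedial bundle. If ITM really do spread along
these vessels, the sector containing a patient's primary melanoma predicts
where their ITM will appear — knowledge that can focus clinical follow-up
on the skin regions actually at risk.

`itmap` implements the quantitative side of that question as a pipeline:

1. a canonical left-leg surface carrying the four drainage sectors
   (`build_reference_leg()`, `segment_zones()`, `project_views()`);
2. landmark-based rigid standardization of patient lesion coordinates onto
   that surface, with mirroring of right-sided cases (`mirror_to_left()`,
   `fit_rigid_transform()`, `transfer_lesions()`, `map_patient()`);
3. per-patient drainage concordance — the fraction of a patient's ITM in
   the primary's sector, classified full match (≥ 90%), partial match
   (≥ 50% and < 90%), or no match (< 50%) (`score_concordance()`,
   `tabulate_patterns()`, `compare_sites()`);
4. skin-surface (geodesic) distances between primary and ITM
   (`geodesic_graph()`, `geodesic_distance()`, `distance_summary()`);
5. cohort-level risk-factor statistics (`chi_square_test()`,
   `mann_whitney_continuous()`, `logistic_risk_model()`);
6. a synthetic cohort-and-lesion generator so that every stage can be
   validated end to end without patient data (`simulation_config()`,
   `simulate_cohort()`, `simulate_lesions()`, `end_to_end_recovery()`).

## The reference leg and its sectors

Clinical studies of this kind hand-draw a 2D leg template from a
photograph. For a computable pipeline we instead use a parametric surface:
the limb is a generalized cylinder — elliptical cross-section rings swept
from the toes along the foot, through a quarter-circle bend at the ankle,
then up the lower leg and thigh, with apex caps at both ends. The canonical
frame is a **left** leg with +z proximal (toes to hip), +y anterior and +x
medial, in centimetres; right-sided patients are mirrored (x → −x) before
analysis. Default segment lengths and radii (foot 25 cm, malleoli at 7 cm,
lower leg 39 cm, thigh 40 cm, realistic cross-section radii) give an adult
limb on which toe-to-groin skin paths reach roughly one metre.

Landmarks used for registration — patella, medial and lateral malleolus,
first and fifth toe tips — are placed on *key rings* whose positions are
closed-form functions of the shape parameters only, so refining the mesh
never moves a landmark (this is also what the registration tests rely on).

Drainage sectors are meridian wedges: every vertex carries a meridian
angle φ (0° = medial, 90° = anterior, measured counter-clockwise viewed
from proximal) that is transported continuously through the ankle bend, so
"medial" on the foot connects to "medial" on the leg. A face belongs to the
sector whose angular interval contains its mean vertex angle. Defaults put
the four boundaries on the pure medial/anterior/lateral/posterior
meridians, making each sector a 90° wedge centred on an oblique anatomical
direction. Two overrides reflect the anatomy: all toe-region faces are
forced anteromedial, and the plantar surface — whose drainage the
underlying anatomical work could not resolve — defaults to anteromedial
but is configurable (`plantar_zone`). A face falling exactly on a boundary
meridian goes to the sector counter-clockwise of the boundary; a 2D
template point on a shared polygon edge goes to the zone earliest in
`zone_ids()` order. Both tie-breaks are arbitrary but documented and
deterministic.

The published anatomical sectors are only available as colored regions in
a figure, not as coordinates; the default meridians are therefore a stated
approximation, and all boundaries are configurable. The same applies
proximally: the anatomical study covered the distal limb, so thigh faces
receive sector labels only by meridian continuation.

## Registration

Patient coordinates are standardized with a 6 degree-of-freedom rigid
transform (three translations, three rotations), fitted to ≥ 3 labeled
landmarks by closed-form orthogonal least squares: centroids aligned,
rotation from the SVD of the cross-covariance matrix with the reflection
corrected. No scaling is applied by default — a deliberate reading of the
6 stated degrees of freedom — but `allow_scale = TRUE` adds a seventh,
uniform-scale parameter (Umeyama estimate) for cohorts with substantial
size variation. Transformed lesions are snapped to the nearest point of
the reference surface (exact point-triangle projection with an exact
centroid-distance prefilter); a lesion farther than `snap_threshold`
(default 3 cm) from the surface is flagged unmappable rather than silently
assigned.

## Geodesic distances

The skin-surface distance between a primary and an ITM is the length of
the shortest path constrained to the surface. We approximate it with a
Steiner-point graph: each mesh edge receives 2^r − 1 additional nodes at
dyadic positions (refinement r, default 3), every pair of nodes on a
common face is joined by the straight segment inside that face, and
Dijkstra's algorithm finds a shortest graph path. That path is then
*shortened to the exact geodesic of its crossing sequence* by three local
moves iterated to convergence: crossing points slide along their edges to
the local straight-line (Snell) position; points pinned on a mesh vertex
are replaced, when the unfolded star wedge between their neighbours is
flatter than π, by the exact crossings of the unfolded straight line; and
any point whose neighbours share a face is dropped. Because the dyadic
node sets are nested, the candidate paths at refinement r + 1 include all
of those at r, and the reported length is non-increasing in r; endpoints
are processed in a canonical order so `geodesic_distance(a, b)` equals
`geodesic_distance(b, a)` exactly.

Measured accuracy at refinement 3: planar patches within 0.05% of the
Euclidean distance (well inside the 0.5% target the tests assert), a
cylinder quarter-arc within 0.1% of the developed arc; the residual error
on the cylinder is dominated by the polyhedral approximation of the
surface itself, not by the path search. An exact polyhedral-geodesic
algorithm (MMP/Chen–Han) would remove even that, but distances are
reported to 0.1 cm over ~30 cm paths, so a graph-plus-shortening scheme is
accurate beyond the reporting precision while staying simple and
deterministic. Joint posture is a property of the mesh (a straightened
leg), not a runtime correction.

## Concordance scoring and the ordinal site comparison

For each evaluable patient (exactly one primary, ≥ 1 mappable ITM) the
concordance fraction is the share of ITM in the primary's sector,
classified full (≥ 90%), partial (≥ 50%), or none. Percentages are rounded
half-up (0.5 away from zero), which reproduces the printed percentages of
the source tables; R's default banker's rounding does not.

The foot-versus-lower-leg comparison treats the category as ordinal
(none < partial < full) and uses the two-sided Mann–Whitney U test with
the tie-corrected normal approximation and **no** continuity correction —
the common statistical-software default, and the convention that
reproduces the published p = 0.007 for the 3/6/6 vs 22/2/7 split
(z = −2.691). An exact-permutation mode (`method = "exact"`, feasible to
12 per group) enumerates all group assignments; tests validate it against
an independent pair-count enumeration oracle. For small ordinal samples
the asymptotic and exact p can differ noticeably (up to ≈ 0.07 even
without ties at n = 6 + 6), which is why the exact mode exists; the
asymptotic version remains the default because it is what the reference
analyses used.

## Cohort risk-factor statistics

Categorical factors use Pearson's chi-square without continuity
correction; continuous covariates use the same Mann–Whitney engine.
ITM risk models are maximum-likelihood logistic regressions with the
conventional clinical coding: age < 55 vs ≥ 55 years, histologic subtype
with superficial spreading melanoma as reference (melanoma of unknown
primary excluded from subtype models), Breslow thickness < 1.0 vs ≥ 1.0 mm,
ulceration with reference *absent*, and site with reference foot. Effects
are reported as odds ratios with 95% Wald intervals and Wald p-values —
the published table labels its column "hazard ratio" while describing
logistic regression; what such a model estimates are odds ratios, and that
is what we call them. (The same table lists ulceration "present" as the
reference yet a ratio above 1 for "absent"; coding present vs absent
reproduces the direction implied by the underlying contingency table.)
Records missing a covariate are dropped from models containing it;
complete or quasi-complete separation is flagged via exploding standard
errors rather than reported as a finite estimate.

## The synthetic generator: what it emulates and what it does not

`simulate_cohort()` draws covariates from marginals shaped like the
clinical cohort (382 patients; 20/42/38% foot/lower-leg/thigh; ~69%
female; truncated-normal age; log-normal Breslow thickness;
ulceration probability increasing with log-thickness) and assigns the ITM
outcome from a logistic model whose default coefficients echo the
published multivariate odds ratios (thickness ≥ 1 mm OR ≈ 5.7, ulceration
≈ 2.1, nodular subtype ≈ 2.6). ITM patients receive a lesion count from
the published count categories (1–5, 6–10, 11–20, > 20) and a small
fraction are relabeled melanoma of unknown primary. Each patient draws
from a private random substream keyed by (seed, patient index), so cohorts
are byte-reproducible and single patients regenerate stably when the
cohort grows.

`simulate_lesions()` places the primary uniformly in its site region and
each ITM in the primary's sector with probability φ (the single
interpretable "biology knob"), otherwise uniformly over the other three
sectors; with probability 0.80 a patient's ITM are restricted proximal of
the primary, matching the published per-patient proximal/distal split.
Every lesion is jittered tangentially (σ = 0.5 cm) and re-snapped to the
surface, emulating localization "in the middle of the scar" after
excision.

The site-specific defaults φ_leg = 0.968 and φ_foot = 0.735 were
calibrated once, on the full generative pipeline (count distribution,
uniform in-sector placement, jitter, default mesh), so that the expected
full-match rate is 71% on the lower leg and 20% on the foot — the
published pattern. A purely binomial calibration that ignores jitter gives
0.92/0.71 and undershoots the full-match rate by ~10 points, because the
jitter moves ~5% of lesions across a sector boundary. The calibration
curve (1500 simulated patients per φ):

| φ (leg) | 0.93 | 0.95 | 0.96 | 0.97 | 0.98 |
|---------|------|------|------|------|------|
| P(full) | 0.57 | 0.65 | 0.68 | 0.72 | 0.76 |

What the generator does **not** emulate: surgically rerouted lymphatic
drainage (modeled only as a lower φ, not as explicit vessel anatomy),
dual-pathway primaries, photographic annotation error beyond isotropic
jitter, anatomical variation of the limb shape (all patients are mapped to
one canonical surface, as in the source methodology), and any spatial
correlation between a patient's ITM beyond the shared sector. Passing
tests therefore demonstrate that the pipeline's inference machinery is
correct and calibrated under the stated generative model — not that the
biological claim holds in real photographs.

## Validation design and problem sizes

The test suite checks, among others: exact recovery of 1000 random rigid
motions (residual < 1e−8 cm); mirror involution to the bit; zone
assignment against a brute-force angular-sector oracle on 1000 random
surface points with exact area partition; geodesic accuracy on analytic
surfaces, exact symmetry, and refinement monotonicity on 100 random pairs;
the published worked examples and table percentages exactly; the published
p = 0.007 and the chi-square bound; type-I error of the site comparison at
equal φ (4.6% over 500 replicates of the 31 + 15 subset, inside the
4–6% acceptance band); and logistic coefficient recovery over 200 cohorts
of n = 2000 with 95% CI coverage required in [0.92, 0.975]. Simulation
sizes (500 / 200 / 50 replicates) were chosen to give Monte-Carlo standard
errors comfortably below the acceptance margins while keeping a full test
run on a single CPU in minutes.

## Worked example

```{r example, eval = FALSE}
leg <- build_reference_leg()
cfg <- simulation_config(seed = 7)

# one synthetic patient in their own (moved, right-sided) image frame
patient <- data.frame(patient_id = "P001", site = "lower_leg",
                      side = "right", has_itm = TRUE, n_itm = 9)
lesions <- simulate_lesions(cfg, patient, leg, patient_index = 1)
obs <- simulate_patient_observation(cfg, lesions, leg, patient_index = 1)

mapped <- map_patient(obs$lesions, obs$landmarks, leg)
score_patient(mapped)

# skin-surface distances primary -> each ITM
gg <- geodesic_graph(leg, refinement = 3)
lesion_distances(gg, mapped$lesions)
```

## Known limitations

* The sector boundaries are an angular-wedge approximation of anatomy that
  is published only pictorially; conclusions sensitive to exact boundary
  placement should vary `boundaries` and `plantar_zone`.
* Geodesics are exact only per crossing sequence; on very coarse meshes a
  path can remain in a slightly suboptimal corridor. Accuracy is
  controlled by `refinement` and the mesh resolution.
* The asymptotic Mann–Whitney p is anti-conservative/conservative in
  small, heavily tied samples; use `method = "exact"` below ~12 per group
  when the decision is borderline.
* One canonical limb stands in for all patients; residual shape mismatch
  appears as snap distance and is capped by `snap_threshold`, not
  modeled.
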