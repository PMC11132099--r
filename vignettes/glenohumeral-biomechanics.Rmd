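---
title: "Patient-specific glenohumeral biomechanics: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific glenohumeral biomechanics: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glenosim)
```

## The scientific question

Rotator cuff tears (RCT) and glenohumeral osteoarthritis (OA) are associated
with distinct scapular morphologies: RCT shoulders tend to have a larger
critical shoulder angle (CSA) and a more superiorly oriented glenoid, OA
shoulders a smaller CSA and a more inferiorly inclined glenoid. The package
implements a complete computational chain for asking how such morphology
shapes glenohumeral joint loading: parametric synthetic scapulae whose CSA
and glenoid inclination (GI) distributions match the two clinical groups,
geometric fitting of a patient-adapted joint centre, a reduced inverse-
dynamics shoulder model with cubic-cost muscle recruitment under a
concavity-compression stability cone, shear-to-compression instability
metrics against a passive-stability polygon, and one-dimensional statistical
parametric mapping (SPM) to compare force curves between cohorts.

Because clinical CT segmentations cannot be redistributed, the package's
subjects are synthetic. The cohort-level force magnitudes of real patients
are therefore not reproduction targets; the chain instead reproduces the
*structure* of the analysis and its directional findings (which way the
instability ratio and moment arms move with morphology), which are the
robust, model-independent content.

## Coordinate conventions

Every shoulder lives in a right-handed local frame: +X lateral (toward the
glenoid face of a right shoulder), +Y superior, +Z anterior; units are mm,
N and degrees. Left shoulders are represented by flipping the anterior
coordinate; `simulate_arc()` mirrors left-side geometry back into the
right-handed frame before analysis, so all reported shear components are
anatomically signed (positive = superior / anterior) for both sides, and
group pooling does not flip signs again.

## The synthetic anatomy generator

`generate_shoulder()` builds a simplified parametric scapula: the glenoid is
a shallow elliptic dish whose rim lies exactly in the glenoid plane; the
acromion is a lateral arch whose tip is solved from the prescribed CSA (the
ray from the inferior glenoid margin at the CSA angle from the glenoid
line); the coracoid and blade are a fixed template scaled by glenoid height,
with a seeded sub-millimetre surface detail field so subjects differ beyond
their parameters. The humeral head is an exact spherical cap of the
prescribed bone radius centred at the patient-adapted joint centre. The
construction is analytically invertible: the landmark-based CSA/GI operators
recover the prescribed angles exactly, which is what makes generator /
morphometrics round-trip tests meaningful.

The GI convention needs stating because clinical conventions vary: GI here
is the angle between the supraspinatus-fossa axis (glenoid centre toward the
angulus superior, i.e. medial) and the inferior-to-superior glenoid line,
projected on the scapular plane. 90 deg means a glenoid face perpendicular
to the fossa axis; the RCT-like group mean is 81.42 deg and the OA-like
group mean 86.13 deg under this convention. Mapping to another clinical
convention is an affine relabelling left to the user.

`sample_cohort()` draws CSA ~ N(32.73, 4.89) and GI ~ N(81.42, 5.89) for the
RCT-like group and CSA ~ N(24.88, 6.15), GI ~ N(86.13, 7.16) for the OA-like
group, truncated to the valid parameter range by resampling (not clipping,
which would distort the distribution shape). Sex and side follow the group
compositions proportionally (RCT 28 M / 27 F and 15 L / 40 R of 55; OA
28 M / 20 F and 17 L / 31 R of 48). Glenoid height is N(36, 2) mm truncated
to [31.5, 40.5] mm, width 0.72 +/- 0.03 of height, humeral head radius
N(24, 1.5) mm: typical adult ranges. What the generator does **not** emulate:
real cortical surface texture, osteophytes, glenoid version/retroversion,
acromial shape classes, and the correlation structure between CSA, GI and
glenoid size in real patients (parameters are drawn independently). Passing
tests therefore demonstrate correctness of the computational chain under
the stated distributions, not clinical validity of any magnitude.

## Geometric fitting

The joint geometry chain mirrors what one would run on segmented meshes:

1. nine rim points resampled at 40 deg spacing around the glenoid rim,
   starting from the superior landmark and rotating through the anterior
   one (the resampling is a design choice; any fixed spacing would do);
2. a total-least-squares plane through the nine points, normal oriented
   laterally via the scapular mesh centroid;
3. a circle fit (algebraic Kasa fit plus Gauss-Newton refinement) to the
   five rim points nearest the inferior direction, projected on the plane —
   its centre is the glenoid centre;
4. a least-squares sphere fit to the humeral head (two-pass vertex
   selection around the articular pole, excluding the shaft);
5. the joint centre placed at the glenoid centre plus the plane normal
   times (bone radius + 2 mm uniform cartilage).

The 2 mm cartilage allowance is the configurable `cartilage_offset`;
reducing it medialises the joint centre, which lengthens the lateral
deltoid moment arm and lowers the peak total force — a property tested
directly.

Stature scaling is affine in glenoid height: `h = 1800 + (gh_patient -
gh_reference - 2.9 * sex) * 74` mm, i.e. 7.4 cm of stature per millimetre of
glenoid height, with a 2.9 mm female offset (the generic reference model is
male). The parenthesisation is the only reading consistent with both stated
gradients. The generic-model glenoid height `gh_reference` has no published
value; it is a configuration constant defaulting to 36 mm. Body mass scales
linearly with height from a configurable 75 kg at 1800 mm; because all
cohort forces are normalised by body weight, the reference mass constant
cancels from %BW results.

## Registration

Template-to-target registration is affine ICP (principal-axes + centroid
initialisation, least-squares affine per iteration, relative-improvement
stop at 1e-6 or 100 iterations, 5000 sampled points) followed by a
landmark-constrained non-rigid warp. The warp is a 3-D thin-plate spline
(biharmonic kernel plus affine part) fitted as a weighted ridge regression:
closest-point correspondences on a subsampled surface are soft constraints,
the four glenoid rim landmarks (superior, anterior, inferior, posterior)
are hard constraints via a 1e7 relative weight. The ridge formulation is a
deliberate numerical choice: the interpolating TPS system with the 3-D
kernel is indefinite and a direct smoothed solve amplifies near-duplicate
control points catastrophically, while the ridge-regularised least-squares
fit is well posed for any kernel sign and any control configuration.
Surface controls closer than 2 mm to a hard landmark are dropped for
conditioning. This warp is a desk-scale stand-in for a diffeomorphic
registration framework: it preserves the pipeline's role (dense
correspondence with glenoid landmark fidelity) but offers no
diffeomorphism guarantee. Accuracy metrics are the symmetric Hausdorff
distance, mean/median point-to-surface distance (true point-to-triangle
distances, computed in compiled code) and per-landmark point-to-point
errors. Hausdorff is symmetric here; one-directional variants exist in the
literature and would be smaller.

## The reduced musculoskeletal model

Nine line-of-action elements span the joint: three deltoid parts
originating on the acromial arch (hence moving with CSA and acromial
offset) and wrapping a sphere centred at the joint centre (radius = bone
radius + 4 mm), and six cuff bundles (supraspinatus, superior/inferior
infraspinatus, superior/inferior subscapularis, teres minor) as straight
lines from the scapular body to the proximal humerus. Strength is
proportional to physiological cross-sectional area (literature-ratio
table, specific tension 60 N/cm^2 — the absolute scale is a free constant
chosen so the protocol's hardest pose, 120 deg with a 10 N hand load, is
feasible; only force *ratios* and directions carry scientific content
here). Muscles are strength-limited but have no force-length-velocity
properties, matching the quasi-static protocol.

Kinematics: elevation arcs in the frontal (abduction) or sagittal
(flexion) plane over 0-120 deg in 12 increments, with a linear 2:1
scapulohumeral rhythm (two thirds of elevation at the glenohumeral joint,
one third scapular rotation about the same axis). The external demand is
the quasi-static gravity + hand-load moment of a straight arm with
standard anthropometric segment fractions of the scaled stature and mass.

Recruitment minimises the cubic cost `sum((F_i/N_i)^3)` subject to moment
equilibrium about the joint centre, bounds `0 <= F_i <= N_i`, and the
stability-cone constraint: the glenoid-directed reaction must pass from the
joint-centre apex through the rim polygon. The cone facets are half-space
constraints linear in the forces, so the program is convex with a strictly
convex objective on the positive orthant — the optimum is unique. The
moment equality is eliminated exactly by a nullspace (SVD) parametrisation,
so the equilibrium residual is at machine precision regardless of solver
tolerance; the inequalities are handled by a log-barrier interior method
(`constrOptim`) with an analytic gradient after a squared-hinge phase-1
search for a strictly feasible start. The barrier leaves forces a fraction
of a newton inside their bounds; tests account for this floor.

Which moment components are enforced is itself a modelling decision. A
nine-element set has no axial humeral rotators and no horizontal-plane
adductor (pectoralis major, latissimus dorsi and teres major are outside
it), and in flexion the deltoids generate a horizontal-plane moment that
only those muscles could balance — enforcing all three components makes
mid-arc flexion infeasible for a fraction of morphologies, and a randomized
feasibility search confirms no non-negative solution exists. The arc
simulation therefore enforces single-DOF inverse dynamics: the moment about
the instantaneous motion axis, which is also the only axis about which
gravity and the hand load exert any moment. Out-of-plane and axial balance
are attributed to the unmodelled musculature. `solve_recruitment()` keeps
the full three-component equality by default (used by the toy-system
oracle tests) and accepts any enforcement basis.

One constraint geometry choice deserves emphasis. The *metric* polygon
(`passive_polygon()`) uses the bony rim: `p_n = g_n / r_humerus` at eight
45-degree directions. But a recruitment cone built from the bony rim alone
makes late flexion infeasible — and the phenomenon the analysis is designed
to exhibit is precisely a dynamic instability ratio that *exceeds* the bony
passive limit in flexion. The recruitment cone is therefore the rim polygon
dilated by `cone_scale = 1.5` about its centroid, representing
capsulolabral containment beyond the bony rim. The value was fixed once
from the protocol's feasibility requirement (flexion to 120 deg under
10 N); with it, simulated flexion shows the instability ratio crossing the
bony polygon from roughly 65 deg onward while abduction stays inside —
the qualitative pattern the metrics are meant to capture.

Sign conventions: compression is positive into the glenoid (along the
negative plane normal), vertical shear positive superior, horizontal shear
positive anterior; moment arms are positive for agonists of the motion.
The instability direction uses the two-argument arctangent
`theta = atan2(rho_vert, rho_horz)` (superior = 90 deg) — the single-
argument form loses the quadrant and cannot represent posterior-inferior
loading. Points exactly on the polygon count as stable. %BW normalisation
uses body weight in newtons (mass x 9.81). Increments with non-positive
compression report `NA` ratios rather than being dropped.

## Cohort statistics

Curves are pooled in long format (subject, group, side, variable, angle,
value). Group summaries give per-angle means and SDs; peak comparisons are
taken on the *group-mean* curves (matching the "mean maximum" convention),
with the mean of per-subject maxima reported alongside. The SPM two-sample
t-test is pointwise, two-tailed, with the family-wise threshold t* taken
from the permutation distribution of the curve-maximum |t| statistic
(observed labelling included). A permutation threshold was chosen over
random-field theory because it is distribution-free, exactly calibrated at
these sample sizes, and needs no smoothness estimate on a 12-point grid;
the random-field variant could be added behind the same interface. The
test suite verifies the cluster-level type-I error is 0.05 +/- 0.02 over
1000 simulated null cohort pairs (200 permutations each) and that the
threshold is stable across seeds at 10000 permutations.

## Degenerate inputs and tie-breaks

Sphere fits reject coplanar points (the algebraic system is rank
deficient); plane fits reject collinear points; the circle fit needs three
points. Rim-point selection breaks the tie between equidistant candidates
for the "inferior five" by the smaller angle from the superior landmark.
The lateral acromion landmark for CSA is whichever acromial landmark
projects more laterally, ties going to the anterolateral one. A muscle line
through the joint centre has zero moment arm (not an error); wrap geometry
falls back to the straight line when the segment does not penetrate the
sphere or an endpoint lies inside it.

## Problem sizes and determinism

Defaults follow the study protocol: cohorts of 55 RCT-like and 48 OA-like
subjects, 12 increments over 0-120 deg, 10 N hand load, both motions.
The test suite exercises smaller cohorts (3-20 subjects) and 200-10000
permutations so the full suite runs in a few minutes; the acceptance script
regenerates the full-size cohorts for the morphometric targets. All
randomness flows from named integer seeds (cohort sampling, per-subject
surface detail, ICP/warp subsampling, permutations); runs are bitwise
reproducible per seed, and subjects are processed independently so ordering
cannot affect results.

## Known limitations

No humeral translation or contact mechanics (the joint is an ideal ball);
no Hill-type muscle properties; the scapular rhythm is a fixed linear
ratio; the generator's blade and acromion are schematic (only rim points,
landmarks and attachment frames feed the downstream computation); CSA is
projected on the scapular plane without glenoid-version correction, which
overestimates CSA for retroverted glenoids; and absolute force magnitudes
depend on the strength table and attachment template, which is why the
package's claims about group differences are directional, not quantitative.
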