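# glenosim

Patient-specific glenohumeral joint biomechanics at desk scale: how scapular
morphology — the critical shoulder angle (CSA) and glenoid inclination (GI)
that separate rotator-cuff-tear-like (RCT) from osteoarthritis-like (OA)
shoulders — shapes joint reaction forces, muscle moment arms and joint
stability. The package is aimed at musculoskeletal modellers and shoulder
biomechanics researchers who want a fully scripted, reproducible version of
the morphology-to-forces analysis chain without access to clinical CT data.

The chain, end to end:

1. **Synthetic anatomy** — parametric scapula + proximal humerus meshes and
   11 anatomical landmarks whose CSA/GI distributions match the two clinical
   groups (RCT: CSA 32.73 ± 4.89°, GI 81.42 ± 5.89°; OA: CSA 24.88 ± 6.15°,
   GI 86.13 ± 7.16°).
2. **Joint geometry** — total-least-squares glenoid plane through nine rim
   points, circle fit to the inferior five for the glenoid centre
   $\vec{x}_{gl}$, least-squares sphere fit of the humeral head (radius
   $r_h$), and the patient-adapted joint centre
   $\vec{x}_{gh} = \vec{x}_{gl} + \hat{n}\,(r_h + 2\,\text{mm})$.
   Stature scales from glenoid height as
   $h = 1800 + (gh_{patient} - gh_{ref} - 2.9\,\text{SEX})\cdot 74$ mm.
3. **Registration** — affine ICP plus a landmark-constrained thin-plate-spline
   warp, verified by Hausdorff, mean/median point-to-surface and per-landmark
   distances.
4. **Reduced inverse dynamics** — nine muscle elements (3 deltoid parts with
   sphere wrapping, 6 cuff bundles), strengths ∝ PCSA; recruitment minimises
   $\sum_i (F_i/N_i)^3$ subject to moment equilibrium $\sum_i \vec{r}_i
   \times \vec{F}_i = \vec{M}_{req}$, bounds $0 \le F_i \le N_i$ and a
   stability cone requiring the joint reaction to pass through the glenoid
   rim polygon; quasi-static 0–120° abduction/flexion arcs with a 10 N hand
   load and 2:1 scapulohumeral rhythm.
5. **Stability metrics** — instability ratios $\rho_{vert}, \rho_{horz}$
   (shear/compression), radial form $r_{ins} = \sqrt{\rho_{vert}^2 +
   \rho_{horz}^2}$, $\theta = \mathrm{atan2}(\rho_{vert}, \rho_{horz})$, and
   the passive-stability polygon $p_n = g_n / r_{humerus}$ at eight 45°
   directions.
6. **Cohort statistics** — %BW-normalised group curves, peak comparisons, and
   1-D SPM two-sample t-tests with a permutation-based critical threshold t*.

See the vignette (`vignettes/glenohumeral-biomechanics.Rmd`) for the model
assumptions, conventions and numerical choices.

## Worked example

```r
library(glenosim)

p <- anatomy_params(csa_deg = 35, gi_deg = 84, seed = 1)
a <- generate_shoulder(p)
measure_csa(a$landmarks)   # 35   — generator/morphometrics round-trip
measure_gi(a$landmarks)    # 84

jg <- fit_joint_geometry(a$scapula, a$humerus, a$landmarks)
jg
#> joint_geometry:
#>   glenoid centre  [0.39, -3.74, 0.30] mm
#>   plane normal    [0.995, 0.105, -0.000]
#>   humeral radius  24.00 mm bone, 26.00 mm effective
#>   joint centre    [26.25, -1.03, 0.30] mm

sim <- simulate_arc(a, "abduction")
sim
#> arc_simulation: abduction, 12 increments over 0-120 deg
#>   peak total force 520.8 N (70.8 %BW) at 87 deg
```

The joint centre sits exactly 2 mm (the cartilage allowance) beyond the
fitted humeral head radius along the glenoid normal. The simulated abduction
arc peaks near 90° at ~71 %BW for this subject; per-increment compression,
superior and anterior shear (N and %BW), muscle forces, moment arms and
torques are in `sim$forces` and `sim$muscle_states`. Instability ratios and
the passive polygon follow with `instability_series(sim)` and
`passive_polygon(jg, glenoid_rim_points(a$scapula, a$landmarks, n = 8))`;
a full two-cohort comparison (group summaries, SPM, polygon areas) runs with
`run_experiment(experiment_config())`.

A command-line front end over the same functions lives at
`inst/cli/glenosim.R` with verbs `generate`, `register`, `simulate` and
`run-all`.

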