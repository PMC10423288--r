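# pearlrot

Non-invasive monitoring of cultured pearl rotation, and prediction of the
final pearl shape from rotation data.

Tahitian pearls (*Pinctada margaritifera*) rotate inside the pearl sac while
nacre is deposited, and the rotation pattern is tied to the final shape of
the pearl: random tumbling goes with (semi-)round pearls, steady axial
rotation with atypical shapes (baroque, drop, button, circled), and absence
of rotation with pearls that receive no regular deposit. `pearlrot`
implements the full measurement-and-analysis chain of a magnetometer-based
monitoring device for this phenomenon, together with a seeded synthetic-data
generator so every stage can be exercised and tested without access to
original recordings.

The chain, stage by stage:

1. **Dome geometry** — a hemispherical 4.2 L dome (radius
   r = (3V/2π)^⅓ ≈ 0.126 m) carrying 25 single-axis magnetic sensors on
   rings at 6°, 30° and 60° elevation plus one zenith sensor
   (`build_dome()`).
2. **Physics simulation** — the magnetized nucleus is a point dipole,
   B ∝ (3(m̂·r̂)r̂ − m̂)/|r|³; class-conditional rotation regimes generate
   moment trajectories u(t) on the unit sphere at a cohort speed of
   0.69 ± 0.13 ° min⁻¹ (`simulate_trajectory()`, `simulate_cohort()`), and a
   clock-driven calibration scene rotates the magnet at exactly one
   revolution per hour (`simulate_clock_scene()`).
3. **Signal path** — channels are smoothed with a Gaussian-weighted moving
   average (window 60 samples), and the moment direction is reconstructed as
   the position-weighted sum of radial readings,
   û(t) ∝ Σᵢ vᵢ(t) (âᵢ·p̂ᵢ) p̂ᵢ (`gaussian_smooth()`,
   `reconstruct_orientation()`). Angular speed comes from spherical step
   angles or from the equator-projected azimuth rate (`angular_speed()`).
4. **Imaging** — weekly trajectory segments are rendered as deterministic
   224 × 224 RGB images, viewed along the data barycenter and coloured by
   time (`render_views()`, `assemble_dataset()` with day / week / month /
   full variants).
5. **Classification** — a frozen convolutional backbone extracts image
   features, the two cultivation scalars (days of cultivation, days from
   graft to acquisition) are z-scored and fused, and a dense/dropout/softmax
   head is trained; per-pearl predictions take the majority vote over weekly
   samples (`train_classifier()`, `predict_pearl()`).
6. **Evaluation** — grouped stratified 70/15/15 repeated holdout (pearls
   never straddle splits), accuracy and weighted/macro F1 with dispersion
   over repeats (`grouped_stratified_split()`, `repeated_holdout()`).

## Worked example

```r
library(pearlrot)

geom <- build_dome()

# calibrate against the clock rig: one revolution per hour
scene <- simulate_clock_scene("perpendicular", ring_position = 2)
rec   <- simulate_recording(scene$trajectory, geom, noise_sd = 0, offset_sd = 0)
est   <- angular_speed(reconstruct_orientation(rec, geom), method = "azimuth")
est
#> <speed_estimate> 6.000 deg/min (sd 0.000), 1.00 h/rev [azimuth, lag 1 s]
calibration_accuracy(est, scene$true_speed)
#> [1] 100

# a small labeled cohort through the whole pipeline
cfg <- experiment_config(simulation = list(n_pearls = 24, seed = 1),
                         evaluation = list(n_repeats = 3, variants = "full"))
res <- run_full_experiment(cfg)
print(res$report, row.names = FALSE, digits = 3)
#>  variant  level accuracy accuracy_sd weighted_f1 macro_f1 f1_other f1_atypical
#>     full sample    0.852       0.128       0.839    0.839    0.952       0.722
#>     full  pearl    1.000       0.000       1.000    1.000    1.000       1.000
#>  f1_round
#>     0.841
#>     1.000
```

The calibration estimate recovers the rig's 6 ° min⁻¹ exactly (the azimuth
rate telescopes over a full revolution). On the 24-pearl cohort, weekly
samples classify at 85% and the per-pearl majority vote over weeks is
perfect — majority voting denoises exactly as in the field data. The
defaults (`experiment_config()`) run the 60-pearl experiment with ten
holdout repeats per dataset variant.

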