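# dancekin

Interpretable kinematic features and genre classification for 3D dance
motion.

## The problem

Dance genres differ in ways audiences can feel but struggle to state:
how bouncy the movement is, how sharply it accents, how much the dancer
turns, how expanded the body is. Deep action-recognition models can
classify skeleton sequences but explain little. `dancekin` takes the
opposite route: it reduces a full-body 3D pose sequence (COCO-17
keypoints at a known frame rate) to **17 named kinematic features** that
a movement researcher can read directly, then shows that this tiny
encoding is enough to drive a competitive genre classifier — and to
analyse *why* it works. The intended users are movement scientists,
dance researchers and anyone building interpretable pipelines on top of
pose estimation.

## The encoding

With $P_{ij}$ the position of joint $j$ at frame $i$ and
$SP_i$ the sacrum (the midpoint of the hips, since COCO omits the
spine), the substrate is forward finite differences with Savitzky–Golay
smoothing after each stage:

$$SV_i = \frac{SP_{i+1}-SP_i}{\Delta T},\quad
SA_i = \frac{SV_{i+1}-SV_i}{\Delta T},\quad
SJ_i = \frac{SA_{i+1}-SA_i}{\Delta T}$$

The 17 features cover four categories — sacral movement (horizontal
speed, height SD, jerkiness $\overline{\|SJ\|}$, bounce frequency and
regularity), extremities (wrist/ankle acceleration, ankle height above
the inferred floor), sacrum-centred angular momentum
($L_{ij} = R_{ij}\times V_{ij}$ with $R_{ij} = P_{ij}-SP_i$; mean/SD
magnitude, horizontal rotation, per-axis sharp-movement rates), and
expandedness ($\overline{\|R_{ij}\|}$, mean and SD). An augmented
registry adds 3 autocorrelation rhythm features. On top of the encoding
sit linear baselines, a budgeted model-zoo search with a greedy weighted
ensemble minimizing multiclass log loss, an SVD (LSA-style) genre
similarity embedding, Shapley/permutation feature importance, per-genre
fingerprints, and a parametric stick-figure simulator with closed-form
feature oracles. See `vignettes/dancekin-methods.Rmd` for the full
methods account.

## Worked example

Simulate a dancer who bounces at 2 Hz (amplitude 5 cm) while turning at
1 rad/s, and extract the encoding (smoothing disabled so the values can
be checked against the closed forms):

```r
library(dancekin)
spec <- motion_spec(duration = 10, bounce_amplitude = 0.05,
                    bounce_frequency = 2, spin_rate = 1, seed = 1)
pose <- generate_motion(spec)
pose
#> pose_sequence 'sim': 600 frames x 17 joints @ 60 fps (10.0 s)
round(unclass(extract_features(pose,
        smoothing = smoothing_config(enabled = FALSE))), 3)
#> sacrum_xz_speed_mean     sacrum_height_sd     sacrum_jerkiness
#>                0.000                0.035               62.419
#>     bounce_frequency    bounce_regularity     wrist_accel_mean
#>                2.000                1.000                5.032
#>     ankle_accel_mean    ankle_height_mean      ankle_height_sd
#>                5.017                0.050                0.035
#>      angmom_mean_mag        angmom_sd_mag  horizontal_rotation
#>                0.094                0.041                0.027
#>         sharp_rate_x         sharp_rate_y         sharp_rate_z
#>                2.010                8.643                1.809
#>    expandedness_mean      expandedness_sd
#>                0.503                0.238
```

The numbers mean what they say: the sacrum's height varies with SD
3.5 cm (a 5 cm sinusoid gives $A/\sqrt2 = 0.035$), it bounces at exactly
2 Hz with perfect regularity, its jerkiness is 62.4 m/s³ (closed form
$A(2\pi f)^3\cdot 2/\pi = 63.2$, recovered to ~1% by raw differences),
and the mean joint is 0.50 m from the sacrum.

Classification end to end on the bundled ten-genre synthetic dataset:

```r
ds <- generate_genre_dataset(n_per_genre = 12, seed = 1)
fm <- extract_feature_matrix(ds)
sp <- split_advanced_test(ds, seed = 1)   # advanced-only test set
ids <- function(d) vapply(d$sequences, `[[`, "", "sequence_id")
reattach <- function(x) { attr(x, "registry") <- attr(fm, "registry")
                          class(x) <- class(fm); x }
tr <- reattach(fm[match(ids(sp$train), fm$sequence_id), ])
te <- reattach(fm[match(ids(sp$test), fm$sequence_id), ])
ens <- automl_fit(tr, train_config(search_budget = 20, seed = 1))
evaluate_model(ens, te)
#> classification_report: accuracy 1.000 (n = 10)
#>             precision recall f1 support
#> Ballet Jazz         1      1  1       1
#> Break               1      1  1       1
#> ...
```

Perfect accuracy here reflects the simulator's well-separated genre
caricatures, not a claim about real dancers (see the vignette's
discussion of what the synthetic results do and do not show). Real
keypoint data enters through `read_pose_sequence()` (JSON, long CSV, or
a keypoints3d container) and flows through the same calls.

## Command line

A thin CLI over the same functions ships in `inst/cli/dancekin.R`
(`simulate`, `extract`, `run`), e.g.

```sh
Rscript inst/cli/dancekin.R run --out run1 --n-per-genre 12 --seed 1
```
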