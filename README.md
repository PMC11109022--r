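# audiencesync

Tools for quantifying how the facial expressions of audience members
synchronize during a live performance.

Automated facial-expression classification turns video of a seated
audience into, for every participant, a per-frame intensity in \[0, 1\]
for each of eight channels — neutral, happy, sad, angry, surprise, fear,
disgust, contempt (0 = expression not detected, 1 = fully present;
50 frames/s in typical recordings). `audiencesync` takes those tables
and asks: do audience members' expressions rise and fall together, and
what drives that synchrony — the performance itself, sitting close to
one another, or who the audience members are (age, empathy, gender)?

## The method

**Sliding-window inter-subject correlation (ISC).** For each expression
channel, every participant's intensity series is Pearson-correlated with
the same channel of every other participant inside a sliding window
(default 60 s = 3000 frames, advanced in 2 s = 100-frame steps), over
the frames both participants' faces could be modelled. The per-window
mean of all pairwise r values is the ISC time course
(`sliding_window_isc()`). A single whole-performance correlation per
pair and channel (`pairwise_isc()`) feeds the pair-level analyses. All
r values entering inference are variance-stabilized with Fisher's
transform, z = atanh(r) (`fisher_z()`).

**Inclusion.** Only participants whose faces could be modelled for
strictly more than 90% of the performance and who completed all
questionnaires are analyzed, and a performance is only analyzed when
more than one participant qualifies (`apply_inclusion()`).

**Engagement.** A dramaturge scores each scene 1–3 for predicted
audience engagement. The scene script is resampled onto the ISC window
grid (`resample_engagement()`) and related to the ISC time courses by
Pearson correlation with JZS Bayes factors and by all-subsets linear
regression ranked with a BIC-based posterior proxy
(`isc_engagement_correlation()`, `engagement_regression()`).

**Proximity.** Seats are a unit grid; pair distance is Euclidean in seat
units. The correlation between √distance and Fisher-z pair ISC
(`proximity_correlation()`) is tested against a permutation null that
shuffles ISC values across pairs 10,000 times
(`permutation_test_proximity()`).

**Pair characteristics.** Each pair's combined age and empathy total
(EQ-short 0–44 or QCAE 4–124) are correlated with pair ISC with
directional Bayes factors under a Cauchy(0.5)-style prior
(`feature_association()`); gender/age groupings are compared against an
age-only null model (`group_contrast()`).

**Synthetic audiences.** `simulate_recording()` generates audiences with
known ground truth — an engagement-gated shared signal, a spatially
correlated local field decaying as exp(−d/λ) across seats,
trait-modulated coupling weights, and frame dropout — so every stage of
the pipeline has a recovery test. `simulate_null_recording()` produces
fully independent tracks for calibration.

## Worked example

```r
library(audiencesync)

cfg <- simulation_config(n_participants = 12, n_frames = 6000, seed = 2024)
sim <- simulate_recording(cfg)
rec <- apply_inclusion(sim$recording)
rec
#> <audience_recording> 'sim-seed2024': 12 participants, 6000 frames

isc <- sliding_window_isc(rec, window_spec(3000, 100))
dplyr::filter(tibble::as_tibble(isc), expression == "happy") |> head(3)
#> # A tibble: 3 x 5
#>   window_start_frame window_start_s expression mean_r n_pairs
#>                <int>          <dbl> <fct>       <dbl>   <int>
#> 1                  0              0 happy      0.0133      66
#> 2                100              2 happy      0.0133      66
#> 3                200              4 happy      0.0138      66
```

Mean happy-expression ISC is about 0.013: weak but positive synchrony
across the 66 pairs, the magnitude typical of real audiences. Seat
proximity and synchrony:

```r
pt <- pairwise_isc(rec)
proximity_correlation(pt, "happy")
#> [1] -0.1693118
permutation_test_proximity(pt, "happy", n_perm = 10000, seed = 99)
#> <permutation_result> r_obs = -0.1693, p = 0.0908 (negative, plain rule,
#>     10000 permutations, 66 pairs, seed 99)
```

Closer pairs are more synchronized (negative correlation with
√distance), though 66 pairs are too few for significance — the effect is
detected reliably at realistic audience sizes (hundreds of pairs; see
the recovery tests). Within-expression versus between-expression
synchrony:

```r
mats <- lapply(participant_ids(rec),
               function(id) individual_vs_rest_matrix(rec, id))
wb <- within_between_contrast(mats)
wb
#> <within_between_contrast> 12 individuals; mean on-diag z = 0.046,
#>     mean off-diag z = 0.001
bf_paired_ttest(wb$individual$contrast, bayes_spec())
#> <bayes_result> BF10 = 4.256e+05 [jzs-ttest]; posterior median 3.494,
#>     95% CI [1.897, 5.295]
```

Each individual's expressions correlate with the rest of the audience
mainly within the same channel (happy with happy, not happy with sad):
overwhelming evidence that on-diagonal synchrony exceeds off-diagonal.

Every result type has `autoplot()`/`plot_*()` methods and broom-style
`tidy()`/`glance()` methods. A thin command-line front end
(`inst/cli/audiencesync.R`, subcommands `simulate`, `analyze`, `report`)
drives the same functions from a shell.

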