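# cannulaskill

Motion-smoothness and outcome metrics for simulator-based hemodialysis
cannulation skill assessment.

## The problem

Inserting a dialysis needle into an arteriovenous (AV) fistula is a
routine but high-stakes clinical task: miscannulation causes
infiltration, hematoma and loss of vascular access. Training simulators
instrument the task with a needle-tip position tracker (100 Hz) and an
in-needle LED that emulates blood *flashback*, the visible confirmation
of correct placement. The open questions this package addresses for
such data are:

1. Which *skill indicator* best reflects clinical skill — the objective
   outcome metric **FR** (flash ratio), an expert **GRS** (global rating
   sheet) score, or years of experience (**Exp**)?
2. How does the degree of sensor-data smoothing affect motion-smoothness
   metrics that depend on higher-order derivatives?
3. Are smoothness metrics better correlated with skill than simpler
   process metrics?

## The metrics

From the task window `[t_entry, t_end]` (first skin puncture to end of
record) the package computes, per trial and per Savitzky–Golay window
span:

| Metric | Definition |
|---|---|
| `T` | task time `t_end − t_entry` (s) |
| `PL` | path length: sum of Euclidean steps of the smoothed tip position (mm) |
| `Pks` | number of local maxima of the speed profile |
| `LDLJ` | log dimensionless jerk `−ln| (T⁵/PL²) ∫‖d³x/dt³‖² dt |` |
| `SPARC` | spectral arc length `−∫₀^ωc √((1/ωc)² + (dV̂/dω)²) dω`, `V̂(ω) = V(ω)/V(0)` |
| `FR` | flash ratio `Σ(t_flash_end − t_flash_begin) / (t_end − t_flash)` ∈ [0, 1] |

Derivatives come from a third-order Savitzky–Golay filter; the window
span sweep `{5, 25, 51, 101, 201}` samples (minimum to 2 s at 100 Hz)
quantifies the effect of smoothing. A single noise-free minimum-jerk
movement attains the LDLJ ceiling `−ln 720 ≈ −6.579` for any amplitude
and duration.

Each indicator is regressed on each standardized process metric (all
but LDLJ are log-transformed and sign-flipped so larger = better);
slopes are compared pairwise with Tukey's studentized-range adjustment,
`CI = (β̂ᵢ − β̂ⱼ) ± q_{α; r, n−r} · SE`.

Because the clinical dataset is IRB-restricted, the package includes a
seeded synthetic-cohort generator (minimum-jerk submovement
trajectories with skill-dependent intermittency, band-limited sensor
noise calibrated to 0.06 mm mean peaks, flashback simulation, and
latent-skill-linked indicators) so the full pipeline is testable.

## Worked example

```r
library(cannulaskill)

co  <- simulate_cohort(cohort_spec(n_participants = 50), seed = 11)
m   <- compute_metrics(co)                  # 800 trials x 5 window spans
fit <- skill_assoc(m, co$participants)
print(fit)
#> Skill-association fit (standardized simple regressions)
#>   indicators: FR, GRS, Exp
#>   process metrics: T, PL, Pks, LDLJ, SPARC
#>   window spans: 5, 25, 51, 101, 201
#>   observations per regression: 800
#>
#> Mean R^2 by indicator (across metrics and spans):
#>     FR    GRS    Exp
#> 0.2782 0.1057 0.0004
```

The ordering is the study's central finding: the objective outcome
metric (FR, mean R² ≈ 0.28) accounts for the process metrics far better
than the observer score (GRS ≈ 0.11), while experience is essentially
uninformative (≈ 0.0004). Pairwise slope comparisons at one span:

```r
tukey_pairwise(fit, by = "metric", indicator = "FR", span = 25)
#> Tukey pairwise slope comparisons (pooled, alpha = 0.05, q = 3.867, df = 795)
#>  group_i group_j estimate  lower  upper significant
#>        T      PL   0.0087 -0.0104 0.0278       FALSE
#>  ...
```

No process metric is significantly better than another at tracking FR —
smoothness metrics are *as* informative as the simpler ones once the
data are adequately smoothed. The single worked trial level:

```r
tr  <- co$trials[[1]]
seg <- segment_task(tr$series, tr$meta$skin_z)
d   <- sg_derivatives(seg, window_span = 25)
ldlj(d, time_metric(seg), path_length(d))   # e.g. -10.7 (smoother -> closer to -6.58)
sparc(d)                                    # e.g. -3.4  (smoother -> closer to -1)
flash_ratio(seg)                            # in [0, 1]
```

A shell entry point mirroring the three stages lives at
`inst/cli/cannulaskill.R` (`simulate`, `compute`, `analyze`, `config`
subcommands).

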