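# operantiiv

Intra-individual variability (IIV) analysis of operant behavior.

Attention-deficit/hyperactivity research cares not only about *how
much* a subject responds but about how *inconsistent* that responding
is from moment to moment. `operantiiv` implements a complete, tested
pipeline for quantifying that inconsistency in operant-conditioning
experiments — from time-stamped chamber event logs (lever presses,
door openings, reinforcers) to per-session **phenotypic dispersion**
for three behavioral traits, through the between-strain and temporal
statistics used to compare an ADHD-model strain (SHR) against its
control (WKY). A seeded synthetic event-stream generator emulates the
two-strain variable-interval study design, so every stage of the
pipeline is testable without access to animal data.

## The statistic

Each 90-minute session is divided into five 18-minute segments. For a
rat *i* with per-segment trait counts *X\_{ij}* (*j* = 1..*J*) and
session mean *X̄\_i*, the individual phenotypic dispersion of that
session is the mean absolute deviation

> PD\_i = (1/J) Σ\_j | X\_{ij} − X̄\_i |

computed per rat, per session, per trait. The three traits follow the
standard operant operationalization:

* **hyperactivity** — total lever presses (correct + incorrect);
  presses with inter-response time (IRT) < 0.67 s are excluded so
  burst responding does not contaminate the activity measure;
* **impulsiveness** — correct lever presses with IRT < 0.67 s;
* **inattention** — incorrect openings of the reinforcer-cubicle door.

Because the dispersion distributions are strongly right-skewed,
between-strain inference uses Kruskal–Wallis ranking of per-rat
session-averaged PD\_i, a linear model on log-transformed PD\_i (strain
means ± 95 % CI, η² variance proportion), and repeated-measures ANOVA
for temporal trends among sessions (day 1–5) and within sessions
(segment 1–5), with per-strain linear slopes.

## Worked example

```r
library(operantiiv)

# 16 SHR-like vs 15 WKY-like rats, five 90-min sessions, VI 180 s
ev <- simulate_experiment(seed = 1)

traits <- extract_traits(ev)                 # per-segment trait counts
pd     <- dispersion_table(traits)           # PD_i per rat-session-trait
cmp    <- compare_strains(pd)
dplyr::select(tidy(cmp), trait, kw_H, kw_p, glm_F, eta2,
              mean_log_SHR, mean_log_WKY)
#> # A tibble: 3 × 7
#>   trait          kw_H       kw_p glm_F  eta2 mean_log_SHR mean_log_WKY
#>   <chr>         <dbl>      <dbl> <dbl> <dbl>        <dbl>        <dbl>
#> 1 hyperactivity  22.5 0.00000210  351. 0.924         4.25         2.66
#> 2 impulsiveness  22.5 0.00000210  184. 0.864         3.45         1.80
#> 3 inattention    22.5 0.00000210  791. 0.965         2.95         1.35
```

The SHR-like strain shows higher dispersion on every trait: the
Kruskal–Wallis H of 22.5 (p ≈ 2·10⁻⁶) is the rank separation of the
31 per-rat averaged PD\_i values; `eta2` says what fraction of the
variance of log-dispersion lies between strains; `mean_log_*` are the
fitted strain means of log(PD\_i + 1).

Within-session trend of inattention dispersion:

```r
trend <- within_sessions_model(segment_deviation_table(traits), "inattention")
tidy(trend)
#> # A tibble: 3 × 8
#>   trait       scope           slope_scale strain n_rats    beta     se      p
#>   <chr>       <chr>           <chr>       <chr>   <int>   <dbl>  <dbl>  <dbl>
#> 1 inattention within_sessions raw         SHR        16  1.42   0.540  0.0193
#> 2 inattention within_sessions raw         WKY        15 -0.0875 0.0687 0.223
#> 3 inattention within_sessions raw         pooled     31  0.688  0.308  0.0333
```

The SHR-like strain's dispersion climbs by ~1.4 counts per segment as
the session progresses (its generator preset injects a positive
within-session dispersion trend); the WKY-like strain stays flat.
`autoplot(cmp)`, `autoplot(trend)` and `plot_pd_distribution(pd)`
return ggplot figures of the same results.

Event files on disk are handled by `read_events()` / `write_events()`
(CSV/TSV with header `rat_id,strain,session,time_s,event_type`), and a
YAML experiment configuration can be loaded with `read_sim_config()`;
a complete example lives in `inst/extdata/default-sim-config.yml`.

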