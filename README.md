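# cascadr

Cascade analysis for irregularly timed event streams.

Surgical safety researchers record *flow disruptions* — timestamped, typed
deviations from a procedure's natural progression — and care especially
about *cascades*: sustained periods in which the disruption rate stays
elevated (here, a mean rate of at least 1 event per minute maintained over
at least 3 minutes). cascadr turns a plain event table into cascade calls
and composition statistics, and is equally applicable to any longitudinal
event data with a time column.

The pipeline:

1. **Ingest** (`load_events`): CSV/TSV with a no-missing-values time column
   (numeric minutes or datetime strings), optional case and event-type
   columns; derives per-case relative time and an any-event indicator.
   Row filters use a small comparison grammar
   (`"Case > 10 and RelativeTime < 380"`).
2. **Regularize** (`bin_counts`): counts in half-open fixed-width bins, so
   changepoint methods apply to irregular event times.
3. **Segment** (`detect_changepoints`): penalized change-in-mean
   segmentation minimizing `sum of segment SSE + beta * m`, with four
   from-scratch solvers — `amoc` (single change), `binseg` (greedy,
   approximate), `exact_segmentation` (optimal partitioning DP), and
   `pelt` (pruned DP, identical output to exact). Default penalty
   `beta = 2 ln n` ("BIC").
4. **Call cascades** (`detect_cascades` / `find_cascades`): maximal runs of
   adjacent segments with mean rate ≥ 1/min lasting ≥ 3 min; each
   cascade's *trigger* is its earliest event's type.
5. **Enrichment** (`enrichment_table`): per event type ET, the pooled
   conditional probabilities P(cascade|ET), P(ET), P(ET|cascade),
   P(ET|¬cascade), plus an Any Event row.
6. **Simulate** (`generate_study`): seeded piecewise-constant-rate point
   processes with planted cascades and in/out-of-cascade type
   distributions, with ground truth for recovery scoring.
7. **Plot** (`render_events`): faceted, paginated stem plots with cascade
   bands and changepoint overlays; every image ships with a regenerable
   plot-spec JSON.

## Worked example

```r
library(cascadr)

cfg <- synthetic_config()           # 41 cases, ~48 events/case,
study <- generate_study(cfg, seed = 1)   # one planted 5-min cascade each
analysis <- detect_cascades(study$events)

cascades_per_case(analysis$cascades)$histogram
#>   n_cascades n_cases   pct
#> 1          0      10 24.4
#> 2          1      29 70.7
#> 3          2       2  4.88

head(trigger_tally(analysis$cascades), 3)
#>   trigger     n
#> 1 EQ         10
#> 2 COO         5
#> 3 TRN         5

tab <- enrichment_table(analysis$events)
tab[tab$event_type %in% c("TRN", "EQ", "Any Event"), ]
#>   event_type  n_in     n p_cascade_given_et  p_et p_et_given_cascade ...
#> 1 TRN           81   394               0.21  0.19               0.25
#> 2 EQ            69   479               0.14  0.23               0.21
#> 3 Any Event    324  2048               0.16  1                  1

share_statements(tab, "TRN")
#>    pct_of_cascade       pct_overall pct_of_noncascade
#>                25                19                18
```

Read: the study generated 2,048 events, 324 of them inside detected
cascades; most cases show exactly one cascade (the planted truth); the
training type (TRN), which the generator concentrates inside cascades,
accounts for 25% of in-cascade events versus 19% of all events — the
enrichment signature the analysis is built to expose. Detected cascade
counts differ from the planted one-per-case because a 5-minute,
2 events/min burst sits near the method's detection limit (see the
vignette's limitations section).

A command-line wrapper over the same pipeline lives at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --input events.csv --time-col Time \
  --case-col Case --type-col EventType --method pelt --penalty bic \
  --plot --out-dir out/
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch: it recomputes the enrichment probabilities from the packaged
per-type study counts (`inst/extdata/disruption_type_counts.csv`), runs
the full synthetic-study pipeline at the package defaults, and measures
planted-cascade recovery on a 100-case benchmark, then writes its JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
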