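# facilinet

Facilitative (cross-feeding) interaction networks from microbial community
time series.

Microbial communities can collapse abruptly, and one proposed mechanism is
the architecture of their *facilitative* interactions: when species feed each
other in closed loops, a decline anywhere in the loop can cascade through
the whole community. `facilinet` provides the full analysis chain needed to
study this on species-by-time abundance tables plus per-species metabolic
descriptions:

1. **Turnover statistics** — per-day relative abundances, Bray-Curtis
   dissimilarity, and a windowed *abruptness* index that flags rapid
   compositional shifts.
2. **A set-based cross-feeding model** — growth closure, directional
   *species coupling scores* (SCS), metabolite-transfer attribution, and the
   community-level *metabolic interaction potential* (MIP) and *metabolic
   resource overlap* (MRO), with seeded replicate runs.
3. **Directed network construction** — donor → recipient edges weighted by
   mean SCS across runs, restricted to the species detected at each time
   point, with feedback-loop edges flagged.
4. **Hierarchy metrics** — treeness *T*, feedforwardness *F* and
   orderability *O* on the strongly-connected-component condensation, which
   together diagnose pyramidal structure and positive feedback loops.
5. **Keystone ranking** — influence (reaching) centrality and PageRank per
   species, aggregated across days and runs.
6. **Synthetic data** — seeded generators for abundance series with planted
   regime shifts and toy metabolic communities with planted dependency
   loops, so the entire pipeline is testable without external data.

## The statistics in brief

* **Abruptness** at time *t* with window *w* (default 5 days):
  `a_t = BC( mean(x_{t-w+1..t}), mean(x_{t+1..t+w}) )`, where the `x` are
  per-day relative-abundance compositions and `BC(u, v) = Σ|u_i − v_i| /
  Σ(u_i + v_i)`. On normalized windows `a_t > 0.5` means more than half of
  the composition turned over.
* **Species coupling score** of recipient *r* on donor *d*: over
  sub-communities containing both in which *r* grows (by boolean growth
  closure), the fraction in which removing *d* abolishes *r*'s growth —
  0 is complete independence, 1 essentiality. Exhaustive enumeration up to
  12 species, seeded Monte-Carlo beyond.
* **MIP** = |union of all requirement sets| − |smallest medium under which
  every species grows with exchange| (exact subset search at desk scale).
  **MRO** = mean over species pairs of |shared requirements| / |smaller
  requirement set|.
* **Orderability** = fraction of nodes in acyclic singleton SCCs.
  **Feedforwardness** = mean over maximal-to-minimal condensation paths of
  (path length in SCCs) / (original nodes covered). **Treeness** compares
  forward and backward path entropies, averaged over leaf-removal from both
  ends; +1 is pyramidal, −1 inverted.

## Worked example

```r
library(facilinet)

# synthetic study system: 32 taxa monitored daily for 110 days, with a
# regime shift at day 18, and a 32-species cross-feeding community with
# two planted dependency loops
series <- simulate_timeseries(seed = 1)
community <- simulate_exchange_community(n_species = 32, n_metabolites = 80,
                                         medium_size = 10,
                                         crossfeed_density = 0.4,
                                         loop_count = 2, seed = 1)

# when did the community turn over?
shift <- abruptness(series, window = 5)
shift[which.max(shift$abruptness), ]
#> # A tibble: 1 × 2
#>       t abruptness
#>   <int>      <dbl>
#> 1    17      0.904

# full pipeline at six time points: 10 seeded coupling runs, networks on
# the species detected above 1% abundance, hierarchy and centrality per day
cfg <- pipeline_config(n_runs = 10, base_seed = 1, mode = "montecarlo",
                       n_samples = 400, min_abundance = 0.01)
res <- run_pipeline(series, community, cfg,
                    days = c(1L, 10L, 20L, 40L, 80L, 110L))

res$hierarchy[, c("day", "n_nodes", "treeness", "feedforwardness", "orderability")]
#> # A tibble: 6 × 5
#>     day n_nodes treeness feedforwardness orderability
#>   <int>   <dbl>    <dbl>           <dbl>        <dbl>
#> 1     1      18   0.0368           1             1
#> 2    10      18   0.0368           1             1
#> 3    20       7   0.6              1             1
#> 4    40       8   1                0.944         0.75
#> 5    80       7   0.6              1             1
#> 6   110       8   0.6              0.905         0.75
```

The abruptness series peaks at the boundary just before the planted shift
(`t = 17`, windows days 13–17 vs 18–22) with a value of 0.90 — more than
90% of the composition turned over. The number of detected nodes collapses
from 18 to 7–8 after the shift. Orderability below 1 (days 40 and 110)
flags feedback loops among the detected species; on those days two of the
network's edges form a mutual-dependency cycle.

```r
head(as.data.frame(keystone_ranking(res$centrality))[, 1:3], 3)
#>   species influence_mean influence_sd
#> 1   sp_01      0.6563959   0.05693009
#> 2   sp_06      0.4117647   0.00000000
#> 3   sp_07      0.3529412   0.00000000

res$scores[, c("day", "n_detected", "mip", "mro")]
#>   day n_detected mip        mro
#> 1   1         18  15 0.04901961
#> 2  10         18  15 0.04901961
#> 3  20          7   3 0.04761905
#> 4  40          8   4 0.01785714
#> 5  80          7   3 0.04761905
#> 6 110          8   4 0.03571429
```

`sp_01` — the generator's medium-fed source species, on which every
cross-fed chain ultimately depends — tops the influence ranking on every
day, despite carrying no special abundance: the keystone signature. The
community-level MIP drops from 15 to 3–4 when the community collapses to
its quasi-stable phase: fewer detected species leave far less to gain from
exchange.

Every result type has `tidy()`/`glance()` methods and `autoplot()` /
`plot_hierarchy_series()` figures. A thin command-line wrapper with
subcommands (`simulate-ts`, `simulate-community`, `abruptness`, `exchange`,
`network`, `hierarchy`, `centrality`, `run-all`) is installed at
`system.file("cli/facilinet.R", package = "facilinet")`.

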