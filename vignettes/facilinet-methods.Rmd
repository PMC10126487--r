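---
title: "Methods: inferring facilitative interaction networks from community time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring facilitative interaction networks from community time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facilinet)
```

`facilinet` studies how the architecture of facilitative (cross-feeding)
interactions in a microbial community changes through time, and whether
positive feedback loops — mutual metabolic dependencies — precede abrupt
community shifts. This vignette documents the models and procedures, the
parameters that matter, the numerical conventions, and the choices made
where the design was genuinely open.

## 1. Turnover: relative abundances and the abruptness index

The community is a species-by-day abundance table. Because per-day totals
reflect sequencing depth or coverage rather than biology, every column is
first normalized to relative abundances; `relative_abundance()` errors on
an all-zero day (naming it) rather than producing `NaN`s.

The *abruptness* at time $t$ with window width $w$ compares the average
composition of the trailing window (samples $t-w+1,\dots,t$) with the
leading window ($t+1,\dots,t+w$) by Bray-Curtis dissimilarity

$$ BC(u, v) = \frac{\sum_i |u_i - v_i|}{\sum_i (u_i + v_i)}. $$

On compositions (each summing to 1) this equals half the L1 distance, so
$a_t > 0.5$ means more than half the community turned over between windows.
The default $w = 5$ matches daily sampling with 5-day windows; the index is
defined for $w \le t \le n_{\text{days}} - w$, and the two windows are
inclusive, consecutive and non-overlapping.

Two conventions were open and are fixed as follows:

* **Normalize before averaging.** Window means are taken over per-day
  *compositions*, not raw counts, so no single deep-coverage day dominates
  its window. This makes the index invariant to rescaling any one day's
  column, which is asserted by a property test. Raw-scale averaging is
  available via `normalize = FALSE`.
* **Irregular sampling.** With gaps in the day labels, windows are built
  over available consecutive samples by default; `contiguous = TRUE`
  restricts to time points whose both windows span calendar-consecutive
  days. The default suits sparse metagenome series (e.g. 13 time points
  over 110 days), the strict flag suits dense amplicon series.

## 2. The set-based cross-feeding model

Genome-scale flux models are replaced by a deliberately boolean
abstraction. A community model is a medium $E$ (freely available
metabolites) and, per species $s$, a requirement set $Req_s$ and a
secretion set $Sec_s$. A species grows when *all* of $Req_s$ is available;
growing species secrete *all* of $Sec_s$; there is no stoichiometry, no
flux magnitude, and secretion is unconditional on anything but growth.
`growth_closure()` computes the least fixed point: start from the medium,
repeatedly grant growth to any member whose requirements are available and
add its secretions, stop at stability. The fixed point is unique, so the
result is order-independent, and it is monotone in both the member set and
the medium (property-tested).

The payoff of the boolean model is that every derived quantity is exactly
enumerable and brute-force verifiable at desk scale. All outputs are
set-based analogs of their flux-based counterparts and are labelled as
such; they capture the *topology* of who can feed whom, not exchange
rates.

**Species coupling score.** The directional dependency of recipient $r$ on
donor $d$ is the fraction, over sub-communities $S$ containing both in
which $r$ grows, of those where $r$ fails to grow in $S \setminus \{d\}$.
The conditioning set — "$r$ and $d$ both present and $r$ grows" — was not
fully pinned down by the flux-based original; this definition is fixed here
and documented. An empty conditioning set yields 0 with a warning. Scores
are exactly 1 for a unique producer of a required non-medium metabolite and
exactly 0 for a recipient fully covered by the medium (both are invariants
in the test suite). Enumeration is exhaustive up to `exhaustive_limit = 12`
species ($2^{12}$ subsets via a shared growth table, so the full
donor-by-recipient matrix costs $2^n$ closures, not $n^2 2^n$). Beyond
that, Monte-Carlo sampling draws sub-communities uniformly (each other
species present with probability 1/2):

* `species_coupling_score()` samples per pair, conditioning on the pair's
  presence directly;
* `coupling_run()` draws one shared pool of `n_samples` subsets per run and
  scores *every* ordered pair from the subsets containing it. Conditioned
  on containing a given pair, a uniform subset is uniform among those
  containing the pair, so the estimator is the same, with roughly
  `n_samples / 4` effective draws per pair at a cost of $|S| + 1$ closures
  per subset instead of $2 \cdot n_{\text{samples}}$ closures per pair.

Monte-Carlo estimates are unbiased for the exhaustive value; the tests
check agreement within three standard errors across seeds and convergence
at large sample counts on a 6-species instance.

**Transfer attribution.** For growing donor $b$ and growing recipient $a$,
every metabolite in $Sec_b \cap Req_a$ not supplied by the medium yields one
$(b, a, m)$ record. Per-metabolite frequencies count distinct donor-recipient
pairs; standardized frequencies divide by the grand total and sum to one per
time point, the form used to compare transfer profiles across days.

**MIP and MRO.** The metabolic interaction potential is
$|\bigcup_s Req_s| - \min\{|E'| : \text{all species grow under } E'\}$ —
how many external metabolites exchange lets the community do without.
Candidate media are subsets of the requirement union (nothing else can
help), searched exactly by increasing size while the union has at most
`exact_limit = 20` members; beyond that a greedy irreducible medium is
used, which can only *under*-estimate MIP, and the result is flagged
`greedy_lower_bound` rather than silently reported as exact. The metabolic
resource overlap is the mean over unordered species pairs of
$|Req_a \cap Req_b| / \min(|Req_a|, |Req_b|)$; pairs with an empty smaller
set are skipped, and `union` (Jaccard) and `mean` denominators are
available, with the variant recorded in the output.

**Replicates.** `replicate_runs()` performs `n_runs = 10` coupling runs
whose seeds are `base_seed + 0 .. n_runs - 1`, and reports per-edge and
per-score means and standard deviations. In exhaustive mode all runs are
identical and SDs are exactly zero — the bookkeeping then simply documents
reproducibility, mirroring the replicate-run convention of seeded
flux-sampling tools.

## 3. Networks, hierarchy, and keystones

`build_network()` keeps a donor → recipient edge when the mean coupling
score across runs exceeds $\tau$ and both endpoints are among the species
detected that day (`detect_nodes()`: abundance at least $\theta$, default
presence). The original analyses state no cutoff, so $\tau = 0$ — any
positive mean score — is the documented default and a required, visible
config value. Arrows follow metabolite flow. Edges are loop-flagged when
their endpoints share a strongly connected component of size $\ge 2$ (or
are self-loops); the loop set is empty exactly when orderability is 1,
which is asserted as a cross-module property test.

On the SCC condensation (DAG of components, each weighted by its size
$\alpha$):

* **Orderability** $O$ = fraction of nodes in acyclic singleton SCCs —
  1 without loops, 0 when one loop swallows everyone. Self-loops count as
  cyclic but are dropped from the condensation's edges. Isolated nodes are
  acyclic singletons and enter the denominator.
* **Path entropies.** $h(v) = 0$ at sinks, otherwise
  $h(v) = \log_2 k_{out}(v) + \frac{1}{k_{out}(v)} \sum_{u} h(u)$: the
  uncertainty (bits) of a downstream path under uniform branching. $H_f$
  averages $h$ over maximal (in-degree-0) nodes; $H_b$ is the same on the
  reversed DAG. Base 2 is cosmetic — the ratio below is base-independent.
* **Treeness** $T$ averages $f(g) = (H_f - H_b) / \max(H_f, H_b)$ (0 when
  both entropies vanish, avoiding 0/0 on chains and single nodes) over a
  leaf-removal schedule starting from the condensation $g_0$. The schedule
  was genuinely open. Removing only minimal nodes turned out, under
  numerical probing on hundreds of random digraphs, to violate the
  antisymmetry $T(G^{rev}) = -T(G)$ that the index is meant to have (a
  pyramid must be the exact negative of its inversion). The default
  therefore follows the entropy-based hierarchy-index methodology of
  averaging over removal from *both* ends: $g_0$, the sequence deleting
  out-degree-0 nodes, and the sequence deleting in-degree-0 nodes, each
  stopping at an empty or edgeless graph. This is exactly antisymmetric
  (property-tested); the one-sided schedule remains available as
  `prune = "minimal"`.
* **Feedforwardness** $F$ = mean over all maximal-to-minimal condensation
  paths of $|\pi| / \sum_{v \in \pi} \alpha(v)$. On a DAG every ratio is 1;
  large cycles on a path shrink it. Isolated condensation nodes contribute
  their trivial one-node path, so a single-SCC graph of $n$ nodes scores
  $1/n$. Path enumeration aborts with an explicit error beyond `max_paths`
  (default $10^5$) rather than silently sampling.

**Centrality.** Influence is unweighted local reaching centrality,
$I(v) = |\{u \ne v: v \leadsto u\}| / (N - 1)$ — "influence" measures vary
across the directed-network literature, so the default here is the
simplest reachability-based, weight-blind variant (a documented
limitation), with the implementation isolated so alternatives can be
swapped in. PageRank uses
the standard damping $d = 0.85$, uniform teleport and uniform dangling-node
redistribution, iterated until the L1 change is below `tol = 1e-10` (error
with diagnostics at `max_iter`); edge weights can optionally serve as
transition probabilities but default to off, mirroring the unweighted
ranking question. Convergence is initialization-independent to within
$10 \cdot tol$, and the implementation is cross-checked against an
independent linear solve and igraph in the tests. `keystone_ranking()`
aggregates per-day, per-run reports into per-species means, SDs and ranks.

## 4. The synthetic generators

`simulate_timeseries()` builds a deterministic skeleton — total mass 1 per
day, geometric rank-abundances (ratio 0.85, keeping the long tail above
realistic detection thresholds) — and multiplies every cell by log-normal
noise (`noise_scale` on the log scale; 0 recovers the skeleton exactly).
The regime shift is instantaneous: at `shift_day` a fraction
`shift_magnitude` of total abundance moves to a disjoint survivor set of
size `quasi_stable_richness`. An optional `recovery_day` staggers the
displaced species' return, each ramping linearly, so richness rises again
late in the series. Defaults (32 species, 110 daily samples, shift at day
18, magnitude 0.9, noise 0.2, 4 survivors) emulate a 110-day pond-water
co-culture with a rapid compositional shift near day 18 and a quasi-stable
low-diversity phase; the shift magnitude is not quantified by the source
system and is a free parameter. What the generator deliberately does *not*
emulate: mechanistic population dynamics (no Lotka-Volterra), compositional
count noise from sequencing, taxon correlations, or gradual shifts — so a
passing recovery test shows the *index* behaves correctly, not that real
communities shift instantaneously.

`simulate_exchange_community()` builds a toy cross-feeding community around
one medium-fed source species. Each requirement slot of a downstream
species is, with probability `crossfeed_density`, a fresh metabolite
secreted by exactly one lower-indexed donor (otherwise a medium
metabolite), so the random part of the designed dependency digraph is
acyclic and every species grows in the full community by construction —
verified by `growth_closure()` at generation time. Dependency loops are
planted explicitly as mutual two-species cycles over dedicated metabolites.
Each loop metabolite gets a *backup producer*: the source for one
direction and, when the community is large enough
($n \ge 2 \cdot \text{loop\_count} + 2$), a reserved second medium-growing
helper for the other. This detail matters: with a single shared backup,
removal of a loop partner can never be decisive while the backup is
present, and both loop directions would carry coupling score exactly 0 —
planted loops would be invisible in score-built networks. With two distinct
helpers, sub-communities exist in which either partner is the other's sole
provider, so both loop edges provably carry positive scores and surface as
red (loop-flagged) edges. At the minimal size ($n = 2 \cdot
\text{loop\_count} + 1$) the single-helper fallback still plants the cycle
in the *designed* digraph, where SCC analysis detects it. In all cases the
designed digraph contains exactly the planted cycles and nothing else.

Both generators route all randomness through one seeded generator per call
(the caller's RNG state is untouched), and identical arguments plus seed
give bit-identical output.

## 5. Pipeline, degenerate inputs and problem sizes

`run_pipeline()` computes coupling once on the full model and restricts
per-day analyses to the detected species: network, hierarchy report,
centrality, MIP/MRO of the detected sub-community, and transfer tables
(raw and standardized). Days with fewer than two detected species are
skipped with a structured record, not an error — single-species days are
expected in quasi-stable phases. Outputs are TSV for tables and JSON for
the manifest, which names the package version, seeds, full configuration
and its MD5 hash; re-running a fixed configuration reproduces every file
byte-identically (tested).

Numerical conventions worth knowing: Bray-Curtis on two all-zero vectors is
an error, not 0; coupling scores with an empty conditioning set are 0 with
a warning; the MIP search refuses infeasible communities; PageRank refuses
to return an unconverged vector; `feedforwardness()` refuses to subsample
silently. Ties in keystone ranks use the `min` convention.

The test suite runs at desk scale by design: exhaustive digraph oracles
cover all 64 digraphs on 3 nodes plus dozens of sampled 4–5-node digraphs;
coupling oracles enumerate all sub-communities of 4–6-species models;
Monte-Carlo checks use $10^2$–$10^4$ samples on a 6-species instance;
planted-shift recovery uses 20 seeds of the full 32 × 110 series. These
sizes keep every expected value independently recomputable by brute force.

## 6. Known limitations

* The boolean growth model ignores stoichiometry, flux magnitudes, uptake
  competition and conditional secretion; coupling scores are topological
  dependencies, not exchange rates.
* Influence centrality ignores edge weights entirely.
* MIP beyond 20 candidate metabolites is a greedy lower bound (flagged).
* The exhaustive coupling path scales as $2^n$; larger communities rely on
  the Monte-Carlo estimator, whose per-pair precision falls with community
  size (effective draws ≈ `n_samples` / 4).
* Node "detection" is a plain abundance threshold; assembly-quality
  filtering of genomes is upstream of this package.
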