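---
title: "Ancestral range reconstruction and sliding-window biogeographic rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral range reconstruction and sliding-window biogeographic rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`rangeburst` reconstructs ancestral geographic ranges on a fossil-calibrated
ultrametric phylogeny (a *chronogram*, branch lengths in Myr) from a coding
of each species into one or more of up to ten single-letter areas.  The
reconstruction treats presence/absence in each area as an independent binary
character evolving under a two-state F81 model: with stationary presence
frequency $\pi_1$ (and $\pi_0 = 1 - \pi_1$), the transition probability over
a branch of duration $t$ with rate multiplier $r$ is

$$P_{ij}(t) = \pi_j + (\delta_{ij} - \pi_j)\,e^{-\beta r t},
\qquad \beta = \frac{1}{2\pi_0\pi_1},$$

so that one change per Myr is expected at stationarity per unit multiplier.
Rate variation **among areas** is the "+G" part: a discrete gamma mixture
with shape $\alpha$ and $k = 4$ equal-probability categories, discretized by
the mean of each quantile slice (the dominant convention; the closed form
uses the regularized incomplete gamma so the multipliers average exactly 1).

The per-area likelihood is Felsenstein pruning with the root weighted by the
stationary distribution and the categories averaged with equal weights.  The
full data likelihood is the product over areas, sharing one $(\pi_1,
\alpha)$.  Inference is Metropolis–Hastings:

* priors: $\pi_1 \sim \mathrm{Uniform}(0,1)$, $\alpha \sim
  \mathrm{Exponential}(1)$ — weakly informative, standard;
* proposals: a reflected sliding window (half-width 0.1) for $\pi_1$ and a
  log-scale multiplier for $\alpha$ (Hastings ratio $\alpha'/\alpha$);
* by default ten chains of 100,000 generations, a 20,000-generation burn-in
  and thinning every 100, started from dispersed prior draws and pooled
  after burn-in (8,000 samples).  One master seed spawns per-chain
  substreams, so a run is bit-reproducible.

Per-node presence posteriors are Rao-Blackwellized: the marginal ancestral
state probability (an up–down pass re-using the pruning quantities, mixing
categories by their data likelihood) is averaged over the pooled parameter
samples.  Presence probabilities are composed into **range** posteriors
under independence, truncated at `max_areas` (default 3): a candidate range
$S$ receives weight $\prod_{a \in S} p_a \prod_{a \notin S} (1-p_a)$,
renormalized over non-empty sets with $|S| \le$ `max_areas`.  If every
allowed weight is zero (all presence probabilities equal to 1 for more areas
than allowed), the single best area is used.  The MAP range breaks ties by
higher probability, then smaller cardinality, then alphabet order, so output
is deterministic.  This "per-area marginals, multiplicative composition"
definition of the Bayesian Binary reconstruction is the package's own: the
original tooling in this tradition does not document whether joint ranges
are sampled directly, so we chose the variant that is exactly testable
against enumeration.  Tips are observed: their assigned range is their
coded set, even when it exceeds `max_areas`.

# Event statistics

Given one range per node (MAP ranges, or the simulator's truth):

* a **transition** is a branch whose parent and child ranges differ in any
  way, including pure expansions (`D` → `D|E`); multi-area ranges are
  composite states.  The event is dated at the branch midpoint — unbiased
  under a uniform prior on where the change happened, with error bounded by
  half the branch length.  Child-node dating was considered and rejected as
  the default because it is systematically young-biased; the midpoint error
  matters for sharp rate features (see the generator section).
* every internal node is an **origination** (one new lineage per split);
  it is *in situ* when the node and both daughters share one range.

Rates use non-overlapping windows of width 0.1 Myr (100,000 years) stepping
from an old edge `t_max` toward the present.  The window opening at
$t_{old}$ covers $(t_{old} - w,\ t_{old}]$ and its value is the event count
divided by the number of lineages at $t_{old}$ ("per branch at the start of
the time frame") and by $w$ — events per lineage per Myr.  Lineages are
counted with the half-open branch convention (a branch occupies
$(\mathrm{age}_{parent}, \mathrm{age}_{child}]$), so every node-age boundary
is counted exactly once.  One deliberate special case: the window whose old
edge coincides with the crown age is normalized by the two crown lineages.
The crown split itself opens the record, and without this convention the
first window would have a zero normalizer and be dropped, silently losing
the root origination and shortening period averages by one window.

Period averages are the arithmetic mean of the window values whose old
edges fall inside the period (a window straddling the boundary belongs to
the period iff its old edge does); a pooled estimator — total events over
total lineage-time — is available behind a flag and is much less sensitive
to high-variance windows where few lineages exist.  For plotting, each
event can instead contribute a triangular cone of base 0.2 Myr (twice the
window) integrating to one over the lineage count at the event time, so the
area under the curve preserves per-lineage event counts.  Lineage-through-
time curves step at node ages, start at 2 at the clade origin and support
clade restriction (via the MRCA of named tips) and young truncation.

# The synthetic-data generator

The generator provides ground truth for everything above.  Trees come from
a forward Gillespie birth–death process started at the two crown lineages.
Two conditioning modes exist: a target tip count $n$ (the simulation stops
at the instant the $(n{+}1)$-th birth would occur, so the sojourn at $n$
lineages is complete and a pure-birth crown age has mean
$\sum_{k=2}^{n} 1/(kb)$ — the closed form the tests check), or a fixed
crown age with survival of both crown sides enforced.  Extinct lineages are
pruned and single-child nodes spliced.

Range histories are simulated event by event along each branch (so the
truth carries exact event times, not just endpoints): area $a$ is gained at
rate $g_a \times$ the epoch dispersal multiplier while the range is below
`max_areas`, and lost at rate $\ell_a$ while the range has more than one
area — the last loss is forbidden, which keeps ranges non-empty without
rejection-resampling.  With `max_areas = 1` gains act as direct switches so
the single-area process still moves.  Epochs are non-overlapping age
intervals; rates are piecewise constant and the Gillespie clock is restarted
at epoch boundaries (memorylessness makes this exact).

The default profile emulates a ten-area, crown-age-10.5-Myr radiation of
roughly 200 extant species with two coupled bursts, in the epochs 6.6–5.8
and 4.7–3.1 mya:

| parameter | default | units | why |
|---|---|---|---|
| birth / death | 0.316 / 0.1 | per lineage per Myr | ~190–220 extant tips at crown age 10.5 |
| per-area gain | 0.002 | per Myr | near-zero baseline dispersal between bursts |
| per-area loss | 0.015 | per Myr | ranges of 1–3 areas (occupancy odds ≈ 0.13) |
| dispersal multiplier | 30 / 60 | — | burst-versus-lull transition contrast of the order seen in continental radiations |
| speciation multiplier | 6 / 3 | — | the bursts are radiations: short branches inside the epochs |
| max areas | 3 | — | matches the reconstruction constraint |

The speciation multipliers matter for a subtle reason.  Transition events
are dated at branch midpoints; on a constant-rate tree of this size the
branches crossing a 0.8–1.6 Myr epoch are themselves ~2 Myr long, and about
half of the burst events get dated outside the burst — enough smearing that
a dispersal-only burst is unrecoverable at high confidence no matter how
strong the multiplier (with exact event times the bursts are always
recovered; the loss is entirely the dating error).  Making the bursts
radiations as well — which is what the motivating scenario describes —
concentrates nodes inside the epochs, shortens the event-bearing branches
and keeps midpoints where the events happened.  The second burst carries
the larger dispersal multiplier because so few lineages exist during the
first burst (~5–8) that its window rates are noise-dominated either way.
With this profile the pooled in-burst transition rate exceeds the flanking
rate in ≈95% of replicates; the residual failures are the midpoint-dating
floor, not generator noise.

What the generator does **not** emulate: phylogenetic error (the tree is
known exactly), founder-event speciation and state-dependent
diversification, area-specific asymmetries in gain/loss (supported but not
defaulted), fossil tips, and any spatial adjacency structure between areas.
Passing tests on synthetic data therefore validate the estimators under the
model's own assumptions, not the biological fidelity of any particular
empirical reconstruction.

# Numerical choices

* Ultrametricity tolerance: max |tip age| ≤ 1e-6 × root age — absorbs float
  noise from upstream dating tools without masking real errors; tips are
  then snapped to age 0.  Polytomies and singleton nodes are rejected, since
  the origination statistics assume one new lineage per node.
* Pruning partials are rescaled per edge with a multiplicative accumulator
  folded into a log only near underflow; a gamma category in which the data
  are impossible (rate multipliers underflow to 0 at tiny $\alpha$)
  receives zero posterior weight rather than propagating NaN.
* Window membership uses a 1e-9 fuzz when binning event times so an event
  on a window edge lands in exactly one window (the older one), keeping the
  conservation identity — sum of rate × width × lineages equals the event
  count — exact.
* MAP ties and the all-weights-zero fallback are deterministic by the
  alphabet order; area relabeling permutes all outputs consistently.
* Proposal scales (0.1 sliding window, log-multiplier 1.0) give acceptance
  rates around 0.2–0.7 across the test problems; they are configuration
  fields, not constants.

# Problem sizes

The test suite and the acceptance script scale the analyses to: oracle
comparisons on trees of 3–6 tips against exhaustive enumeration (1e-10),
parameter recovery on twenty 100-tip datasets with 20,000-generation
two-chain runs, MAP-range accuracy on five slow-evolution datasets,
burst detection on fifty default-profile fixtures, and one full pipeline
run on a default fixture.  These sizes were chosen to exercise every code
path at meaningful statistical resolution; the defaults of
`bbm_config()` reproduce the full ten-chain protocol when you have a real
dataset in hand.

# Known limitations

* The BBM definition here composes per-area marginals; it does not sample
  joint ancestral ranges, so range posteriors at adjacent nodes are not
  draws from one joint history.
* No missing or ambiguous tip states: every species must be coded.
* Transition dating inherits up to half a branch of error; rate features
  narrower than typical branch lengths blur accordingly (this is intrinsic
  to endpoint-based reconstructions, not to this implementation).
* The sampler updates two scalars; for very large area sets with strong
  rate heterogeneity a per-area rate model would mix better but would no
  longer be the classic shared-parameter analysis.
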