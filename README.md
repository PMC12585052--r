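# rangeburst

Ancestral geographic-range reconstruction and sliding-window biogeographic
rates for time-calibrated phylogenies.

Historical biogeographers studying continental radiations — for example a
rodent clade spreading across South America after an intercontinental
invasion — want to know *where* ancestral lineages lived, *when* lineages
moved between regions, and whether movement and lineage origination came in
bursts tied to climatic or geologic events.  `rangeburst` implements that
workflow end to end for species coded into up to ten discrete areas on an
ultrametric chronogram (branch lengths in Myr):

1. **Bayesian Binary MCMC (BBM) reconstruction.**  Presence/absence in each
   area is a binary character under a two-state F81 model,
   `P_ij(t) = pi_j + (delta_ij - pi_j) exp(-beta r t)` with
   `beta = 1/(2 pi0 pi1)`, plus discrete-gamma rate variation among areas
   (shape `alpha`, k = 4).  Metropolis–Hastings samples `(pi1, alpha)`
   across independent chains (default: ten chains, 100,000 generations,
   20,000 burn-in, sampled every 100); per-node presence posteriors are
   Rao-Blackwellized marginals, composed into range posteriors truncated at
   three areas, and summarized as MAP ranges with deterministic tie-breaks.
2. **Events and rates.**  Branches whose endpoint ranges differ become dated
   transition events (branch midpoint); every split is an origination,
   flagged *in situ* when parent and daughters share a range.  Rates are
   events per lineage per Myr in contiguous 0.1-Myr windows, normalized by
   the lineage count at each window's old edge, with period averages,
   triangular-cone plot series (0.2-Myr base) and lineage-through-time
   curves.
3. **A ground-truth simulator.**  Forward Gillespie birth–death trees plus
   per-area gain/loss range evolution with exact event times, including a
   reference two-burst profile (epoch-specific dispersal and speciation
   multipliers in the 6.6–5.8 and 4.7–3.1 mya windows) used for
   calibration and burst-detection checks.

The methods vignette (`vignettes/range-reconstruction.Rmd`) documents the
model, every tunable parameter, and the design decisions.

## Worked example

Simulate a 60-tip radiation with known history, reconstruct it, and measure
transition rates:

```r
library(rangeburst)

cfg   <- sim_config(n_tips = 60, crown_age = 10, seed = 7,
                    gain = 0.01, loss = 0.08, epochs = NULL)
chron <- simulate_bd_tree(cfg)
sim   <- simulate_range_evolution(chron, cfg)

res <- run_bbm_mcmc(chron, sim$coding,
                    bbm_config(generations = 5000, burnin = 1000,
                               samplefreq = 20, chains = 2, seed = 7))
res
#> Bayesian Binary MCMC reconstruction
#>   pooled samples: 400 from 2 chains
#>   posterior mean pi1  = 0.1654
#>   posterior mean alpha = 0.1216

ids <- chron$node_ids[(chron$n_tips + 1):length(chron$node_ids)]
mean(res$map_ranges[ids] == sim$truth$node_ranges[ids])
#> [1] 0.9661017    # MAP ranges recover 96.6% of the true node ranges

events <- extract_events(chron, res$map_ranges)
s <- sliding_window_rates(events, chron, "transition", width = 0.1)
period_mean_rate(s, 8, 0)
#> [1] 0.1524995    # transitions per lineage per Myr, averaged over 8-0 mya

head(events[events$kind == "transition", c("time", "node", "from", "to")], 3)
#>       time node from  to
#> 3 7.395430  N63    E B|E
#> 6 5.836435  N77    E E|I
#> 7 4.799644  N64  B|E   B
```

The posterior mean `pi1` ≈ 0.17 reflects that each species occupies few of
the ten areas; `alpha` ≈ 0.12 indicates strong rate heterogeneity among
areas (most areas change slowly, a few fast).  Transitions come out dated
and directed (`E -> B|E` is an expansion, `B|E -> B` a contraction), ready
for window rates, period summaries and cone plots.

For file-based runs there is a four-subcommand CLI over the same functions
(`inst/scripts/rangeburst-pipeline.R`: `simulate`, `reconstruct`, `rates`,
`ltt`) driven by a YAML config; `reconstruct` writes the range-posterior
table, an annotated newick with per-node MAP ranges, the MCMC trace and a
log, and `rates` turns an annotated tree into event, rate, period-summary
and LTT tables.

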