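test_that("config invariants are enforced", {
  expect_error(sim_config(birth = 0.5, death = 0.5), "birth > death")
  expect_error(sim_config(birth = 0.5, death = 0.8), "birth > death")
  expect_error(sim_config(gain = 0), "> 0")
  expect_error(sim_config(epochs = data.frame(old = c(5, 4.5),
                                              young = c(4, 3),
                                              multiplier = c(2, 2))),
               "overlap")
  expect_error(sim_config(n_tips = NULL, crown_age = NULL), "target")
})

test_that("birth-death trees are reproducible, ultrametric and on target", {
  cfg <- sim_config(birth = 1, death = 0, n_tips = 12, crown_age = NULL,
                    seed = 31, epochs = NULL)
  t1 <- simulate_bd_tree(cfg)
  t2 <- simulate_bd_tree(cfg)
  expect_identical(write_chronogram(t1), write_chronogram(t2))
  expect_equal(t1$n_tips, 12)
  # with both targets the depth is standardized to the crown age
  cfg2 <- sim_config(n_tips = 40, crown_age = 10.5, seed = 32, epochs = NULL)
  t3 <- simulate_bd_tree(cfg2)
  expect_equal(t3$n_tips, 40)
  expect_equal(t3$root_age, 10.5, tolerance = 1e-9)
  # crown-age-only conditioning
  cfg3 <- sim_config(birth = 0.9, death = 0.1, n_tips = NULL, crown_age = 6,
                     seed = 33, epochs = NULL)
  t4 <- simulate_bd_tree(cfg3)
  expect_equal(t4$root_age, 6, tolerance = 1e-6)
  expect_gte(t4$n_tips, 2)
})

test_that("pure-birth crown ages match the waiting-time sum", {
  # E[crown age] = sum_{k=2}^{n} 1/(k b): the simulator stops at the moment
  # the (n+1)th birth would occur, so the sojourn at n lineages is complete
  b <- 1
  n <- 40
  ages <- vapply(1:500, function(i)
    simulate_bd_tree(sim_config(birth = b, death = 0, n_tips = n,
                                crown_age = NULL, seed = 6000 + i,
                                epochs = NULL))$root_age,
    numeric(1))
  expected <- sum(1 / (b * (2:n)))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - expected), 3 * se + 1e-12)
})

test_that("a frozen gain process inherits the root range everywhere", {
  cfg <- sim_config(n_tips = 25, crown_age = 8, seed = 41, gain = 1e-12,
                    loss = 0.2, epochs = NULL)
  # gain must be > 0 by config contract; 1e-12 over ~100 lineage-Myr is
  # effectively frozen
  ch <- simulate_bd_tree(cfg)
  sim <- simulate_range_evolution(ch, cfg)
  expect_equal(nrow(sim$truth$events), 0)
  expect_equal(length(unique(sim$truth$node_ranges)), 1L)
  expect_equal(nchar(unique(sim$truth$node_ranges)), 1L)
})

test_that("ranges stay non-empty and within max_areas; events lie on branches", {
  set.seed(414)
  for (i in 1:5) {
    cfg <- sim_config(n_tips = 40, crown_age = 9, seed = 700 + i,
                      gain = 0.08, loss = 0.15, max_areas = 3, epochs = NULL)
    ch <- simulate_bd_tree(cfg)
    sim <- simulate_range_evolution(ch, cfg)
    sizes <- lengths(strsplit(unname(sim$truth$node_ranges), "|",
                              fixed = TRUE))
    expect_true(all(sizes >= 1 & sizes <= 3))
    expect_true(all(lengths(sim$coding) >= 1))
    ev <- sim$truth$events
    if (nrow(ev)) {
      idx <- match(ev$branch, ch$node_ids)
      parent <- ch$phylo$edge[match(idx, ch$phylo$edge[, 2]), 1]
      expect_true(all(ev$time > ch$ages[idx] - 1e-12))
      expect_true(all(ev$time < ch$ages[parent] + 1e-12))
    }
  }
})

test_that("gain-event counts match the Poisson exposure expectation", {
  # single permissive regime: count gains against gain rate x open time
  cfg0 <- sim_config(n_tips = 30, crown_age = 6, seed = 1, gain = 0.04,
                     loss = 0.3, max_areas = 3, epochs = NULL)
  nrep <- 200
  gains <- numeric(nrep)
  exposure <- numeric(nrep)
  for (i in seq_len(nrep)) {
    cfg <- sim_config(n_tips = 30, crown_age = 6, seed = 8000 + i,
                      gain = 0.04, loss = 0.3, max_areas = 3, epochs = NULL)
    ch <- simulate_bd_tree(cfg)
    sim <- simulate_range_evolution(ch, cfg)
    ev <- sim$truth$events
    gains[i] <- sum(ev$kind == "gain")
    # open exposure: per branch segment, (areas not held) x duration while
    # below max_areas; reconstruct from the event history exactly
    exposure[i] <- local({
      phy <- ch$phylo
      tot <- 0
      for (r in seq_len(nrow(phy$edge))) {
        child <- ch$node_ids[phy$edge[r, 2]]
        t_hi <- ch$ages[phy$edge[r, 1]]
        t_lo <- ch$ages[phy$edge[r, 2]]
        bev <- ev[ev$branch == child, , drop = FALSE]
        bev <- bev[order(-bev$time), , drop = FALSE]
        parent_key <- sim$truth$node_ranges[ch$node_ids[phy$edge[r, 1]]]
        S <- range_letters(parent_key)
        times <- c(t_hi, bev$time, t_lo)
        for (seg in seq_len(length(times) - 1)) {
          if (length(S) < 3) tot <- tot + (10 - length(S)) *
              (times[seg] - times[seg + 1])
          if (seg <= nrow(bev)) S <- range_letters(bev$to[seg])
        }
      }
      tot
    })
  }
  expected <- 0.04 * mean(exposure)
  se <- sd(gains) / sqrt(nrep)
  expect_lt(abs(mean(gains) - expected), 3 * se + 1e-9)
})

test_that("fixtures round-trip through the readers and are byte-stable", {
  d1 <- tempfile(); d2 <- tempfile()
  # the default two-burst profile
  cfg <- sim_config(seed = 51)
  fx1 <- make_fixture(cfg, d1)
  fx2 <- make_fixture(cfg, d2)
  expect_identical(readLines(fx1$paths$truth), readLines(fx2$paths$truth))
  expect_identical(readLines(fx1$paths$tree), readLines(fx2$paths$tree))
  ch <- parse_chronogram(fx1$paths$tree)
  rc <- read_region_codings(fx1$paths$codings, cfg$alphabet)
  expect_silent(validate_tip_match(ch, rc))
  expect_equal(ch$root_age, 10.5, tolerance = 1e-6)
  truth <- jsonlite::read_json(fx1$paths$truth)
  expect_equal(length(truth$node_ranges), length(ch$node_ids))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("F81+G character simulation respects the stationary frequency", {
  set.seed(415)
  ch <- random_ultrametric(60)
  ch$phylo$edge.length <- ch$phylo$edge.length / ch$root_age * 50
  ch <- as_chronogram(ch$phylo)
  sim <- simulate_area_characters(ch, f81_params(0.25, 1, 4),
                                  area_alphabet(LETTERS[1:10]), seed = 61)
  # long tree: tip states near stationarity, presence frequency near pi1
  expect_lt(abs(mean(sim$tips) - 0.25), 0.08)
  expect_true(all(sim$rates %in% discrete_gamma_rates(1, 4)))
  sim2 <- simulate_area_characters(ch, f81_params(0.25, 1, 4),
                                   area_alphabet(LETTERS[1:10]), seed = 61)
  expect_identical(sim$tips, sim2$tips)
})
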