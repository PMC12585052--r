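test_that("toy reconstruction yields the hand-enumerated events", {
  ch <- toy_chronogram()
  ev <- extract_events(ch, toy_assignment())
  tr <- ev[ev$kind == "transition", ]
  expect_equal(nrow(tr), 1)
  expect_equal(tr$time, 2) # branch midpoint (3 + 1) / 2
  expect_equal(tr$from, "X")
  expect_equal(tr$to, "Y")
  orig <- ev[ev$kind == "origination", ]
  expect_equal(sort(orig$time), c(1, 2, 3))
  expect_equal(orig$in_situ[order(orig$time)], c(TRUE, TRUE, FALSE))
  # sorted old to young
  expect_true(all(diff(ev$time) <= 0))
})

test_that("constant assignments give zero transitions, all in-situ splits", {
  set.seed(410)
  ch <- random_ultrametric(20)
  a <- setNames(rep("Q", length(ch$node_ids)), ch$node_ids)
  ev <- extract_events(ch, a)
  expect_equal(sum(ev$kind == "transition"), 0)
  expect_equal(sum(ev$kind == "origination"), ch$n_tips - 1)
  expect_true(all(ev$in_situ[ev$kind == "origination"]))
  expect_error(extract_events(ch, a[-1]), "missing")
})

test_that("a pure range expansion counts as a transition", {
  ch <- toy_chronogram()
  a <- c(N5 = "D", N6 = "D|E", N7 = "D", A = "D|E", B = "D|E",
         C = "D", D = "D")
  ev <- extract_events(ch, a)
  tr <- ev[ev$kind == "transition", ]
  expect_equal(nrow(tr), 1)
  expect_equal(tr$from, "D")
  expect_equal(tr$to, "D|E")
})

test_that("sliding windows reproduce the hand-computed toy rate", {
  ch <- toy_chronogram()
  ev <- extract_events(ch, toy_assignment())
  s <- sliding_window_rates(ev, ch, "transition", 0.1, 3.0, 0)
  expect_equal(nrow(s), 30)
  w2 <- s[abs(s$window_old_edge - 2.0) < 1e-9, ]
  expect_equal(w2$lineages, 2)
  expect_equal(w2$rate, 5.0) # 1 event / 2 lineages / 0.1 Myr
  expect_equal(sum(s$rate != 0), 1)
  # doubling the width halves the single-event rate
  s2 <- sliding_window_rates(ev, ch, "transition", 0.2, 3.0, 0)
  expect_equal(max(s2$rate), 2.5)
  # no events of a kind -> all-zero series
  none <- ev[0, ]
  s0 <- sliding_window_rates(none, ch, "transition", 0.1, 3.0, 0)
  expect_true(all(s0$rate == 0))
})

test_that("windows opening above the root are dropped with a note", {
  ch <- toy_chronogram()
  ev <- extract_events(ch, toy_assignment())
  expect_message(s <- sliding_window_rates(ev, ch, "transition", 0.1, 3.5, 0),
                 "dropping")
  expect_true(all(s$window_old_edge <= ch$root_age + 1e-9))
})

test_that("period means average window values over old edges in range", {
  ch <- toy_chronogram()
  ev <- extract_events(ch, toy_assignment())
  s <- sliding_window_rates(ev, ch, "transition", 0.1, 3.0, 0)
  expect_equal(period_mean_rate(s, 3.0, 1.0), 5.0 / 20)
  expect_error(period_mean_rate(s, 0.05, 0.01), "no windows")
  # constant series: mean is the constant
  s$rate <- 1.7
  expect_equal(period_mean_rate(s, 2.5, 0.5), 1.7)
})

test_that("event counts are conserved by the window normalization", {
  set.seed(411)
  for (i in 1:5) {
    cfg <- sim_config(n_tips = 40, crown_age = 8, seed = 500 + i,
                      gain = 0.05, loss = 0.2,
                      epochs = NULL)
    ch <- simulate_bd_tree(cfg)
    sim <- simulate_range_evolution(ch, cfg)
    ev <- extract_events(ch, sim$truth$node_ranges)
    for (kd in c("transition", "origination")) {
      s <- sliding_window_rates(ev, ch, kd, 0.1, ch$root_age, 0)
      total <- sum(ev$kind == kd &
                     ev$time > min(s$window_old_edge) - 0.1 - 1e-9)
      expect_equal(sum(s$rate * 0.1 * s$lineages), total, tolerance = 1e-9)
    }
  }
})

test_that("rates are invariant under area relabeling", {
  set.seed(412)
  cfg <- sim_config(n_tips = 30, crown_age = 8, seed = 77, gain = 0.05,
                    loss = 0.2, epochs = NULL)
  ch <- simulate_bd_tree(cfg)
  sim <- simulate_range_evolution(ch, cfg)
  a <- sim$truth$node_ranges
  perm <- setNames(rev(LETTERS[1:10]), LETTERS[1:10])
  a2 <- vapply(a, function(key)
    paste(sort(unname(perm[range_letters(key)])), collapse = "|"), "")
  s1 <- sliding_window_rates(extract_events(ch, a), ch, "transition")
  s2 <- sliding_window_rates(extract_events(ch, a2), ch, "transition")
  expect_equal(s1$rate, s2$rate)
})

test_that("cone kernels have the documented geometry and add linearly", {
  ch <- toy_chronogram()
  ev <- extract_events(ch, toy_assignment())
  cs <- cone_series(ev, ch, "transition", 0.2, 0.001, 3, 0)
  # peak 2 * (1/2) / 0.2 = 5 at the event age, zero outside +/- 0.1
  expect_equal(max(cs$value), 5, tolerance = 1e-6)
  expect_equal(cs$age[which.max(cs$value)], 2, tolerance = 1e-9)
  expect_true(all(cs$value[cs$age > 2.1 | cs$age < 1.9] == 0))
  # duplicated event doubles the series
  ev2 <- rbind(ev, ev[ev$kind == "transition", ])
  cs2 <- cone_series(ev2, ch, "transition", 0.2, 0.001, 3, 0)
  expect_equal(cs2$value, 2 * cs$value, tolerance = 1e-12)
  # no events: identically zero
  cs0 <- cone_series(ev[0, ], ch, "transition", 0.2, 0.01, 3, 0)
  expect_true(all(cs0$value == 0))
})

test_that("cone series integrates to the lineage-weighted event count", {
  set.seed(413)
  cfg <- sim_config(n_tips = 30, crown_age = 8, seed = 88, gain = 0.05,
                    loss = 0.2, epochs = NULL)
  ch <- simulate_bd_tree(cfg)
  sim <- simulate_range_evolution(ch, cfg)
  ev <- extract_events(ch, sim$truth$node_ranges)
  tr <- ev[ev$kind == "transition" & ev$time > 0.2 &
             ev$time < ch$root_age - 0.2, ]
  cs <- cone_series(tr, ch, "transition", 0.2, 0.0005, ch$root_age, 0)
  integral <- sum(cs$value) * 0.0005
  expected <- sum(1 / vapply(tr$time, function(t) lineages_at(ch, t),
                             numeric(1)))
  expect_equal(integral, expected, tolerance = 1e-3)
})

test_that("LTT curves step at node ages and honor clades and cutoffs", {
  ch <- toy_chronogram()
  l <- ltt_curve(ch)
  expect_equal(l$age, c(3, 2, 1))
  expect_equal(l$lineages, c(2, 3, 4))
  cherry <- ltt_curve(ch, mrca_of = c("A", "B"))
  expect_equal(cherry$age, 1)
  expect_equal(cherry$lineages, 2)
  trunc <- ltt_curve(ch, cutoff = 0.5)
  expect_equal(trunc, l, ignore_attr = TRUE)
  trunc2 <- ltt_curve(ch, cutoff = 1.5)
  expect_equal(trunc2$age, c(3, 2))
  expect_error(ltt_curve(ch, mrca_of = c("A", "Zz")), "Zz")
})
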