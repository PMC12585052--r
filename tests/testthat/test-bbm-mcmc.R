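test_that("range composition matches its documented examples", {
  al2 <- area_alphabet(c("D", "E"))
  rp0 <- compose_range_posterior(c(D = 1, E = 0), 3, al2)
  expect_equal(rp0[["D"]], 1)
  expect_true(all(rp0[names(rp0) != "D"] == 0))
  expect_equal(compose_range_posterior(c(D = 0.5, E = 0.5), 2, al2),
               c(D = 1 / 3, E = 1 / 3, "D|E" = 1 / 3), tolerance = 1e-12)
  al3 <- area_alphabet(c("D", "E", "H"))
  rp <- compose_range_posterior(c(D = 0.5, E = 0.5, H = 0.5), 2, al3)
  expect_length(rp, 6)
  expect_equal(unname(rp), rep(1 / 6, 6), tolerance = 1e-12)
  expect_error(compose_range_posterior(numeric(0), 2,
                                       structure(character(0),
                                                 class = "area_alphabet")),
               "empty")
})

test_that("range posteriors sum to one and match subset enumeration", {
  set.seed(406)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    al <- area_alphabet(LETTERS[1:n])
    p <- setNames(runif(n), as.character(al))
    for (ma in 1:3) {
      rp <- compose_range_posterior(p, ma, al)
      expect_equal(sum(rp), 1, tolerance = 1e-9)
      oracle <- enum_range_posterior(p, ma, al)
      expect_equal(rp[sort(names(rp))], oracle[sort(names(oracle))],
                   tolerance = 1e-12)
    }
  }
})

test_that("all-zero weights fall back to the single best area", {
  al <- area_alphabet(c("A", "B", "C", "D"))
  # four certain presences but max_areas 3: every allowed subset has weight 0
  rp <- compose_range_posterior(c(A = 1, B = 1, C = 1, D = 1), 3, al)
  expect_equal(rp, c(A = 1))
})

test_that("MAP range uses probability, then cardinality, then alphabet order", {
  al <- area_alphabet(c("D", "E", "H"))
  expect_equal(map_range(c(D = 0.7, E = 0.3), al), "D")
  expect_equal(map_range(c(D = 0.5, E = 0.5), al), "D")
  expect_equal(map_range(c("D|E" = 0.4, D = 0.4, H = 0.2), al), "D")
  # cardinality breaks the E vs D|E tie; D loses on probability
  expect_equal(map_range(c("E" = 0.4, "D|E" = 0.4, "D" = 0.39), al), "E")
  # scaling the posterior does not change the argmax
  expect_equal(map_range(10 * c("D|E" = 0.4, D = 0.4, H = 0.2), al), "D")
})

test_that("posterior sample count follows the thinning arithmetic", {
  cfg <- bbm_config()
  expect_identical(cfg[c("generations", "burnin", "samplefreq", "chains",
                         "max_areas")],
                   list(generations = 100000L, burnin = 20000L,
                        samplefreq = 100L, chains = 10L, max_areas = 3L))
  expect_equal(n_posterior_samples(cfg), 8000)
  expect_equal(n_posterior_samples(bbm_config(1000, 200, 30, 3)),
               3 * 26)
  expect_error(bbm_config(1000, 1000), "burnin")
})

small_sim <- function(pi1, seed, n = 40) {
  ch <- as_chronogram(ape::rcoal(n))
  ch$phylo$edge.length <- ch$phylo$edge.length / ch$root_age * 5
  ch <- as_chronogram(ch$phylo)
  sim <- simulate_area_characters(ch, f81_params(pi1, 1, 4),
                                  area_alphabet(LETTERS[1:8]), seed = seed)
  list(ch = ch, tips = sim$tips)
}

test_that("the sampler is deterministic given the seed", {
  set.seed(407)
  s <- small_sim(0.4, 1)
  cfg <- bbm_config(generations = 600, burnin = 200, samplefreq = 10,
                    chains = 2, seed = 9)
  r1 <- run_bbm_mcmc(s$ch, s$tips, cfg)
  r2 <- run_bbm_mcmc(s$ch, s$tips, cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$area_posteriors, r2$area_posteriors)
  expect_identical(r1$map_ranges, r2$map_ranges)
  expect_equal(nrow(r1$samples), n_posterior_samples(cfg))
  expect_true(all(r1$area_posteriors >= 0 & r1$area_posteriors <= 1))
  for (rp in r1$range_posteriors)
    expect_equal(sum(rp), 1, tolerance = 1e-9)
})

test_that("posterior means of pi1 order correctly across extreme truths", {
  set.seed(408)
  lo <- small_sim(0.1, 21)
  hi <- small_sim(0.9, 22)
  cfg <- bbm_config(generations = 2000, burnin = 500, samplefreq = 10,
                    chains = 2, seed = 3)
  m_lo <- mean(run_bbm_mcmc(lo$ch, lo$tips, cfg)$samples$pi1)
  m_hi <- mean(run_bbm_mcmc(hi$ch, hi$tips, cfg)$samples$pi1)
  expect_lt(m_lo, m_hi)
  expect_lt(m_lo, 0.5)
  expect_gt(m_hi, 0.5)
})

test_that("degenerate and mismatched codings are rejected", {
  ch <- toy_chronogram()
  al <- area_alphabet(c("X", "Y"))
  rc <- read_region_codings("taxon,areas\nA,X\nB,X\nC,X\nD,X", al)
  expect_error(run_bbm_mcmc(ch, rc, bbm_config(100, 10, 10, 1)),
               "degenerate|signal")
  rc2 <- read_region_codings("taxon,areas\nA,X\nB,X\nC,Y\nZ,Y", al)
  expect_error(run_bbm_mcmc(ch, rc2, bbm_config(100, 10, 10, 1)),
               "mismatch")
})

test_that("relabeling areas permutes posteriors and MAP ranges", {
  set.seed(409)
  n <- 25
  ch <- as_chronogram(ape::rcoal(n))
  al <- area_alphabet(c("A", "B", "C"))
  X <- matrix(rbinom(n * 3, 1, 0.5), n, 3,
              dimnames = list(ch$phylo$tip.label, c("A", "B", "C")))
  X[rowSums(X) == 0, 1] <- 1L
  cfg <- bbm_config(generations = 500, burnin = 100, samplefreq = 10,
                    chains = 1, seed = 4)
  r <- run_bbm_mcmc(ch, X, cfg, al)
  # permuted alphabet C,A,B with matching column relabels
  perm <- c(C = "A", A = "B", B = "C") # old -> new letter
  X2 <- X
  colnames(X2) <- unname(perm[colnames(X)])
  al2 <- area_alphabet(c("A", "B", "C"))
  r2 <- run_bbm_mcmc(ch, X2[, c("A", "B", "C")], cfg, al2)
  # parameter chain untouched (loglik may differ by summation-order noise)
  expect_equal(r$samples$pi1, r2$samples$pi1, tolerance = 1e-12)
  expect_equal(r$samples$alpha, r2$samples$alpha, tolerance = 1e-12)
  expect_equal(unname(r2$area_posteriors[, unname(perm["A"])]),
               unname(r$area_posteriors[, "A"]), tolerance = 1e-12)
  relabel <- function(key) {
    paste(sort(unname(perm[range_letters(key)])), collapse = "|")
  }
  expect_equal(unname(vapply(r$map_ranges, relabel, "")),
               unname(r2$map_ranges))
})
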