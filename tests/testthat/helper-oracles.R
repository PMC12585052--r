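# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's pruning/composition code paths: likelihoods and marginals by
# exhaustive enumeration over internal states, range composition by bitmask
# enumeration, the F81 matrix by truncated series matrix exponential.

toy_chronogram <- function() parse_chronogram("((A:1,B:1):2,(C:2,D:2):1);")

# root and MRCA(C,D) in X, MRCA(A,B) and its tips in Y: one transition on
# the branch into MRCA(A,B), dated at (3+1)/2 = 2
toy_assignment <- function()
  c(N5 = "X", N6 = "Y", N7 = "X", A = "Y", B = "Y", C = "X", D = "X")

random_ultrametric <- function(n) as_chronogram(ape::rcoal(n))

# matrix exponential of the two-state F81 generator by truncated Taylor series
series_expm_f81 <- function(pi1, rate, t, nterms = 200L) {
  beta <- 1 / (2 * pi1 * (1 - pi1))
  Q <- beta * rate * matrix(c(-pi1, 1 - pi1, pi1, -(1 - pi1)), 2L, 2L)
  A <- Q * t
  out <- diag(2)
  term <- diag(2)
  for (i in seq_len(nterms)) {
    term <- term %*% A / i
    out <- out + term
  }
  out
}

# exhaustive joint enumeration over internal-node states
enum_area_likelihood <- function(chron, presence, params) {
  phy <- chron$phylo
  ntip <- chron$n_tips
  m <- phy$Nnode
  edge <- phy$edge
  elen <- numeric(ntip + m)
  elen[edge[, 2L]] <- phy$edge.length
  rates <- discrete_gamma_rates(params$alpha, params$k)
  pivec <- c(1 - params$pi1, params$pi1)
  tipst <- as.integer(presence[phy$tip.label])
  combos <- as.matrix(expand.grid(rep(list(0:1), m)))
  root <- ntip + 1L
  lik <- numeric(length(rates))
  for (ci in seq_along(rates)) {
    Ps <- lapply(seq_len(nrow(edge)), function(e)
      f81_transition_matrix(params, rates[ci], elen[edge[e, 2L]]))
    tot <- 0
    for (row in seq_len(nrow(combos))) {
      st <- c(tipst, combos[row, ])
      pr <- pivec[st[root] + 1L]
      for (e in seq_len(nrow(edge)))
        pr <- pr * Ps[[e]][st[edge[e, 1L]] + 1L, st[edge[e, 2L]] + 1L]
      tot <- tot + pr
    }
    lik[ci] <- tot
  }
  log(mean(lik))
}

# exhaustive marginal P(present) per node, mixing categories by likelihood
enum_area_marginals <- function(chron, presence, params) {
  phy <- chron$phylo
  ntip <- chron$n_tips
  m <- phy$Nnode
  edge <- phy$edge
  elen <- numeric(ntip + m)
  elen[edge[, 2L]] <- phy$edge.length
  rates <- discrete_gamma_rates(params$alpha, params$k)
  pivec <- c(1 - params$pi1, params$pi1)
  tipst <- as.integer(presence[phy$tip.label])
  combos <- as.matrix(expand.grid(rep(list(0:1), m)))
  root <- ntip + 1L
  w1 <- numeric(ntip + m)
  tot <- 0
  for (ci in seq_along(rates)) {
    Ps <- lapply(seq_len(nrow(edge)), function(e)
      f81_transition_matrix(params, rates[ci], elen[edge[e, 2L]]))
    for (row in seq_len(nrow(combos))) {
      st <- c(tipst, combos[row, ])
      pr <- pivec[st[root] + 1L]
      for (e in seq_len(nrow(edge)))
        pr <- pr * Ps[[e]][st[edge[e, 1L]] + 1L, st[edge[e, 2L]] + 1L]
      tot <- tot + pr
      w1[st == 1L] <- w1[st == 1L] + pr
    }
  }
  stats::setNames(w1 / tot, chron$node_ids)
}

# independent subset enumeration over bitmasks
enum_range_posterior <- function(p, max_areas, alphabet) {
  n <- length(alphabet)
  out <- numeric(0)
  for (mask in seq_len(2^n - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) > max_areas) next
    w <- prod(ifelse(bits == 1L, p[as.character(alphabet)],
                     1 - p[as.character(alphabet)]))
    out[paste(as.character(alphabet)[bits == 1L], collapse = "|")] <- w
  }
  out / sum(out)
}
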