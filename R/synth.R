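#' Simulation configuration
#'
#' Conditions for the birth-death + range-evolution generator.  The defaults
#' describe the default two-burst profile used throughout the package's
#' calibration checks: ~190 extant tips on a crown age of 10.5 Myr, ten
#' areas, per-area gain/loss rates slow relative to branch durations, and a
#' dispersal (gain) multiplier elevated inside the 6.6-5.8 and 4.7-3.1 mya
#' epochs to emulate a two-burst transition history.
#'
#' @param birth,death Speciation and extinction rates per lineage per Myr;
#'   `birth > death >= 0` is required.
#' @param n_tips Target extant tip count (conditioned by forward simulation
#'   with retries), or `NULL` to condition on `crown_age` alone.
#' @param crown_age Crown age in Myr.  When both `n_tips` and `crown_age`
#'   are given, the tree is simulated to `n_tips` tips and its depth is then
#'   standardized to `crown_age`.
#' @param alphabet An [area_alphabet()].
#' @param gain,loss Per-area gain and loss rates per Myr (scalars or vectors
#'   over the alphabet); both must be > 0.
#' @param max_areas Maximum areas a simulated range may hold.
#' @param epochs Data.frame with columns `old`, `young`, `multiplier` and
#'   optionally `birth_multiplier`: non-overlapping age intervals
#'   `(young, old]` in which the gain (dispersal) rate -- and, when
#'   `birth_multiplier` is given, the speciation rate -- is multiplied; ages
#'   outside every epoch use multiplier 1.  Epoch speciation multipliers
#'   require crown-age conditioning (the tree must live in absolute time).
#' @param seed Master seed; tree and range stages draw deterministic
#'   substreams from it.
#' @param retries Resimulation cap when the whole tree goes extinct.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(birth = 0.316, death = 0.1, n_tips = 190L,
                       crown_age = 10.5, alphabet = area_alphabet(),
                       gain = 0.002, loss = 0.015, max_areas = 3L,
                       epochs = data.frame(old = c(6.6, 4.7),
                                           young = c(5.8, 3.1),
                                           multiplier = c(30, 60),
                                           birth_multiplier = c(6, 3)),
                       seed = 1L, retries = 100L) {
  if (!is.numeric(birth) || !is.numeric(death) || birth <= death || death < 0)
    stop("need birth > death >= 0")
  if (is.null(n_tips) && is.null(crown_age))
    stop("give a target tip count, a crown age, or both")
  if (!is.null(n_tips) && n_tips < 2L) stop("n_tips must be >= 2")
  stopifnot(inherits(alphabet, "area_alphabet"))
  narea <- length(alphabet)
  gain <- rep_len(gain, narea); loss <- rep_len(loss, narea)
  if (any(gain <= 0) || any(loss <= 0)) stop("gain and loss rates must be > 0")
  names(gain) <- names(loss) <- as.character(alphabet)
  if (as.integer(max_areas) < 1L) stop("max_areas must be >= 1")
  if (!is.null(epochs) && nrow(epochs)) {
    stopifnot(all(c("old", "young", "multiplier") %in% names(epochs)))
    if (any(epochs$old <= epochs$young)) stop("each epoch needs old > young")
    o <- order(-epochs$old)
    ep <- epochs[o, , drop = FALSE]
    if (nrow(ep) > 1L && any(ep$old[-1L] > ep$young[-nrow(ep)] + 1e-12))
      stop("epochs must not overlap")
    epochs <- ep
    if (any(epochs$multiplier < 0)) stop("epoch multipliers must be >= 0")
    if (is.null(epochs$birth_multiplier)) epochs$birth_multiplier <- 1
    if (any(epochs$birth_multiplier <= 0))
      stop("epoch birth multipliers must be > 0")
    if (any(epochs$birth_multiplier != 1) && is.null(crown_age))
      stop("epoch speciation multipliers require crown-age conditioning")
  }
  structure(list(birth = birth, death = death,
                 n_tips = if (is.null(n_tips)) NULL else as.integer(n_tips),
                 crown_age = crown_age, alphabet = alphabet,
                 gain = gain, loss = loss, max_areas = as.integer(max_areas),
                 epochs = epochs, seed = as.integer(seed),
                 retries = as.integer(retries)),
            class = "sim_config")
}

# forward Gillespie birth-death from the two crown lineages.
# n-mode: stop at the moment the (n+1)th birth would occur, so the sojourn at
# n lineages is complete (pure-birth crown age then sums Exp(k*b) waits for
# k = 2..n).  age-mode: run for a fixed duration, conditioning on extant
# descendants on both sides of the crown; the birth rate may vary by epoch
# (piecewise constant in age).  Returns NULL on extinction / failed crown
# condition.
.sim_bd_once <- function(birth, death, n_target = NULL, duration = NULL,
                         epochs = NULL) {
  bmult_at <- function(age) {
    if (is.null(epochs) || !nrow(epochs)) return(1)
    hit <- which(epochs$old >= age & age > epochs$young)
    if (length(hit)) epochs$birth_multiplier[hit[1L]] else 1
  }
  start <- c(0, 0); endt <- c(NA_real_, NA_real_)
  left <- c(NA_integer_, NA_integer_); right <- left
  dead <- c(FALSE, FALSE); side <- c(1L, 2L)
  alive <- c(1L, 2L)
  t <- 0
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) return(NULL)
    age <- if (is.null(duration)) Inf else duration - t
    b_now <- birth * (if (is.null(duration)) 1 else bmult_at(age))
    total <- n_alive * (b_now + death)
    dt <- stats::rexp(1, total)
    if (!is.null(duration)) {
      # piecewise-constant rates: redraw if the wait crosses an epoch edge
      bnd <- .next_boundary(epochs, age) # next younger epoch boundary
      if (age - dt < max(bnd, 0)) {
        if (bnd <= 0) { t <- duration; break }
        t <- duration - bnd
        next
      }
    }
    t <- t + dt
    is_birth <- stats::runif(1) < b_now / (b_now + death)
    if (is_birth && !is.null(n_target) && n_alive == n_target) break
    who <- alive[sample.int(n_alive, 1L)]
    endt[who] <- t
    alive <- alive[alive != who]
    if (is_birth) {
      id1 <- length(start) + 1L; id2 <- id1 + 1L
      start <- c(start, t, t); endt <- c(endt, NA_real_, NA_real_)
      left <- c(left, NA_integer_, NA_integer_)
      right <- c(right, NA_integer_, NA_integer_)
      dead <- c(dead, FALSE, FALSE)
      side <- c(side, side[who], side[who])
      left[who] <- id1; right[who] <- id2
      alive <- c(alive, id1, id2)
    } else {
      dead[who] <- TRUE
    }
  }
  if (!is.null(n_target) && length(alive) != n_target) return(NULL)
  if (!is.null(duration) &&
      (!any(side[alive] == 1L) || !any(side[alive] == 2L))) return(NULL)
  endt[alive] <- t

  # prune extinct subtrees while building newick; splice single-child nodes
  label <- 0L
  build <- function(id) {
    if (is.na(left[id])) {
      if (dead[id]) return(NULL)
      label <<- label + 1L
      return(list(str = sprintf("t%d", label), len = endt[id] - start[id]))
    }
    l <- build(left[id]); r <- build(right[id])
    here <- endt[id] - start[id]
    if (is.null(l) && is.null(r)) return(NULL)
    if (is.null(l)) return(list(str = r$str, len = r$len + here))
    if (is.null(r)) return(list(str = l$str, len = l$len + here))
    list(str = sprintf("(%s:%.12g,%s:%.12g)", l$str, l$len, r$str, r$len),
         len = here)
  }
  a <- build(1L); b <- build(2L)
  nwk <- if (is.null(a) || is.null(b)) {
    s <- if (is.null(a)) b else a
    if (!grepl("(", s$str, fixed = TRUE)) return(NULL) # single surviving tip
    paste0(s$str, ";")
  } else {
    sprintf("(%s:%.12g,%s:%.12g);", a$str, a$len, b$str, b$len)
  }
  ape::read.tree(text = nwk)
}

#' Simulate an extant-only ultrametric birth-death chronogram
#'
#' Constant-rate forward (Gillespie) birth-death from the two crown
#' lineages.  With a target tip count the simulation stops at the moment the
#' next birth would exceed the target; with a crown age it runs for that
#' duration conditioned on survival of both crown lineages; with both, the
#' tip-count tree is depth-standardized to the crown age.  Whole-tree
#' extinction triggers a resimulation, up to `cfg$retries`.
#'
#' @param cfg A [sim_config()].
#' @return A `chronogram`.  Deterministic for a fixed `cfg$seed`.
#' @export
simulate_bd_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream_seeds(cfg$seed, 2L)[1L])
  varying_birth <- !is.null(cfg$epochs) && nrow(cfg$epochs) &&
    any(cfg$epochs$birth_multiplier != 1)
  for (i in seq_len(cfg$retries)) {
    if (varying_birth) {
      # epochs live in absolute time: condition on the crown age and accept
      # tip counts within a window around the target
      phy <- .sim_bd_once(cfg$birth, cfg$death, duration = cfg$crown_age,
                          epochs = cfg$epochs)
      if (!is.null(phy) && !is.null(cfg$n_tips)) {
        n <- length(phy$tip.label)
        if (n < 0.6 * cfg$n_tips || n > 1.6 * cfg$n_tips) phy <- NULL
      }
    } else if (!is.null(cfg$n_tips)) {
      phy <- .sim_bd_once(cfg$birth, cfg$death, n_target = cfg$n_tips)
    } else {
      phy <- .sim_bd_once(cfg$birth, cfg$death, duration = cfg$crown_age)
    }
    if (!is.null(phy)) {
      ch <- as_chronogram(phy)
      if (!varying_birth && !is.null(cfg$n_tips) &&
          !is.null(cfg$crown_age) && ch$root_age > 0) {
        phy$edge.length <- phy$edge.length * cfg$crown_age / ch$root_age
        ch <- as_chronogram(phy)
      }
      return(ch)
    }
  }
  stop("birth-death simulation failed ", cfg$retries,
       " times (extinction or tip-count window); adjust rates or retries")
}

# epoch gain multiplier at age t: epoch (young, old] applies; 1 elsewhere
.epoch_multiplier <- function(epochs, t) {
  if (is.null(epochs) || !nrow(epochs)) return(1)
  hit <- which(epochs$old >= t & t > epochs$young)
  if (length(hit)) epochs$multiplier[hit[1L]] else 1
}

# age of the next (younger) epoch boundary strictly below t, or -Inf
.next_boundary <- function(epochs, t) {
  if (is.null(epochs) || !nrow(epochs)) return(-Inf)
  b <- c(epochs$old, epochs$young)
  b <- b[b < t - 1e-12]
  if (length(b)) max(b) else -Inf
}

#' Simulate range evolution along a chronogram
#'
#' Continuous-time Markov evolution of area sets along every branch,
#' simulated event by event (Gillespie) so exact event times are known.
#' Area `a` is gained at rate `gain_a` times the epoch multiplier while the
#' range holds fewer than `max_areas` areas, and lost at rate `loss_a` while
#' the range holds more than one (the final loss is forbidden, so ranges are
#' never empty).  With `max_areas = 1` gains act as direct single-area
#' switches.  The root range is a uniformly drawn single area.
#'
#' @param chron A `chronogram`.
#' @param cfg A [sim_config()] (its tree fields are ignored).
#' @return A list: `coding` (a `region_coding` of the tip ranges), `truth`
#'   (class `sim_truth`: `node_ranges` named range-key vector over all
#'   nodes, `events` data.frame of exact gain/loss events with columns
#'   `branch`, `time`, `kind`, `area`, `from`, `to`, and `params` echoing
#'   the generator settings).
#' @export
simulate_range_evolution <- function(chron, cfg) {
  stopifnot(inherits(chron, "chronogram"), inherits(cfg, "sim_config"))
  set.seed(.substream_seeds(cfg$seed, 2L)[2L])
  alphabet <- cfg$alphabet
  narea <- length(alphabet)
  phy <- chron$phylo
  edge <- phy$edge
  ages <- chron$ages
  ntip <- chron$n_tips
  root <- ntip + 1L

  state <- vector("list", ntip + phy$Nnode)
  state[[root]] <- sample.int(narea, 1L)
  ev <- list()

  po <- ape::reorder.phylo(phy, "postorder")$edge
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE] # preorder: parents first
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1L]; chd <- pre[r, 2L]
    S <- state[[p]]
    t_cur <- ages[p]; t_end <- ages[chd]
    repeat {
      mult <- .epoch_multiplier(cfg$epochs, t_cur)
      if (cfg$max_areas == 1L) {
        gsel <- setdiff(seq_len(narea), S)
        grates <- cfg$gain[gsel] * mult
        lrates <- numeric(0); lsel <- integer(0)
      } else {
        gsel <- if (length(S) < cfg$max_areas) setdiff(seq_len(narea), S) else integer(0)
        grates <- cfg$gain[gsel] * mult
        lsel <- if (length(S) > 1L) S else integer(0)
        lrates <- cfg$loss[lsel]
      }
      total <- sum(grates) + sum(lrates)
      bnd <- max(.next_boundary(cfg$epochs, t_cur), t_end)
      if (total <= 0) {
        if (bnd <= t_end) break
        t_cur <- bnd
        next
      }
      dt <- stats::rexp(1, total)
      if (t_cur - dt < bnd) {
        if (bnd <= t_end) break
        t_cur <- bnd
        next
      }
      t_cur <- t_cur - dt
      pick <- sample.int(length(grates) + length(lrates), 1L,
                         prob = c(grates, lrates))
      from <- S
      if (pick <= length(grates)) {
        a <- gsel[pick]
        S <- if (cfg$max_areas == 1L) a else sort(c(S, a))
        kind <- "gain"
      } else {
        a <- lsel[pick - length(grates)]
        S <- setdiff(S, a)
        kind <- "loss"
      }
      ev[[length(ev) + 1L]] <- data.frame(
        branch = chron$node_ids[chd], time = t_cur, kind = kind,
        area = as.character(alphabet)[a],
        from = range_key(alphabet[from], alphabet),
        to = range_key(alphabet[S], alphabet),
        stringsAsFactors = FALSE)
    }
    state[[chd]] <- S
  }

  node_ranges <- vapply(state, function(s)
    range_key(alphabet[s], alphabet), character(1L))
  names(node_ranges) <- chron$node_ids
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = character(0), time = numeric(0), kind = character(0),
               area = character(0), from = character(0), to = character(0))
  events <- events[order(-events$time), , drop = FALSE]
  rownames(events) <- NULL

  coding <- stats::setNames(
    lapply(seq_len(ntip), function(i) as.character(alphabet)[state[[i]]]),
    phy$tip.label)
  coding <- structure(coding, class = "region_coding", alphabet = alphabet)
  truth <- structure(
    list(node_ranges = node_ranges, events = events,
         params = list(gain = cfg$gain, loss = cfg$loss,
                       max_areas = cfg$max_areas, epochs = cfg$epochs,
                       seed = cfg$seed)),
    class = "sim_truth")
  list(coding = coding, truth = truth)
}

#' Simulate per-area binary characters under the inference model
#'
#' Generates tip presence/absence for every area directly under the binary
#' F81+G model used by the reconstruction: each area draws one of the `k`
#' discrete gamma rate multipliers uniformly, the root state is drawn from
#' the stationary distribution, and states evolve down each branch with the
#' F81 transition probabilities.  This is the simulation-based-calibration
#' counterpart of [run_bbm_mcmc()].
#'
#' @param chron A `chronogram`.
#' @param params An [f81_params()].
#' @param alphabet An [area_alphabet()].
#' @param seed Integer seed.
#' @return List: `tips` (0/1 tip-by-area matrix), `node_states` (0/1
#'   node-by-area matrix over all nodes), `rates` (per-area category
#'   multiplier drawn).
#' @export
simulate_area_characters <- function(chron, params, alphabet, seed = 1L) {
  stopifnot(inherits(chron, "chronogram"), inherits(params, "f81_params"))
  set.seed(as.integer(seed))
  narea <- length(alphabet)
  cats <- discrete_gamma_rates(params$alpha, params$k)
  phy <- chron$phylo
  ntip <- chron$n_tips
  nnode <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")$edge
  pre_idx <- rev(seq_len(nrow(po)))
  elen <- numeric(nnode)
  elen[phy$edge[, 2L]] <- phy$edge.length

  states <- matrix(0L, nrow = nnode, ncol = narea,
                   dimnames = list(chron$node_ids, as.character(alphabet)))
  rates <- stats::setNames(numeric(narea), as.character(alphabet))
  root <- ntip + 1L
  for (a in seq_len(narea)) {
    r <- cats[sample.int(length(cats), 1L)]
    rates[a] <- r
    states[root, a] <- as.integer(stats::runif(1) < params$pi1)
    for (i in pre_idx) {
      p <- po[i, 1L]; ch <- po[i, 2L]
      P <- f81_transition_matrix(params, rate = r, t = elen[ch])
      states[ch, a] <- as.integer(
        stats::runif(1) < P[states[p, a] + 1L, 2L])
    }
  }
  list(tips = states[seq_len(ntip), , drop = FALSE], node_states = states,
       rates = rates)
}

#' Write a complete synthetic fixture to disk
#'
#' Simulates a chronogram and range evolution under `cfg` and writes the
#' tree (newick), the tip region codings (CSV, `taxon,areas`) and the ground
#' truth (JSON: node ranges, exact event list, generator parameters).  With
#' the same seed the three files are byte-identical across runs.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Writable output directory (created if absent).
#' @return Invisibly, a list with the `chron`, `coding`, `truth` objects and
#'   the three file `paths`.
#' @export
make_fixture <- function(cfg = sim_config(), out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  chron <- simulate_bd_tree(cfg)
  sim <- simulate_range_evolution(chron, cfg)
  paths <- list(tree = file.path(out_dir, "tree.nwk"),
                codings = file.path(out_dir, "codings.csv"),
                truth = file.path(out_dir, "truth.json"))
  write_chronogram(chron, paths$tree)
  areas <- vapply(sim$coding, paste, character(1L), collapse = "|")
  utils::write.csv(data.frame(taxon = names(sim$coding), areas = areas),
                   paths$codings, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(node_ranges = as.list(sim$truth$node_ranges),
         events = sim$truth$events,
         params = list(birth = cfg$birth, death = cfg$death,
                       n_tips = cfg$n_tips, crown_age = cfg$crown_age,
                       alphabet = as.character(cfg$alphabet),
                       gain = as.list(cfg$gain), loss = as.list(cfg$loss),
                       max_areas = cfg$max_areas, epochs = cfg$epochs,
                       seed = cfg$seed)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(chron = chron, coding = sim$coding, truth = sim$truth,
                 paths = paths))
}
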