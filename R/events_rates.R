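#' Extract dated transition and origination events from a range assignment
#'
#' A transition is a branch whose parent-node and child-node assigned ranges
#' differ (any set inequality, including pure expansions such as
#' `D -> D|E`); it is dated at the branch midpoint,
#' `(age_parent + age_child) / 2`.  Every internal node contributes one
#' origination event at its own age in its assigned range; the event is
#' flagged in-situ when the node and both daughters reconstruct to the same
#' range.  Events are returned sorted old to young.
#'
#' @param chron A `chronogram`.
#' @param assignments Named character vector (node id -> range key) covering
#'   every node of the tree.
#' @return A data.frame of class `event_record` with columns `kind`
#'   ("transition"/"origination"), `time` (age, Myr), `node` (child node id
#'   for transitions, the splitting node for originations), `from`, `to`
#'   (transition ranges), `region` (origination range) and `in_situ`.
#' @export
extract_events <- function(chron, assignments) {
  stopifnot(inherits(chron, "chronogram"))
  miss <- setdiff(chron$node_ids, names(assignments))
  if (length(miss))
    stop("assignment missing node(s): ", paste(miss, collapse = ", "))
  a <- assignments[chron$node_ids] # by ape node number
  edge <- chron$phylo$edge
  ages <- chron$ages
  ntip <- chron$n_tips

  # transitions on branches
  pr <- a[edge[, 1L]]
  cr <- a[edge[, 2L]]
  chg <- which(pr != cr)
  trans <- data.frame(
    kind = rep("transition", length(chg)),
    time = (unname(ages[edge[chg, 1L]]) + unname(ages[edge[chg, 2L]])) / 2,
    node = chron$node_ids[edge[chg, 2L]],
    from = unname(pr[chg]), to = unname(cr[chg]),
    region = rep(NA_character_, length(chg)),
    in_situ = rep(NA, length(chg)),
    stringsAsFactors = FALSE)

  # originations at internal nodes
  internal <- (ntip + 1L):(ntip + chron$phylo$Nnode)
  kids <- split(edge[, 2L], edge[, 1L])
  insitu <- vapply(internal, function(v)
    all(a[kids[[as.character(v)]]] == a[v]), logical(1L))
  orig <- data.frame(
    kind = "origination",
    time = unname(ages[internal]),
    node = chron$node_ids[internal],
    from = NA_character_, to = NA_character_,
    region = unname(a[internal]), in_situ = insitu,
    stringsAsFactors = FALSE)

  ev <- rbind(trans, orig)
  ev <- ev[order(-ev$time, ev$kind, ev$node), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_record", "data.frame")
  ev
}

# window normalizer: lineages at the window's old edge, except that the
# window opening exactly at the crown age is normalized by the two crown
# lineages (the crown split itself starts the record)
.window_lineages <- function(chron, t) {
  n <- lineages_at(chron, min(t, chron$root_age))
  if (n == 0L && abs(t - chron$root_age) <= 1e-9) n <- 2L
  n
}

#' Sliding-window per-lineage event rates
#'
#' Contiguous windows of fixed width step from `t_max` toward `t_min`; the
#' window with old edge `t_old` covers `(t_old - width, t_old]` and its value
#' is the number of events of the requested kind inside it, divided by the
#' number of lineages at the window's old edge ("per branch at the start of
#' the time frame") and by the width in Myr.  Windows opening older than the
#' root have no lineages and are dropped with a message.
#'
#' @param events An `event_record` from [extract_events()].
#' @param chron The companion `chronogram`.
#' @param kind "transition" or "origination".
#' @param width Window width in Myr (default 0.1, i.e. 100,000 years).
#' @param t_max Old edge of the first window (default: the root age).
#' @param t_min Young limit of the series (default 0).
#' @return A data.frame of class `rate_series` with columns
#'   `window_old_edge`, `lineages`, `count` and `rate` (events per lineage
#'   per Myr); attributes `kind` and `width`.
#' @export
sliding_window_rates <- function(events, chron, kind = "transition",
                                 width = 0.1, t_max = chron$root_age,
                                 t_min = 0) {
  stopifnot(inherits(chron, "chronogram"), width > 0)
  kind <- match.arg(kind, c("transition", "origination"))
  n_win <- floor((t_max - t_min) / width + 1e-9)
  if (n_win < 1L) stop("no complete window fits between t_max and t_min")
  edges <- t_max - (seq_len(n_win) - 1L) * width

  tt <- events$time[events$kind == kind]
  # assign each event to exactly one window: old-edge boundary inclusive
  j <- floor((t_max - tt) / width + 1e-9)
  j <- j[j >= 0 & j < n_win]
  counts <- tabulate(j + 1L, nbins = n_win)

  lin <- vapply(edges, function(e) .window_lineages(chron, e), integer(1L))
  keep <- lin > 0L
  if (any(!keep))
    message("dropping ", sum(!keep), " window(s) opening older than the root")
  out <- data.frame(window_old_edge = edges[keep], lineages = lin[keep],
                    count = counts[keep],
                    rate = counts[keep] / lin[keep] / width)
  attr(out, "kind") <- kind
  attr(out, "width") <- width
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Period-average rate from a windowed series
#'
#' Arithmetic mean of the window values whose old edges lie in
#' `(t_young, t_old]`; a window straddling a period boundary belongs to the
#' period iff its old edge is inside.  `pooled = TRUE` instead divides the
#' total event count by the total lineage-time
#' (`sum(lineages * width)`) of the selected windows.
#'
#' @param series A `rate_series`.
#' @param t_old,t_young Period limits in Myr (old > young).
#' @param pooled Use the pooled-count estimator instead of the mean of
#'   window values.
#' @return Events per lineage per Myr (scalar).
#' @export
period_mean_rate <- function(series, t_old, t_young, pooled = FALSE) {
  stopifnot(inherits(series, "rate_series"), t_old > t_young)
  e <- series$window_old_edge
  sel <- e <= t_old + 1e-9 & e > t_young + 1e-9
  if (!any(sel))
    stop("no windows with old edges inside (", t_young, ", ", t_old, "]")
  if (pooled) {
    sum(series$count[sel]) /
      sum(series$lineages[sel] * attr(series, "width"))
  } else {
    mean(series$rate[sel])
  }
}

#' Triangular-cone event series for plotting
#'
#' Each event contributes a symmetric triangular kernel of total base width
#' `cone_width` centered at its time, scaled to integrate to one over the
#' number of lineages at the event time, and the series is the sum of the
#' kernels sampled on a regular age grid.  The total integral therefore
#' equals `sum_i 1 / N(t_i)`.
#'
#' @param events An `event_record`.
#' @param chron The companion `chronogram`.
#' @param kind "transition" or "origination".
#' @param cone_width Total base width in Myr (default 0.2, i.e. twice the
#'   0.1-Myr sliding window).
#' @param grid_step Grid spacing in Myr.
#' @param t_max,t_min Age range of the grid.
#' @return Data.frame with columns `age` and `value`.
#' @export
cone_series <- function(events, chron, kind = "transition", cone_width = 0.2,
                        grid_step = 0.01, t_max = chron$root_age, t_min = 0) {
  stopifnot(cone_width > 0, grid_step > 0)
  kind <- match.arg(kind, c("transition", "origination"))
  grid <- seq(t_max, t_min, by = -grid_step)
  val <- numeric(length(grid))
  half <- cone_width / 2
  tt <- events$time[events$kind == kind]
  for (t0 in tt) {
    n <- .window_lineages(chron, min(t0, chron$root_age))
    h <- 2 / (n * cone_width) # triangle area = 1/n
    d <- abs(grid - t0)
    inside <- d < half
    val[inside] <- val[inside] + h * (1 - d[inside] / half)
  }
  data.frame(age = grid, value = val)
}

#' Lineage-through-time curve
#'
#' Right-continuous step function of the number of reconstructed lineages,
#' stepping up by one at each internal node age.  The curve starts at 2 just
#' younger than the clade's root split and ends at the clade's tip count at
#' the present (or at `cutoff`).
#'
#' @param chron A `chronogram`.
#' @param mrca_of Optional character vector naming at least two tips; the
#'   curve is then restricted to the clade subtended by their MRCA.
#' @param cutoff Optional young truncation age in Myr (rows older than or at
#'   the cutoff are kept).
#' @return Data.frame with columns `age` (node ages, old to young) and
#'   `lineages` (count holding from that age to the next step); attribute
#'   `n_tips` is the clade tip count.
#' @export
ltt_curve <- function(chron, mrca_of = NULL, cutoff = 0) {
  stopifnot(inherits(chron, "chronogram"))
  if (!is.null(mrca_of)) {
    if (length(mrca_of) < 2L) stop("mrca_of must name at least 2 tips")
    unknown <- setdiff(mrca_of, chron$phylo$tip.label)
    if (length(unknown))
      stop("unknown taxon: ", paste(unknown, collapse = ", "))
    node <- ape::getMRCA(chron$phylo, mrca_of)
    sub <- ape::extract.clade(chron$phylo, node)
    chron <- as_chronogram(sub)
  }
  internal_ages <- sort(chron$ages[(chron$n_tips + 1L):length(chron$ages)],
                        decreasing = TRUE)
  out <- data.frame(age = unname(internal_ages),
                    lineages = seq_along(internal_ages) + 1L)
  out <- out[out$age >= cutoff - 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tips") <- chron$n_tips
  out
}
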