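# Orchestration: one reproducible run from tree + codings to rates tables.
# All artifacts are written atomically (temp file + rename) and every table
# carries the config hash in a leading comment line.

.config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

.write_tsv_atomic <- function(df, path, hash = NULL) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  path
}

.read_tsv <- function(path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)

.log_line <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = logfile, append = TRUE)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file with keys `tree`, `codings`, `out`, `alphabet` (a
#' string of area letters), a `bbm` block (generations, burnin, samplefreq,
#' chains, max_areas, seed), a `rates` block (window, cone, span_old,
#' span_young, periods: list of label/old/young), optional `clades`
#' (label -> taxon list) and `plot`.  Missing keys take the package
#' defaults (window 0.1 Myr, cone 0.2 Myr, max_areas 3).
#'
#' @param path Path to the YAML config.
#' @param seed Optional seed overriding the file's.
#' @return A list of class `run_config`.
#' @export
load_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  for (f in c("tree", "codings"))
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]]))
      stop("config references missing file: ", raw[[f]])
  bbm <- raw$bbm %||% list()
  if (!is.null(seed)) bbm$seed <- seed
  config <- do.call(bbm_config, bbm)
  rates <- raw$rates %||% list()
  rates$window <- rates$window %||% 0.1
  rates$cone <- rates$cone %||% 0.2
  rates$span_young <- rates$span_young %||% 0
  alphabet <- area_alphabet(strsplit(raw$alphabet %||%
                                       paste(LETTERS[1:10], collapse = ""),
                                     "")[[1L]])
  structure(list(tree = raw$tree, codings = raw$codings,
                 out = raw$out %||% ".", alphabet = alphabet, bbm = config,
                 rates = rates, clades = raw$clades,
                 plot = isTRUE(raw$plot)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the ancestral range reconstruction stage
#'
#' Parses the chronogram and region codings, validates them against each
#' other, runs the Bayesian Binary MCMC and writes four artifacts into the
#' output directory: `range_posteriors.tsv` (node, range, probability),
#' `annotated.nwk` (newick with per-node MAP range comments),
#' `mcmc_trace.tsv` and `run.log`.  The log records the seed, the config
#' hash, sample counts and acceptance rates.  Writes are atomic; on error
#' partial outputs are removed.
#'
#' @param config A `run_config` from [load_run_config()], or a list with
#'   the same fields built in code.
#' @return Invisibly, a named list of artifact paths.
#' @export
cmd_reconstruct <- function(config) {
  out <- config$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logfile <- file.path(out, "run.log")
  paths <- c(range_posteriors = file.path(out, "range_posteriors.tsv"),
             annotated = file.path(out, "annotated.nwk"),
             trace = file.path(out, "mcmc_trace.tsv"),
             log = logfile)
  on.exit(unlink(paste0(paths, ".tmp")), add = TRUE)

  hash <- .config_hash(config[c("tree", "codings", "alphabet", "bbm")])
  .log_line(logfile, "reconstruct: config hash ", hash)
  cfg <- config$bbm
  .log_line(logfile, "bbm config: generations=", cfg$generations,
            " burnin=", cfg$burnin, " samplefreq=", cfg$samplefreq,
            " chains=", cfg$chains, " max_areas=", cfg$max_areas,
            " seed=", cfg$seed)

  chron <- parse_chronogram(config$tree)
  coding <- read_region_codings(config$codings, config$alphabet)
  validate_tip_match(chron, coding)
  .log_line(logfile, "inputs: ", chron$n_tips, " tips, crown age ",
            format(chron$root_age, digits = 6), " Myr, ",
            length(config$alphabet), " areas")

  res <- run_bbm_mcmc(chron, coding, cfg, config$alphabet)
  .log_line(logfile, "pooled posterior samples: ", nrow(res$samples),
            " (expected ", n_posterior_samples(cfg), ")")
  .log_line(logfile, "mean acceptance: pi1 ",
            format(mean(res$diagnostics$accept_pi1), digits = 3),
            ", alpha ",
            format(mean(res$diagnostics$accept_alpha), digits = 3))

  rp <- do.call(rbind, lapply(names(res$range_posteriors), function(id)
    data.frame(node_id = id, range = names(res$range_posteriors[[id]]),
               probability = unname(res$range_posteriors[[id]]))))
  .write_tsv_atomic(rp, paths[["range_posteriors"]], hash)
  .write_tsv_atomic(res$samples, paths[["trace"]], hash)
  txt <- write_annotated_newick(chron, res$map_ranges, res$range_posteriors)
  tmp <- paste0(paths[["annotated"]], ".tmp")
  writeLines(txt, tmp)
  file.rename(tmp, paths[["annotated"]])
  .log_line(logfile, "artifacts written to ", out)
  invisible(as.list(paths))
}

# per-period event tallies mirroring the map figures: in-situ originations
# per region and transitions per from->to pair
.period_region_counts <- function(events, label, t_old, t_young) {
  sel <- events$time <= t_old + 1e-9 & events$time > t_young + 1e-9
  ev <- events[sel, , drop = FALSE]
  orig <- ev[ev$kind == "origination" & ev$in_situ, , drop = FALSE]
  trans <- ev[ev$kind == "transition", , drop = FALSE]
  rbind(
    if (nrow(orig)) {
      tab <- table(orig$region)
      data.frame(period = label, kind = "origination_in_situ",
                 from = NA_character_, region = names(tab),
                 count = as.integer(tab))
    },
    if (nrow(trans)) {
      tab <- table(paste(trans$from, trans$to, sep = ">"))
      parts <- strsplit(names(tab), ">", fixed = TRUE)
      data.frame(period = label, kind = "transition",
                 from = vapply(parts, `[`, "", 1L),
                 region = vapply(parts, `[`, "", 2L),
                 count = as.integer(tab))
    })
}

#' Run the events-and-rates stage
#'
#' Reads an annotated chronogram (every node carrying a MAP range), extracts
#' transition and origination events, computes sliding-window rate series
#' for both kinds, period summaries for the configured named periods (mean
#' and pooled per-lineage rates plus event counts and per-region tallies),
#' and LTT curves for the whole tree and each configured clade.
#'
#' @param config A `run_config`.
#' @param annotated Path to the annotated newick from [cmd_reconstruct()]
#'   (default: `annotated.nwk` in the output directory).
#' @return Invisibly, a named list of artifact paths.
#' @export
cmd_rates <- function(config, annotated = file.path(config$out, "annotated.nwk")) {
  out <- config$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logfile <- file.path(out, "run.log")
  hash <- .config_hash(config[c("tree", "codings", "alphabet", "rates")])
  .log_line(logfile, "rates: config hash ", hash)

  ann <- read_annotated_newick(annotated)
  chron <- ann$chron
  events <- extract_events(chron, ann$assignments)
  .log_line(logfile, "events: ",
            sum(events$kind == "transition"), " transitions, ",
            sum(events$kind == "origination"), " originations (",
            sum(events$in_situ, na.rm = TRUE), " in situ)")

  rc <- config$rates
  t_max <- rc$span_old %||% chron$root_age
  t_max <- min(t_max, chron$root_age)
  series <- list(
    transition = sliding_window_rates(events, chron, "transition",
                                      rc$window, t_max, rc$span_young),
    origination = sliding_window_rates(events, chron, "origination",
                                       rc$window, t_max, rc$span_young))
  paths <- c(events = file.path(out, "events.tsv"),
             transition_rates = file.path(out, "transition_rates.tsv"),
             origination_rates = file.path(out, "origination_rates.tsv"),
             period_summary = file.path(out, "period_summary.tsv"),
             region_counts = file.path(out, "region_counts.tsv"),
             ltt = file.path(out, "ltt.tsv"))
  on.exit(unlink(paste0(paths, ".tmp")), add = TRUE)
  .write_tsv_atomic(as.data.frame(events), paths[["events"]], hash)
  .write_tsv_atomic(as.data.frame(series$transition),
                    paths[["transition_rates"]], hash)
  .write_tsv_atomic(as.data.frame(series$origination),
                    paths[["origination_rates"]], hash)

  periods <- rc$periods
  if (!is.null(periods) && length(periods)) {
    summ <- do.call(rbind, lapply(periods, function(p) {
      do.call(rbind, lapply(names(series), function(kd) {
        sel <- events$kind == kd &
          events$time <= p$old + 1e-9 & events$time > p$young + 1e-9
        data.frame(period = p$label, old = p$old, young = p$young, kind = kd,
                   mean_rate = period_mean_rate(series[[kd]], p$old, p$young),
                   pooled_rate = period_mean_rate(series[[kd]], p$old,
                                                  p$young, pooled = TRUE),
                   events = sum(sel))
      }))
    }))
    .write_tsv_atomic(summ, paths[["period_summary"]], hash)
    counts <- do.call(rbind, lapply(periods, function(p)
      .period_region_counts(events, p$label, p$old, p$young)))
    if (is.null(counts))
      counts <- data.frame(period = character(0), kind = character(0),
                           from = character(0), region = character(0),
                           count = integer(0))
    .write_tsv_atomic(counts, paths[["region_counts"]], hash)
  }

  ltt <- ltt_curve(chron)
  ltt$clade <- "all"
  if (!is.null(config$clades)) {
    for (lab in names(config$clades)) {
      cl <- ltt_curve(chron, mrca_of = config$clades[[lab]])
      cl$clade <- lab
      ltt <- rbind(ltt, cl)
    }
  }
  .write_tsv_atomic(ltt, paths[["ltt"]], hash)

  if (isTRUE(config$plot)) {
    pdf_path <- file.path(out, "rates.pdf")
    grDevices::pdf(pdf_path, width = 8, height = 6)
    for (kd in names(series)) {
      cs <- cone_series(events, chron, kd, rc$cone,
                        grid_step = rc$window / 10, t_max, rc$span_young)
      plot(cs$age, cs$value, type = "l", xlim = rev(range(cs$age)),
           xlab = "age (mya)", ylab = "events per lineage per Myr",
           main = paste0(kd, " rate (cone width ", rc$cone, " Myr)"))
      graphics::points(series[[kd]]$window_old_edge, series[[kd]]$rate,
                       pch = 16, cex = 0.4, col = "grey40")
    }
    grDevices::dev.off()
    paths <- c(paths, plot = pdf_path)
  }
  .log_line(logfile, "rate artifacts written to ", out)
  invisible(as.list(paths))
}

#' Write an LTT table for the whole tree or a clade
#' @param config A `run_config`.
#' @param clade Optional clade label defined in the config.
#' @return Invisibly the output path.
#' @export
cmd_ltt <- function(config, clade = NULL) {
  chron <- parse_chronogram(config$tree)
  taxa <- if (!is.null(clade)) config$clades[[clade]]
  ltt <- ltt_curve(chron, mrca_of = taxa)
  path <- file.path(config$out,
                    paste0("ltt_", if (is.null(clade)) "all" else clade, ".tsv"))
  if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)
  .write_tsv_atomic(ltt, path)
  invisible(path)
}

#' Write a synthetic fixture (CLI convenience wrapper)
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly the fixture paths.
#' @export
cmd_simulate <- function(cfg = sim_config(), out_dir) {
  fx <- make_fixture(cfg, out_dir)
  invisible(fx$paths)
}
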