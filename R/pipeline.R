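#' Pipeline run configuration
#'
#' Declarative description of a full run: input paths, calendar, the
#' resolutions to materialize, per-target-zone selection and clustering
#' settings, and the fusion lag range. Can be written/read as YAML (see
#' [read_run_config()]) so runs are reproducible from a single document.
#'
#' @param events Path to the events CSV.
#' @param partition Path to the partition CSV.
#' @param out Output directory.
#' @param external Optional character vector of external-series CSV paths.
#' @param year Study year.
#' @param resolutions Coarse resolutions to materialize besides daily
#'   (subset of weekly/biweekly/monthly; monthly is always produced).
#' @param targets List of per-zone settings: each a list with `zone` and
#'   optionally `k`, `linkage` and [selection_config()] fields.
#' @param lag_range Correlation lag range in months.
#' @param seed Seed for any stochastic step.
#' @param strict Strict event validation.
#' @return A `run_config` list.
#' @export
run_config <- function(events, partition, out, external = character(),
                       year = 2013L, resolutions = "monthly",
                       targets = list(), lag_range = 3L, seed = 1L,
                       strict = FALSE) {
  resolutions <- union(resolutions, "monthly")
  bad <- setdiff(resolutions, c("weekly", "biweekly", "monthly"))
  if (length(bad)) stop("unknown resolution(s): ", paste(bad, collapse = ", "))
  for (tg in targets)
    if (is.null(tg$zone)) stop("every clustering target needs a zone")
  structure(list(events = events, partition = partition, out = out,
                 external = external, year = as.integer(year),
                 resolutions = resolutions, targets = targets,
                 lag_range = as.integer(lag_range), seed = as.integer(seed),
                 strict = isTRUE(strict)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("events", "partition", "out")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  run_config(events = y$events, partition = y$partition, out = y$out,
             external = as.character(y$external %||% character()),
             year = y$year %||% 2013L,
             resolutions = as.character(y$resolutions %||% "monthly"),
             targets = y$targets %||% list(),
             lag_range = y$lag_range %||% 3L,
             seed = y$seed %||% 1L,
             strict = y$strict %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

target_selection_config <- function(tg) {
  selection_config(
    target_zone = tg$zone,
    min_consecutive_months = tg$min_consecutive_months %||% 2L,
    max_months = tg$max_months %||% 11L,
    min_months_elsewhere = tg$min_months_elsewhere %||% 1L,
    required_period = tg$required_period,
    rog_ratio_threshold = tg$rog_ratio_threshold %||% 3,
    exclude_urban = tg$exclude_urban %||% FALSE,
    exclude_nonmoving = tg$exclude_nonmoving %||% TRUE)
}

#' Run the full mobility-profiling pipeline
#'
#' Executes the canonical stage order — ingest, daily regularization,
#' interpolation, time/space aggregation, population counts and signatures,
#' per-zone selection, Jaccard clustering, context fusion — writing every
#' intermediate artifact to the output directory plus a flat key=value
#' manifest with input checksums, stage timings and versions. Re-running on
#' identical inputs and config reproduces identical outputs.
#'
#' @param cfg A [run_config()].
#' @return The manifest as a named list, invisibly. Artifacts on disk:
#'   trajectory matrices (`itm_*.csv`), counts and signatures, per-zone
#'   audits, cluster labels and curves, fusion reports, `manifest.txt`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$events, cfg$partition, cfg$external))
    if (!file.exists(p)) stop("input not found: ", p)
  if (!dir.exists(cfg$out) && !dir.create(cfg$out, recursive = TRUE))
    stop("cannot create output directory ", cfg$out)
  set.seed(cfg$seed)
  manifest <- list(pipeline_version = as.character(utils::packageVersion("cdrmob")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed)
  for (p in c(events = cfg$events, partition = cfg$partition))
    manifest[[paste0("checksum_", basename(p))]] <- unname(tools::md5sum(p))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    message("[", name, "] starting")
    val <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest[[paste0("time_", name)]] <<- round(proc.time()[["elapsed"]] - s, 3)
    val
  }
  outfile <- function(...) file.path(cfg$out, paste0(...))

  cal <- study_calendar(cfg$year)
  part <- stage("ingest_partition", read_partition(cfg$partition))
  events <- stage("ingest_events",
                  read_events(cfg$events, part, cal, strict = cfg$strict))
  traj <- stage("trajectories", build_trajectories(events))
  tsum <- as.data.frame(traj[, list(n_visits = .N), by = "user_id"])
  utils::write.csv(tsum, outfile("trajectory_summary.csv"), row.names = FALSE)

  daily_raw <- stage("daily_regularization",
                     daily_preferential(traj, cal, part))
  daily <- stage("interpolation", interpolate_missing(daily_raw))
  write_itmatrix(daily, outfile("itm_daily_region.csv"))
  mats <- list()
  for (res in cfg$resolutions) {
    m <- stage(paste0("aggregate_", res), aggregate_time(daily, res, cal))
    mats[[res]] <- m
    write_itmatrix(m, outfile("itm_", res, "_region.csv"))
  }
  mpl <- stage("zone_mapping", aggregate_space(mats[["monthly"]], part))
  write_itmatrix(mpl, outfile("itm_monthly_zone.csv"))

  counts <- stage("population_counts", population_count(mpl))
  sig <- zscore_signature(counts)
  write_tidy_matrix(counts, outfile("counts_monthly_zone.csv"))
  write_tidy_matrix(sig, outfile("signatures_monthly_zone.csv"))
  raw_counts <- population_count(aggregate_space(
    aggregate_time(daily_raw, "monthly", cal), part))
  bias <- interpolation_bias(raw_counts, counts)
  utils::write.csv(data.frame(zone = names(bias$bias_pct),
                              bias_pct = unname(bias$bias_pct)),
                   outfile("interpolation_bias.csv"), row.names = FALSE)

  profile_sets <- list()
  for (tg in cfg$targets) {
    zn <- as.character(tg$zone)
    scfg <- target_selection_config(tg)
    sel <- stage(paste0("select_zone_", zn),
                 select_users(mpl, daily, part, scfg))
    utils::write.csv(sel$audit, outfile("selection_audit_zone", zn, ".csv"),
                     row.names = FALSE)
    if (length(sel$selected) == 0L) next
    B <- binarize(mpl, sel$selected, zn)
    ps <- stage(paste0("cluster_zone_", zn),
                hierarchical_profiles(B, k = tg$k %||% 3L,
                                      linkage = tg$linkage %||% "average"))
    profile_sets[[zn]] <- ps
    utils::write.csv(data.frame(user_id = names(ps$labels),
                                cluster = unname(ps$labels)),
                     outfile("clusters_zone", zn, ".csv"), row.names = FALSE)
    cc <- data.frame(cluster = rep(seq_len(ps$k), each = ncol(ps$curves)),
                     month = rep(seq_len(ncol(ps$curves)), ps$k),
                     count = as.vector(t(ps$curves)),
                     zscore = as.vector(t(ps$signatures)))
    utils::write.csv(cc, outfile("profile_curves_zone", zn, ".csv"),
                     row.names = FALSE)
  }

  if (length(cfg$external) && length(profile_sets)) {
    fusion <- stage("fusion", {
      rows <- list()
      align <- list()
      for (xp in cfg$external) {
        xs <- read_external_series(xp, cal, "monthly")
        for (zn in names(profile_sets)) {
          if (!zn %in% rownames(xs$values)) next
          ext_sig <- rescale_to_signature(xs, zn)
          ps <- profile_sets[[zn]]
          for (c in seq_len(ps$k)) {
            ct <- correlate_series(ps$signatures[c, ], ext_sig,
                                   cfg$lag_range)
            ct$zone <- zn; ct$series <- xs$name; ct$profile <- c
            rows[[length(rows) + 1L]] <- ct
          }
        }
        zs <- intersect(names(profile_sets), rownames(xs$values))
        if (length(zs))
          align[[length(align) + 1L]] <-
            cbind(series = xs$name,
                  event_alignment_report(profile_sets[zs], xs))
      }
      list(corr = if (length(rows)) do.call(rbind, rows) else NULL,
           align = if (length(align)) do.call(rbind, align) else NULL)
    })
    if (!is.null(fusion$corr))
      utils::write.csv(fusion$corr[, c("zone", "series", "profile", "lag",
                                       "correlation", "n")],
                       outfile("fusion_correlations.csv"), row.names = FALSE)
    if (!is.null(fusion$align))
      utils::write.csv(fusion$align, outfile("fusion_alignment.csv"),
                       row.names = FALSE)
  }
  manifest$time_total <- round(proc.time()[["elapsed"]] - t0, 3)
  manifest$n_users <- nrow(daily)
  manifest$rejected_records <- attr(events, "rejected")
  writeLines(sprintf("%s=%s", names(manifest),
                     vapply(manifest, as.character, character(1))),
             outfile("manifest.txt"))
  invisible(manifest)
}

write_tidy_matrix <- function(m, path) {
  df <- data.frame(zone = rep(rownames(m), ncol(m)),
                   bin = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(unclass(m)))
  df <- df[order(df$zone, df$bin), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
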