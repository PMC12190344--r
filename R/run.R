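# Configuration, reproducible scenario execution and output management.

#' Run configuration
#'
#' Assembles a validated run configuration. Precedence of values is
#' overrides > config file > defaults; all resolved values are echoed into
#' the run's metadata so a run is fully reconstructible from its outputs.
#'
#' @param model `"abm"` or `"cpm"`.
#' @param scenario scenario name ([abm_preset()] names for the ABM,
#'   [cpm_scenario()] names for the CPM).
#' @param seed integer seed.
#' @param n_steps steps (ABM) or MCS (CPM) to run.
#' @param out_dir output directory (created if missing).
#' @param snapshot_every snapshot interval in steps/MCS (0 disables
#'   intermediate snapshots; the final state is always written).
#' @param sample_every time-series sampling interval.
#' @param abm named list of [abm_params()] overrides.
#' @param cpm named list of [scene_spec()] overrides.
#' @param config_file optional YAML file; its sections (`model`, `scenario`,
#'   `seed`, `n_steps`, `snapshot_every`, `sample_every`, `abm:`, `cpm:`)
#'   are applied between the defaults and the explicit arguments.
#' @return a list of class `run_config`.
#' @export
run_config <- function(model = c("abm", "cpm"), scenario = NULL, seed = 1L,
                       n_steps = NULL, out_dir = tempfile("pllpsim-run-"),
                       snapshot_every = 0L, sample_every = NULL,
                       abm = list(), cpm = list(), config_file = NULL) {
  explicit <- list()
  if (!missing(model)) explicit$model <- match.arg(model)
  if (!is.null(scenario)) explicit$scenario <- scenario
  if (!missing(seed)) explicit$seed <- seed
  if (!is.null(n_steps)) explicit$n_steps <- n_steps
  if (!missing(out_dir)) explicit$out_dir <- out_dir
  if (!missing(snapshot_every)) explicit$snapshot_every <- snapshot_every
  if (!is.null(sample_every)) explicit$sample_every <- sample_every
  if (length(abm)) explicit$abm <- abm
  if (length(cpm)) explicit$cpm <- cpm

  cfg <- list(model = "abm", scenario = NULL, seed = 1L, n_steps = NULL,
              out_dir = out_dir, snapshot_every = 0L, sample_every = NULL,
              abm = list(), cpm = list())
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    fc <- yaml::read_yaml(config_file)
    cfg <- utils::modifyList(cfg, fc[!vapply(fc, is.null, TRUE)])
  }
  cfg <- utils::modifyList(cfg, explicit)
  cfg$model <- match.arg(cfg$model, c("abm", "cpm"))
  if (is.null(cfg$scenario))
    cfg$scenario <- if (cfg$model == "abm") "abm_fast_leader" else "wildtype"
  valid <- if (cfg$model == "abm")
    c("abm_no_migration", "abm_fast_leader", "abm_slow_leader",
      "abm_shrinking_wnt")
  else c("wildtype", "stall_leading", "stall_then_recover",
         "boost_lat_contractility")
  if (!cfg$scenario %in% valid)
    stop("unknown scenario '", cfg$scenario, "' for model '", cfg$model,
         "'; valid choices: ", paste(valid, collapse = ", "))
  if (is.null(cfg$n_steps))
    cfg$n_steps <- if (cfg$model == "abm") 2000L else 2000L
  if (is.null(cfg$sample_every))
    cfg$sample_every <- if (cfg$model == "abm") 100L else 50L
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_steps <- as.integer(cfg$n_steps)
  class(cfg) <- "run_config"
  cfg
}

#' Execute a configured run
#'
#' Runs the chosen model and scenario with the seeded generator and writes,
#' under the configured output directory: `timeseries.csv`, periodic and
#' final snapshots (agent-table CSV for the ABM; lattice integer-array text,
#' cell-table CSV for the CPM; PNG renders for both), `summary.json`, and
#' `metadata.json` echoing every resolved configuration value. Identical
#' configuration and seed give bit-identical CSV output.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the simulation object (`sim`) and the
#'   paths of all written files (`files`).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop("cannot create output directory: ", config$out_dir)
  files <- character(0)
  snap_dir <- file.path(config$out_dir, "snapshots")

  if (config$model == "abm") {
    params <- do.call(abm_preset, c(list(name = config$scenario), config$abm))
    sim <- run_abm(params, n_steps = config$n_steps, seed = config$seed,
                   sample_every = config$sample_every)
    series <- sim$series
    snap <- function(state, tag) {
      dir.create(snap_dir, showWarnings = FALSE)
      f1 <- file.path(snap_dir, paste0("agents-", tag, ".csv"))
      utils::write.csv(state$agents, f1, row.names = FALSE)
      f2 <- file.path(snap_dir, paste0("agents-", tag, ".png"))
      grDevices::png(f2, width = 700, height = 350)
      op <- graphics::par(mfrow = c(1, 2))
      plot(state, mode = "breed", main = paste("step", state$step_index))
      plot(state, mode = "density", main = "density")
      graphics::par(op)
      grDevices::dev.off()
      c(f1, f2)
    }
    if (config$snapshot_every > 0) {
      # re-run with interleaved snapshots for exact reproducibility
      set.seed(config$seed)
      state <- init_abm(params)
      files <- c(files, snap(state, sprintf("%06d", 0L)))
      for (i in seq_len(config$n_steps)) {
        state <- step_abm(state, params)
        if (i %% config$snapshot_every == 0L)
          files <- c(files, snap(state, sprintf("%06d", i)))
      }
      sim$state <- state
    }
    files <- c(files, snap(sim$state, "final"))
    terminal <- list(n_clusters = series$n_clusters[nrow(series)],
                     n_agents = series$n_agents[nrow(series)],
                     n_depositer = series$n_depositer[nrow(series)])
  } else {
    spec <- do.call(scene_spec, config$cpm)
    snap_state <- function(state, tag) {
      dir.create(snap_dir, showWarnings = FALSE)
      f1 <- file.path(snap_dir, paste0("lattice-", tag, ".txt"))
      utils::write.table(state$lattice, f1, row.names = FALSE,
                         col.names = FALSE)
      f2 <- file.path(snap_dir, paste0("cells-", tag, ".csv"))
      utils::write.csv(cpm_cells(state), f2, row.names = FALSE)
      f3 <- file.path(snap_dir, paste0("scene-", tag, ".png"))
      grDevices::png(f3, width = 800, height = 320)
      plot(state, main = paste("MCS", state$mcs))
      grDevices::dev.off()
      c(f1, f2, f3)
    }
    scen <- cpm_scenario(config$scenario)
    set.seed(config$seed)
    state <- build_primordium_scene(spec)
    reports <- list(detect_rosettes_cpm(state))
    if (config$snapshot_every > 0)
      files <- c(files, snap_state(state, sprintf("%06d", 0L)))
    t <- 0L
    while (t < config$n_steps) {
      state <- apply_scenario(state, scen, t)
      chunk <- min(config$sample_every, config$n_steps - t)
      state <- cpm_step(state, chunk)
      t <- t + chunk
      reports[[length(reports) + 1]] <- detect_rosettes_cpm(state)
      if (config$snapshot_every > 0 && t %% config$snapshot_every == 0L)
        files <- c(files, snap_state(state, sprintf("%06d", t)))
      if (t %% 1000L == 0L)
        message("mcs ", t, "/", config$n_steps, " rosettes ",
                reports[[length(reports)]]$n_rosettes)
    }
    sim <- structure(list(series = report_series(reports), reports = reports,
                          state = state, scenario = scen,
                          seed = config$seed, burn_in = 200L),
                     class = "cpm_sim")
    series <- sim$series
    files <- c(files, snap_state(state, "final"))
    tc <- terminal_count(sim)
    terminal <- list(n_rosettes = as.integer(tc),
                     settled = attr(tc, "settled"),
                     settling_time = attr(tc, "settling_time"))
  }

  ts_file <- file.path(config$out_dir, "timeseries.csv")
  utils::write.csv(series, ts_file, row.names = FALSE)
  files <- c(ts_file, files)

  meta_file <- file.path(config$out_dir, "metadata.json")
  jsonlite::write_json(unclass(config), meta_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  summary_file <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(
    list(model = config$model, scenario = config$scenario,
         seed = config$seed, n_steps = config$n_steps,
         terminal = terminal,
         files = c(basename(meta_file), "summary.json",
                   sub(paste0("^", config$out_dir, "/?"), "", files))),
    summary_file, auto_unbox = TRUE, digits = NA)
  files <- c(files, meta_file, summary_file)
  invisible(list(sim = sim, files = files))
}

#' Parameter sweep
#'
#' Runs the cross-product of a parameter grid and a seed list on top of a
#' base configuration and aggregates terminal cluster/rosette counts.
#'
#' @param base a [run_config()].
#' @param grid named list of parameter-value vectors; names refer to fields
#'   of the model's parameter section (`abm` or `cpm`).
#' @param seeds integer vector of seeds (must be non-empty).
#' @param out_csv optional path for the summary CSV.
#' @return data frame with one row per grid cell: the grid values,
#'   `mean_terminal`, `sd_terminal`, and per-seed terminal counts
#'   (`terminal_seed<seed>`).
#' @export
sweep_runs <- function(base, grid, seeds, out_csv = NULL) {
  stopifnot(inherits(base, "run_config"))
  if (!length(seeds)) stop("at least one seed is required")
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  if (!nrow(cells)) cells <- data.frame(row.names = 1)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    terms <- numeric(length(seeds))
    for (k in seq_along(seeds)) {
      cfg <- base
      cfg$seed <- as.integer(seeds[k])
      cfg$out_dir <- file.path(base$out_dir,
                               sprintf("cell%03d-seed%d", i, seeds[k]))
      sect <- if (cfg$model == "abm") "abm" else "cpm"
      if (ncol(cells))
        cfg[[sect]] <- utils::modifyList(cfg[[sect]],
                                         as.list(cells[i, , drop = FALSE]))
      res <- run_simulation(cfg)
      s <- res$sim$series
      terms[k] <- if (!is.null(s$n_rosettes)) s$n_rosettes[nrow(s)]
                  else s$n_clusters[nrow(s)]
    }
    row <- cells[i, , drop = FALSE]
    row$mean_terminal <- mean(terms)
    row$sd_terminal <- stats::sd(terms)
    for (k in seq_along(seeds))
      row[[paste0("terminal_seed", seeds[k])]] <- terms[k]
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
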