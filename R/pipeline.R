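# Pipeline orchestration: a single entry point dispatching to the package's
# stages (synth, expression, fitness, analyze, simulate, power) from a flat
# YAML configuration or an in-memory list, with deterministic seeding and a
# machine-readable run-metadata sidecar next to every output.

#' Read a flat YAML run configuration
#'
#' @param path YAML file of flat key-value pairs.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  yaml::read_yaml(path)
}

#' Read and validate a genotype panel TSV
#'
#' @param path TSV with columns `genotype_id`, `median_expression_pct`,
#'   `noise_pct`, `fitness`.
#' @return Data frame; a schema violation raises an error naming the
#'   offending column.
#' @export
read_panel_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("panel file not found: %s", path),
                               call. = FALSE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genotype_id", "median_expression_pct", "noise_pct", "fitness")
  for (col in need) {
    if (!col %in% names(d))
      stop(sprintf("panel file %s: missing required column '%s'", path, col),
           call. = FALSE)
    if (col != "genotype_id" && !is.numeric(d[[col]]))
      stop(sprintf("panel file %s: column '%s' is not numeric", path, col),
           call. = FALSE)
  }
  d
}

#' Write a genotype panel TSV
#' @param panel Panel data frame. @param path Output file.
#' @export
write_panel_tsv <- function(panel, path) {
  write.table(panel, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_sidecar <- function(path, stage, params) {
  meta <- list(stage = stage, seed = params$seed %||% NA,
               parameters = params,
               package = "noisefit",
               version = as.character(utils::packageVersion("noisefit")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

#' Run a pipeline stage
#'
#' Dispatches on `config$stage` ("synth", "analyze", "expression",
#' "fitness", "simulate" or "power"), executes the stage with the package
#' functions, writes tab-separated outputs under `config$out_dir` together
#' with a JSON metadata sidecar recording the parameters and seed, and
#' returns the results invisibly. Configuration may be a named list or a
#' path to a flat YAML file; entries in `...` override file values.
#'
#' @param config Named list or YAML path. Common fields: `stage`, `seed`,
#'   `out_dir`. Stage-specific fields mirror the corresponding function
#'   arguments (e.g. `n_genotypes`, `noise_effect` for "synth";
#'   `panel` path, `span`, `fitness_drop`, `noise_metric`,
#'   `n_permutations` for "analyze").
#' @param ... Overrides applied on top of `config`.
#' @return Invisible list with the stage results and output paths.
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config)) config <- read_run_config(config)
  over <- list(...)
  config[names(over)] <- over
  stage <- config$stage %||% stop("config lacks 'stage'", call. = FALSE)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  res <- switch(
    stage,
    synth = {
      sp <- gen_study_panel(
        n_genotypes = as.integer(config$n_genotypes %||% 43L),
        noise_effect = config$noise_effect %||% 1e-4,
        seed = seed,
        emit = config$emit %||% character(0))
      panel_path <- file.path(out_dir, "panel.tsv")
      truth_path <- file.path(out_dir, "truth.tsv")
      write_panel_tsv(sp$panel, panel_path)
      write_truth_tsv(sp$truth, truth_path)
      write_sidecar(panel_path, "synth",
                    config[setdiff(names(config), "stage")])
      list(panel = sp$panel, truth = sp$truth,
           paths = c(panel = panel_path, truth = truth_path))
    },
    analyze = {
      panel <- if (is.data.frame(config$panel)) config$panel else
        read_panel_tsv(config$panel)
      cfg <- analysis_config(
        span_noise = config$span %||% 2 / 3,
        span_fitness = config$span %||% 2 / 3,
        fitness_drop = config$fitness_drop %||% 0.005,
        n_permutations = as.integer(config$n_permutations %||% 100000L),
        seed = seed)
      an <- analyze_noise_fitness(panel, cfg)
      delta_path <- file.path(out_dir, "delta_table.tsv")
      write.table(as.data.frame(an$delta_table), delta_path, sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write_sidecar(delta_path, "analyze",
                    config[setdiff(names(config), c("stage", "panel"))])
      if (isTRUE(config$grid)) {
        grid_path <- file.path(out_dir, "robustness_grid.tsv")
        write.table(robustness_grid(panel, cfg), grid_path, sep = "\t",
                    row.names = FALSE, quote = FALSE)
      }
      c(an, list(paths = c(delta_table = delta_path)))
    },
    expression = {
      files <- config$events %||% stop("'events' paths required", call. = FALSE)
      cal <- mrna_calibration(config$cal_a %||% 10.469,
                              config$cal_b %||% -9.586)
      rows <- do.call(rbind, lapply(files, function(f) {
        expression_from_events(read_event_csv(f), cal = cal,
                               min_cells = config$min_cells %||% 1000L)
      }))
      path <- file.path(out_dir, "expression.tsv")
      write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
      write_sidecar(path, "expression",
                    config[setdiff(names(config), "stage")])
      list(samples = rows, paths = c(expression = path))
    },
    fitness = {
      files <- config$series %||% stop("'series' paths required", call. = FALSE)
      rows <- do.call(rbind, lapply(files, function(f) {
        s <- read.csv(f)
        fit <- fitness_from_series(s)
        data.frame(file = f, w = fit$w, ci_lo = fit$ci95[[1L]],
                   ci_hi = fit$ci95[[2L]])
      }))
      path <- file.path(out_dir, "fitness.tsv")
      write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
      write_sidecar(path, "fitness", config[setdiff(names(config), "stage")])
      list(fitness = rows, paths = c(fitness = path))
    },
    simulate = {
      grid <- data.frame(mu_E = config$mu, nu_E = config$noise)
      cfg <- sim_config(T = config$T %||% 1000,
                        seed_cells = as.integer(config$seed_cells %||% 1000L),
                        replicates = as.integer(config$replicates %||% 100L))
      res <- sweep_fitness(grid, cfg,
                           noise_metric = config$metric %||% "sd",
                           dt_kind = config$dt %||% "gaussian", seed = seed)
      path <- file.path(out_dir, "simulation.tsv")
      write.table(as.data.frame(res), path, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      write_sidecar(path, "simulate", config[setdiff(names(config), "stage")])
      list(result = res, paths = c(simulation = path))
    },
    power = {
      grid <- if (is.data.frame(config$grid)) config$grid else
        read.delim(config$grid)
      res <- power_sweep(grid, power_config(
        n_sims = as.integer(config$sims %||% 5000L)), seed = seed)
      path <- file.path(out_dir, "power.tsv")
      write.table(res, path, sep = "\t", row.names = FALSE, quote = FALSE)
      write_sidecar(path, "power", config[setdiff(names(config), "stage")])
      list(result = res, paths = c(power = path))
    },
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
  )
  invisible(res)
}
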