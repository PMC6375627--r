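config_schema <- list(
  top = c("model", "task", "seed", "output"),
  model = c("family", "params", "omega", "mu", "epsilon", "cost_on_death"),
  task_common = c("name"),
  task = list(
    "list-models" = character(0),
    manifold = c("grid_size"),
    stationary = c("grid_size", "delta"),
    "simulate-ssa" = c("initial_counts", "t_max", "stop", "max_events",
                       "record", "thin_dt", "bins", "burn_in"),
    "simulate-sde" = c("p0", "t_max", "dt", "bins", "burn_in", "thin"),
    "optimal-nu" = c("family", "params"),
    "scan-reversal" = c("omega_values", "epsilon_values", "grid_size"),
    "sweep-mu" = c("mu_values", "grid_size"),
    compare = c("t_max", "burn_in", "bins", "replicates", "grid_size")
  )
)

#' Read and validate a run configuration
#'
#' Run configurations are YAML files with the strict schema
#' `model` (family, params, omega, mu, epsilon, cost_on_death),
#' `task` (name plus task-specific settings), `seed`, and `output`
#' (directory). Unknown keys are rejected with the offending key path;
#' a valid configuration round-trips losslessly through YAML.
#'
#' @param path YAML file path.
#' @return A validated `demsoc_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as from [yaml::read_yaml()]).
#' @export
validate_run_config <- function(cfg) {
  reject_unknown(cfg, config_schema$top, "")
  if (is.null(cfg$task$name)) {
    stop("config error at task$name: missing", call. = FALSE)
  }
  task_name <- cfg$task$name
  if (!task_name %in% names(config_schema$task)) {
    stop(sprintf("config error at task$name: unknown task '%s'", task_name),
         call. = FALSE)
  }
  reject_unknown(cfg$task,
                 c(config_schema$task_common, config_schema$task[[task_name]]),
                 "task$")
  needs_model <- !task_name %in% c("list-models", "optimal-nu")
  if (needs_model) {
    if (is.null(cfg$model)) stop("config error at model: missing",
                                 call. = FALSE)
    reject_unknown(cfg$model, config_schema$model, "model$")
    for (key in c("family", "omega")) {
      if (is.null(cfg$model[[key]])) {
        stop(sprintf("config error at model$%s: missing", key),
             call. = FALSE)
      }
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "demsoc_config")
}

reject_unknown <- function(x, allowed, prefix) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("config error at %s%s: unknown key", prefix, unknown[1]),
         call. = FALSE)
  }
  invisible(x)
}

config_model <- function(cfg) {
  m <- cfg$model
  make_model(m$family, m$params %||% list(), omega = m$omega,
             mu = m$mu %||% 0, epsilon = m$epsilon %||% 0,
             cost_on_death = m$cost_on_death %||% TRUE)
}

config_hash <- function(cfg) {
  rlang::hash(cfg[setdiff(names(cfg), "output")])
}

#' Execute a run configuration
#'
#' Maps a validated configuration deterministically to a set of
#' artifacts: a tab-separated results table and a JSON summary (config
#' hash, package version, seed, headline numbers) in the configured
#' output directory. The same configuration and seed always produce
#' byte-identical summaries.
#'
#' @param cfg A `demsoc_config` (or path to a YAML file).
#' @param output Output directory override.
#' @param dry_run If `TRUE`, print the resolved plan and compute nothing.
#' @return Invisibly, a list with `table` (tibble), `summary` (list) and
#'   the written file paths (`NULL` when no output directory is set).
#' @export
run_config <- function(cfg, output = NULL, dry_run = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(unclass(cfg))
  out_dir <- output %||% cfg$output
  task <- cfg$task$name
  if (dry_run) {
    cat("plan:", task, "| seed:", cfg$seed,
        "| config hash:", config_hash(cfg), "\n")
    return(invisible(NULL))
  }
  set.seed(cfg$seed)
  res <- switch(task,
    "list-models" = list(table = list_models(), summary = list()),
    manifold = run_task_manifold(cfg),
    stationary = run_task_stationary(cfg),
    "simulate-ssa" = run_task_ssa(cfg),
    "simulate-sde" = run_task_sde(cfg),
    "optimal-nu" = run_task_optimal(cfg),
    "scan-reversal" = run_task_reversal(cfg),
    "sweep-mu" = run_task_sweep(cfg),
    compare = run_task_compare(cfg)
  )
  summary <- c(
    list(task = task, seed = cfg$seed, config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("demsoc"))),
    res$summary
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    table_path <- file.path(out_dir, paste0(gsub("-", "_", task), ".tsv"))
    header <- sprintf("# demsoc %s | task: %s | seed: %d | config: %s",
                      summary$package_version, task, cfg$seed,
                      summary$config_hash)
    writeLines(header, table_path)
    suppressWarnings(utils::write.table(
      res$table, table_path, sep = "\t", row.names = FALSE,
      quote = FALSE, append = TRUE))
    json_path <- file.path(out_dir, paste0(gsub("-", "_", task), ".json"))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(table = table_path, summary = json_path)
  }
  invisible(list(table = res$table, summary = summary, paths = paths))
}

run_task_manifold <- function(cfg) {
  model <- config_model(cfg)
  tab <- slow_manifold(model, grid_size = cfg$task$grid_size %||% 401L)
  list(table = tab,
       summary = list(family = model$family,
                      n_range = range(tab$n),
                      ratio_range = range(tab$ratio)))
}

run_task_stationary <- function(cfg) {
  model <- config_model(cfg)
  d <- stationary_density(model, grid_size = cfg$task$grid_size %||% 4001L,
                          delta = cfg$task$delta %||% 1e-4)
  fav <- if (d$integrable) favourability(d) else NULL
  list(table = d$grid,
       summary = c(list(family = model$family,
                        integrable = d$integrable,
                        exponents = as.list(d$exponents)),
                   if (!is.null(fav))
                     as.list(fav[1, setdiff(names(fav), "integrable")])))
}

run_task_ssa <- function(cfg) {
  model <- config_model(cfg)
  tk <- cfg$task
  sim <- simulate_ssa(model, unlist(tk$initial_counts),
                      t_max = tk$t_max %||% Inf,
                      stop = tk$stop %||% "t_max",
                      seed = cfg$seed,
                      max_events = tk$max_events %||% 1e8,
                      record = tk$record %||% "thin",
                      thin_dt = tk$thin_dt %||% 1,
                      bins = tk$bins %||% 50L,
                      burn_in = tk$burn_in %||% 0)
  list(table = sim$trajectory %||% sim$occupancy,
       summary = list(family = model$family, events = sim$events,
                      stop_reason = sim$stop_reason,
                      final = as.list(sim$final),
                      mean_density = sim$mean_density))
}

run_task_sde <- function(cfg) {
  model <- config_model(cfg)
  tk <- cfg$task
  sim <- simulate_frequency_sde(model, p0 = tk$p0 %||% 0.5,
                                t_max = tk$t_max, dt = tk$dt,
                                seed = cfg$seed, bins = tk$bins %||% 50L,
                                burn_in = tk$burn_in %||% 0,
                                thin = tk$thin %||% 10L)
  list(table = sim$path,
       summary = list(family = model$family, dt = sim$dt,
                      boundary_time = sim$boundary_time,
                      p_end = sim$path$p[nrow(sim$path)]))
}

run_task_optimal <- function(cfg) {
  tab <- optimal_social_action(cfg$task$family, cfg$task$params)
  list(table = tab, summary = as.list(tab[1, ]))
}

run_task_reversal <- function(cfg) {
  model <- config_model(cfg)
  tab <- reversal_scan(model, unlist(cfg$task$omega_values),
                       unlist(cfg$task$epsilon_values),
                       grid_size = cfg$task$grid_size %||% 2001L)
  list(table = tab,
       summary = list(family = model$family,
                      n_reversals = sum(tab$reversal, na.rm = TRUE)))
}

run_task_sweep <- function(cfg) {
  model <- config_model(cfg)
  tab <- mutation_sweep(model, unlist(cfg$task$mu_values),
                        grid_size = cfg$task$grid_size %||% 2001L)
  list(table = tab,
       summary = list(family = model$family,
                      shapes = paste(tab$shape, collapse = " -> ")))
}

# exact-process occupancy versus the analytic stationary density
run_task_compare <- function(cfg) {
  model <- config_model(cfg)
  tk <- cfg$task
  bins <- tk$bins %||% 40L
  t_max <- tk$t_max %||% 20000
  burn_in <- tk$burn_in %||% max(0.05 * t_max, 1)
  replicates <- tk$replicates %||% 4L
  p0 <- 0.5
  n0 <- quasi_equilibrium_density(model, p0)
  N0 <- round(model$omega * n0 * c(p0, 1 - p0))
  seeds <- derive_seeds(cfg$seed, replicates)
  weight <- numeric(bins)
  for (s in seeds) {
    sim <- simulate_ssa(model, N0, t_max = t_max, seed = s,
                        record = "none", bins = bins, burn_in = burn_in)
    weight <- weight + sim$occupancy$weight
  }
  emp <- weight / sum(weight)
  d <- stationary_density(model, grid_size = tk$grid_size %||% 4001L)
  edges <- seq(0, 1, length.out = bins + 1)
  bin_of <- pmin(findInterval(d$grid$p, edges, rightmost.closed = TRUE),
                 bins)
  w <- c(diff(d$grid$p) / 2, 0) + c(0, diff(d$grid$p) / 2)
  ana <- tapply(d$grid$density * w, bin_of, sum)
  ana_mass <- numeric(bins)
  ana_mass[as.integer(names(ana))] <- ana
  ana_mass <- ana_mass / sum(ana_mass)
  list(
    table = tibble::tibble(
      p_mid = (seq_len(bins) - 0.5) / bins,
      simulated = emp,
      analytic = ana_mass
    ),
    summary = list(family = model$family,
                   total_variation = 0.5 * sum(abs(emp - ana_mass)),
                   t_max = t_max, replicates = replicates)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
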