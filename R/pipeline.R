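# Pipeline orchestration: each step reads and writes the package's
# file dialects so an analysis can be scripted end to end from a YAML
# configuration. A thin command-line front-end wrapping these
# functions ships in inst/cli/clinemap.

#' Read a pipeline configuration
#'
#' YAML with (all optional, defaults shown by [default_config()]):
#' `output_dir`; `world` (path to a world spec for simulation);
#' `records` (record CSV path); `grid: cell_size`; `fixation: lo, hi,
#' min_n`; `cline: transect (JSON path), locus, model ("select" or
#' scaling/tails pair), chains, burn_in, generations, thin, seed`;
#' `gls: covariates, response`.
#'
#' @param path YAML file path.
#' @return config list (class `clinemap_config`).
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  structure(cfg, class = "clinemap_config")
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(output_dir = ".",
       world = NULL,
       records = NULL,
       grid = list(cell_size = 4),
       fixation = list(lo = 0.05, hi = 0.95, min_n = 1),
       cline = list(transect = NULL, locus = "A", model = "select",
                    chains = 3, burn_in = 1e4, generations = 1e5,
                    thin = 10, seed = NULL),
       gls = list(covariates = c("bio01", "bio20", "bio12", "bio28"),
                  response = "dominant_class", locus = "B"))
}

.out_path <- function(config, ...) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$output_dir, ...)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes `records.csv` (record dialect), `env.csv` (environmental
#' cell dialect at the configured cell size) and `truth.json` (the
#' complete generating world, round-trippable via [read_world()]).
#'
#' @param config a config list ([read_config()]); its `world` entry
#'   may be a path or a [world_spec] (default world if `NULL`).
#' @param seed optional override of the world's seed.
#' @return invisibly, the written paths.
#' @export
run_simulate <- function(config = default_config(), seed = NULL) {
  world <- config$world
  if (is.null(world)) world <- world_spec()
  else if (is.character(world)) world <- read_world(world)
  if (!is.null(seed)) world$seed <- seed
  ds <- sample_records(world)
  grid <- build_grid(ds, grid_spec(config$grid$cell_size))
  env <- attach_environment(ds, grid, world, locus = config$gls$locus,
                            response = config$gls$response)
  paths <- c(records = .out_path(config, "records.csv"),
             env = .out_path(config, "env.csv"),
             truth = .out_path(config, "truth.json"))
  write_records(ds, paths["records"])
  utils::write.csv(env, paths["env"], row.names = FALSE)
  write_world(world, paths["truth"])
  invisible(paths)
}

#' Grid a record file and summarise fixation
#'
#' Writes `grid.csv` (one row per occupied cell) and
#' `fixation.json` (per-locus percentages of cells in each fixation
#' class, plus source counts).
#'
#' @inheritParams run_simulate
#' @param records_path record CSV (default from config).
#' @return invisibly, list with the grid and written paths.
#' @export
run_grid <- function(config = default_config(), records_path = NULL) {
  path <- if (is.null(records_path)) config$records else records_path
  ds <- read_records(path)
  grid <- build_grid(ds, grid_spec(config$grid$cell_size))
  fx <- config$fixation
  fixation <- lapply(c(A = "A", B = "B", C = "C"), function(locus) {
    res <- tryCatch(
      fixation_summary(grid, locus, min_n = fx$min_n,
                       lo = fx$lo, hi = fx$hi),
      error = function(e) NULL)
    if (is.null(res)) NULL
    else list(percent = as.list(res$percent), n_cells = res$n_cells)
  })
  out <- c(grid = .out_path(config, "grid.csv"),
           fixation = .out_path(config, "fixation.json"))
  write_grid(grid, out["grid"])
  jsonlite::write_json(
    list(cell_size = config$grid$cell_size,
         n_cells = nrow(grid$cells),
         sources = summarize_sources(ds),
         fixation = fixation),
    out["fixation"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(grid = grid, paths = out))
}

#' Fit a cline for one locus along one transect, to disk
#'
#' Writes `cline_<transect>_<locus>.json` (model table, ML and
#' posterior summaries, diagnostics) and the matching envelope CSV
#' (`x_km,p_lo,p_med,p_hi`).
#'
#' @inheritParams run_simulate
#' @param grid a `frequency_grid` (or `NULL` to grid
#'   `config$records`).
#' @return invisibly, the [fit_cline()] object.
#' @export
run_cline <- function(config = default_config(), grid = NULL) {
  if (is.null(grid))
    grid <- run_grid(config)$grid
  cc <- config$cline
  t <- if (inherits(cc$transect, "transect")) cc$transect
       else read_transect(cc$transect)
  model <- cc$model
  if (is.list(model) && !inherits(model, "cline_model_spec"))
    model <- cline_model_spec(model$scaling, model$tails)
  fit <- fit_cline(grid, t, cc$locus, model = model, chains = cc$chains,
                   burn_in = cc$burn_in, generations = cc$generations,
                   thin = cc$thin, seed = cc$seed)
  stem <- paste0("cline_", gsub("[^A-Za-z0-9]+", "-", t$name), "_",
                 cc$locus)
  write_cline_fit(fit,
                  json_path = .out_path(config, paste0(stem, ".json")),
                  envelope_path = .out_path(config,
                                            paste0(stem, "_envelope.csv")))
  invisible(fit)
}

#' Environmental association analysis, to disk
#'
#' Writes `envassoc.json`: the 16-model GLS AIC table, the best
#' model's coefficient table, the VIF table, the univariate screens
#' and the per-covariate criteria report.
#'
#' @inheritParams run_simulate
#' @param env_cells environmental cell table (or `NULL` to read
#'   `env.csv` from the output directory).
#' @return invisibly, list with the component results.
#' @export
run_envassoc <- function(config = default_config(), env_cells = NULL) {
  if (is.null(env_cells))
    env_cells <- utils::read.csv(.out_path(config, "env.csv"))
  covs <- config$gls$covariates
  mg <- gls_model_grid(env_cells, covs)
  screens <- env_screens(env_cells, covs)
  vifs <- vif(env_cells[, covs])
  crit <- criteria_report(mg, screens)
  best <- attr(mg, "fits")[[1]]
  jsonlite::write_json(
    list(models = mg[, c("formula", "k", "logL", "aic", "delta_aic")],
         best = list(formula = paste(best$covariates, collapse = " + "),
                     beta = as.list(best$beta), se = as.list(best$se),
                     p = as.list(best$p), rho = best$rho,
                     aic = best$aic),
         vif = as.list(vifs),
         screens = screens,
         criteria = crit),
    .out_path(config, "envassoc.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(models = mg, screens = screens, vif = vifs,
                 criteria = crit))
}

#' Run the full pipeline: simulate, grid, cline, environment
#'
#' @inheritParams run_simulate
#' @return invisibly, list of the step results.
#' @export
run_all <- function(config = default_config(), seed = NULL) {
  sim_paths <- run_simulate(config, seed = seed)
  config$records <- unname(sim_paths["records"])
  gr <- run_grid(config)
  cline_fit <- if (!is.null(config$cline$transect))
    run_cline(config, grid = gr$grid)
  env <- run_envassoc(config,
                      env_cells = utils::read.csv(sim_paths["env"]))
  invisible(list(simulate = sim_paths, grid = gr, cline = cline_fit,
                 envassoc = env))
}
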