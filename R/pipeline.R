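#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent nested list) with stage blocks
#' `simulate`, `idealize`, `stats`, `titration`, plus a global `seed`,
#' `outdir` and `figures` flag. Unknown keys are rejected by name, so typos
#' fail loudly; the configuration round-trips through the file unchanged.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return The validated configuration list (class `"run_config"`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a YAML file path or a list")
  schema <- list(
    seed = NULL, outdir = NULL, figures = NULL,
    simulate = list(duration = NULL, levels = NULL, occupancies = NULL,
                    mean_dwells = NULL,
                    acquisition = list(sample_rate = NULL, filter_corner = NULL,
                                       noise_sd = NULL, voltage = NULL,
                                       reversal = NULL, full_conductance = NULL,
                                       pH = NULL)),
    idealize = list(max_levels = NULL, dead_time = NULL, min_separation = NULL,
                    stay_prob = NULL),
    stats = list(burst_cutoff = NULL, same_level_only = NULL,
                 per_open_time = NULL),
    titration = list(pH_grid = NULL,
                     truth = list(K_H = NULL, K_OC = NULL, n_sites = NULL),
                     start = list(K_H = NULL, K_OC = NULL)))
  check_keys(config, schema, "config")
  defaults <- list(
    seed = 1L, outdir = file.path(tempdir(), "kirgate-run"), figures = TRUE,
    simulate = list(duration = 20, levels = c(0, 0.45, 0.74, 0.92, 1.00),
                    occupancies = c(0.06, 0.02, 0.07, 0.26, 0.59),
                    mean_dwells = 0.010,
                    acquisition = list(sample_rate = 3000, filter_corner = 1000,
                                       noise_sd = 0.3, voltage = -120,
                                       reversal = 0, full_conductance = 60,
                                       pH = 7.4)),
    idealize = list(max_levels = 5, dead_time = 5e-4, min_separation = 0.3,
                    stay_prob = 0.999),
    stats = list(burst_cutoff = 0.1, same_level_only = TRUE,
                 per_open_time = FALSE),
    titration = list(pH_grid = c(6.2, 6.5, 6.8, 7.1, 7.4, 7.7, 8.0),
                     truth = list(K_H = 2e-7, K_OC = 0.05, n_sites = 4),
                     start = list(K_H = 1e-6, K_OC = 0.1)))
  out <- utils::modifyList(defaults, config)
  class(out) <- c("run_config", class(out))
  out
}

check_keys <- function(x, schema, where) {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown))
    stop("unknown key '", unknown[1L], "' in ", where)
  for (nm in names(x)) {
    if (is.list(schema[[nm]]) && length(schema[[nm]]))
      check_keys(x[[nm]], schema[[nm]], paste0(where, "$", nm))
  }
  invisible(TRUE)
}

#' Run the full sub-state analysis pipeline
#'
#' Orchestrates simulate -> idealize -> stats -> titration fit with a single
#' global seed, writing a report bundle (JSON summary, CSV tables, optional
#' figures) into the configured output directory. All reported numbers are
#' a pure function of (config, seed); a stage failure raises an error while
#' preserving the outputs of the completed stages.
#'
#' @param config A YAML path, nested list, or validated `"run_config"`.
#' @return (Invisibly) the report list, also written to
#'   `<outdir>/report.json`.
#' @examples
#' \donttest{
#' cfg <- system.file("extdata", "demo.yaml", package = "kirgate")
#' rep <- run_pipeline(cfg)
#' rep$titration$K_H
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  message("[simulate] seed ", cfg$seed)
  trace <- stage("simulate", {
    acq <- do.call(acquisition_params, cfg$simulate$acquisition)
    tr <- simulate_occupancy_trace(cfg$simulate$levels,
                                   cfg$simulate$occupancies,
                                   cfg$simulate$mean_dwells, acq,
                                   duration = cfg$simulate$duration,
                                   seed = cfg$seed)
    write_trace(tr, file.path(cfg$outdir, "trace.csv"))
    tr
  })
  message("[idealize]")
  ideal <- stage("idealize", {
    lv <- detect_levels(trace,
                        expected_max_levels = cfg$idealize$max_levels,
                        min_separation = cfg$idealize$min_separation)
    ev <- idealize(trace, lv, dead_time = cfg$idealize$dead_time,
                   stay_prob = cfg$idealize$stay_prob)
    write_levels(lv, file.path(cfg$outdir, "levels.json"))
    write_events(ev, file.path(cfg$outdir, "events.csv"))
    list(levels = lv, events = ev)
  })
  report$levels <- list(current_pA = ideal$levels$current,
                        rel_amplitude = ideal$levels$rel_amplitude)
  message("[stats]")
  st <- stage("stats", {
    tm <- transition_matrix(ideal$events)
    occ <- occupancies(ideal$events)
    cls <- closure_stats(ideal$events, burst_cutoff = cfg$stats$burst_cutoff,
                         same_level_only = cfg$stats$same_level_only,
                         per_open_time = cfg$stats$per_open_time)
    list(transitions = unclass(tm), occupancies = occ, closures = cls)
  })
  report$occupancies <- as.list(st$occupancies)
  report$transition_matrix <- apply(st$transitions, 1L, as.integer,
                                    simplify = FALSE)
  report$closures <- st$closures[c("n", "frequency", "mean_dwell", "se_dwell")]
  message("[titration] fitting K_H, K_OC")
  tit <- stage("titration", {
    true_p <- model_params(site_class("HBC", cfg$titration$truth$n_sites,
                                      cfg$titration$truth$K_H),
                           K_OC = cfg$titration$truth$K_OC)
    tab <- predict_titration(true_p, cfg$titration$pH_grid)
    write_titration(tab, file.path(cfg$outdir, "titration.csv"))
    start <- model_params(site_class("HBC", cfg$titration$truth$n_sites,
                                     cfg$titration$start$K_H),
                          K_OC = cfg$titration$start$K_OC)
    fit_titration(tab, start)
  })
  cf <- coef(tit)
  report$titration <- list(K_H = unname(cf[[1L]]), K_OC = unname(cf[["K_OC"]]),
                           sse = tit$sse, converged = tit$convergence,
                           row_rmse = unname(sqrt(rowSums(tit$residuals^2))))
  if (isTRUE(cfg$figures)) {
    stage("figures", {
      grDevices::png(file.path(cfg$outdir, "trace.png"), 900, 500)
      n_show <- min(length(trace$times), 5 * trace$acquisition$sample_rate)
      graphics::plot(trace$times[1:n_show], trace$current[1:n_show],
                     type = "l", xlab = "time (s)", ylab = "current (pA)",
                     main = "simulated trace")
      graphics::abline(h = ideal$levels$current, col = 2, lty = 3)
      grDevices::dev.off()
      grDevices::png(file.path(cfg$outdir, "titration.png"), 700, 500)
      plot(tit, main = "titration fit")
      grDevices::dev.off()
    })
  }
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
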