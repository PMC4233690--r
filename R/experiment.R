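#' Specification of a full experiment
#'
#' Bundles every input of one of the study designs: the shared population
#' configuration, per-scenario sentence targets and initial prevalences, the
#' replicate count, horizon and base seed. Defaults reproduce the study
#' conditions for each experiment:
#' \describe{
#'   \item{fifty_year}{both scenarios initialised at 1\%, 600-month horizon.}
#'   \item{california}{black initialised at 1\%, white at 0.15\%, 300-month
#'     horizon (the 1986--2010 window).}
#'   \item{null_control}{non-contagious model; the spontaneous rate is tuned
#'     so the black scenario ends near the target prevalence (3\%), then both
#'     scenarios run at that rate, initialised at 1\%.}
#'   \item{ode_analysis}{contact ensembles are run, the population-wide mean
#'     transmission rate is calibrated from the pooled event logs, and the
#'     steady-state bifurcation sweep is emitted.}
#' }
#'
#' @param experiment one of "fifty_year", "california", "null_control",
#'   "ode_analysis".
#' @param population a \code{\link{population_config}}.
#' @param scenarios named list; each element has \code{sentence_mean},
#'   \code{sentence_median} (months) and \code{init_prevalence}.
#' @param n_replicates ensemble size per scenario.
#' @param horizon months simulated.
#' @param base_seed integer; every random stage derives its seed from it.
#' @param calibration_sentence s used to derive monthly rates from the survey
#'   marginals.
#' @param min_incarcerable_age,adult_child_age years; see
#'   \code{\link{epidemic_config}}.
#' @param null_target_prevalence,null_tolerance tuning target for the
#'   null-control experiment.
#' @return List of class \code{"experiment_spec"}.
#' @export
experiment_spec <- function(experiment = c("fifty_year", "california",
                                           "null_control", "ode_analysis"),
                            population = population_config(),
                            scenarios = NULL,
                            n_replicates = 250,
                            horizon = NULL,
                            base_seed = 1L,
                            calibration_sentence = 14,
                            min_incarcerable_age = 15,
                            adult_child_age = 18,
                            null_target_prevalence = 0.03,
                            null_tolerance = 0.003) {
  experiment <- match.arg(experiment)
  if (is.null(horizon))
    horizon <- if (experiment == "california") 300L else 600L
  if (is.null(scenarios)) {
    white_init <- if (experiment == "california") 0.0015 else 0.01
    scenarios <- list(
      black = list(sentence_mean = 17, sentence_median = 12,
                   init_prevalence = 0.01),
      white = list(sentence_mean = 14, sentence_median = 10,
                   init_prevalence = white_init))
  }
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    need <- c("sentence_mean", "sentence_median", "init_prevalence")
    if (!all(need %in% names(sc)))
      stop("scenario '", nm, "' must define ", paste(need, collapse = ", "))
  }
  if (!inherits(population, "population_config")) {
    population <- do.call(population_config, population)
  }
  out <- list(experiment = experiment, population = population,
              scenarios = scenarios, n_replicates = as.integer(n_replicates),
              horizon = as.integer(horizon), base_seed = as.integer(base_seed),
              calibration_sentence = calibration_sentence,
              min_incarcerable_age = min_incarcerable_age,
              adult_child_age = adult_child_age,
              null_target_prevalence = null_target_prevalence,
              null_tolerance = null_tolerance)
  class(out) <- "experiment_spec"
  out
}

.spec_fields <- c("experiment", "population", "scenarios", "n_replicates",
                  "horizon", "base_seed", "calibration_sentence",
                  "min_incarcerable_age", "adult_child_age",
                  "null_target_prevalence", "null_tolerance")

#' Load / save an experiment specification (JSON)
#'
#' The config file is a JSON object whose keys are the arguments of
#' \code{\link{experiment_spec}}; omitted keys take the documented defaults
#' and unknown keys raise a validation error naming the field. A minimal
#' config is \code{\{"experiment": "fifty_year"\}}. The load-save-load round
#' trip is the identity.
#'
#' @param path JSON file path.
#' @return A validated \code{experiment_spec}.
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  unknown <- setdiff(names(raw), .spec_fields)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$population)) {
    pop_unknown <- setdiff(names(raw$population),
                           names(formals(population_config)))
    if (length(pop_unknown))
      stop("unknown population field(s): ", paste(pop_unknown, collapse = ", "))
    for (f in c("friend_count_pmf", "children_count_pmf"))
      if (!is.null(raw$population[[f]]))
        raw$population[[f]] <- unlist(raw$population[[f]])
  }
  if (!is.null(raw$scenarios))
    raw$scenarios <- lapply(raw$scenarios, function(s) lapply(s, unlist))
  do.call(experiment_spec, raw)
}

#' @rdname load_config
#' @param spec an \code{experiment_spec}.
#' @export
save_config <- function(spec, path) {
  jsonlite::write_json(save_config_list(spec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.scenario_config <- function(spec, name, seed_offset, rate_table) {
  sc <- spec$scenarios[[name]]
  dist <- fit_sentence_nb(sc$sentence_mean, sc$sentence_median, label = name)
  epidemic_config(sentence_dist = dist, rate_table = rate_table,
                  init_prevalence = sc$init_prevalence,
                  horizon = spec$horizon, n_replicates = spec$n_replicates,
                  min_incarcerable_age = spec$min_incarcerable_age,
                  adult_child_age = spec$adult_child_age,
                  rng_seed = spec$base_seed + seed_offset, label = name)
}

#' Run a full experiment and write its outputs
#'
#' Generates the shared synthetic population once, runs the per-scenario
#' ensembles (contagious or spontaneous depending on the experiment),
#' computes recidivism tables, and writes population CSVs, event logs,
#' prevalence series, recidivism CSVs, an ensemble summary, a provenance
#' JSON carrying every parameter needed to reproduce the run, and PDF plots.
#' Re-running with the same spec reproduces identical CSVs.
#'
#' @param spec an \code{\link{experiment_spec}}.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the population, per-scenario ensembles,
#'   recidivism tables, and (as applicable) tuned rate or ODE calibration.
#' @export
run_experiment <- function(spec, out_dir, quiet = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  say("[%s] generating population (seed %d)", spec$experiment, spec$base_seed)
  population <- generate_population(spec$population, seed = spec$base_seed)
  write_population(population, file.path(out_dir, "agents.csv"),
                   file.path(out_dir, "ties.csv"))
  rate_table <- monthly_rate_table(survey_table(), spec$calibration_sentence)
  write_relation_table(rate_table, file.path(out_dir, "monthly_rates.csv"))

  ens <- list(); recid <- list(); extra <- list()
  tuned_rate <- NULL
  if (spec$experiment == "null_control") {
    tune_name <- if ("black" %in% names(spec$scenarios)) "black"
                 else names(spec$scenarios)[1]
    cfg_t <- .scenario_config(spec, tune_name, 0L, rate_table)
    say("tuning spontaneous rate to target %.3f", spec$null_target_prevalence)
    tuned <- tune_spontaneous_rate(population, cfg_t,
                                   spec$null_target_prevalence,
                                   spec$null_tolerance)
    tuned_rate <- tuned$rate
    extra$tuning <- tuned
    say("tuned spontaneous rate: %.6f (achieved %.4f)", tuned$rate,
        tuned$achieved)
  }
  for (i in seq_along(spec$scenarios)) {
    nm <- names(spec$scenarios)[i]
    cfg <- .scenario_config(spec, nm, 1000L * i, rate_table)
    say("running %s scenario '%s' (%d replicates x %d months)",
        if (is.null(tuned_rate)) "contagious" else "spontaneous",
        nm, cfg$n_replicates, cfg$horizon)
    ens[[nm]] <- if (is.null(tuned_rate))
      run_ensemble(population, cfg)
    else run_ensemble(population, cfg, mechanism = "spontaneous",
                      spontaneous_rate = tuned_rate)
    write_event_log(ens[[nm]], file.path(out_dir, paste0("events_", nm, ".csv")))
    write_prevalence(ens[[nm]], file.path(out_dir, paste0("prevalence_", nm, ".csv")))
    summ <- ens[[nm]]$summary
    summ$scenario <- nm
    utils::write.csv(summ, file.path(out_dir, paste0("summary_", nm, ".csv")),
                     row.names = FALSE)
    rec <- try(compute_recidivism_tables(extract_release_records(ens[[nm]])),
               silent = TRUE)
    if (!inherits(rec, "try-error")) {
      recid[[nm]] <- rec
      write_recidivism_tables(rec, out_dir, paste0("recidivism_", nm))
    } else say("no recidivism statistics for '%s' (no complete releases)", nm)
  }
  if (spec$experiment == "ode_analysis") {
    p_hat <- calibrate_mean_rate(ens)
    extra$ode <- list(p_hat = p_hat,
                      critical_sentence = critical_sentence(p_hat))
    sweep <- bifurcation_sweep(p_hat)
    utils::write.csv(sweep, file.path(out_dir, "ode_bifurcation.csv"),
                     row.names = FALSE)
    say("calibrated mean transmission rate: %.4f (critical sentence %.1f months)",
        p_hat, extra$ode$critical_sentence)
  }

  grDevices::pdf(file.path(out_dir, "prevalence.pdf"), width = 7, height = 5)
  cols <- c("black", "grey50", "tomato", "steelblue")
  ymax <- max(vapply(ens, function(e) max(e$summary$p97.5), numeric(1)))
  for (i in seq_along(ens))
    plot(ens[[i]], col = cols[(i - 1) %% length(cols) + 1], add = i > 1,
         ylim = c(0, ymax * 1.05))
  graphics::legend("topleft", legend = names(ens), lwd = 2,
                   col = cols[seq_along(ens)], bty = "n")
  grDevices::dev.off()
  for (nm in names(recid)) {
    grDevices::pdf(file.path(out_dir, paste0("recidivism_", nm, ".pdf")),
                   width = 8, height = 6)
    plot(recid[[nm]])
    grDevices::dev.off()
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("incarcsim")),
    spec = jsonlite::fromJSON(jsonlite::toJSON(
      save_config_list(spec), auto_unbox = TRUE, digits = NA)),
    fitted_sentences = lapply(names(spec$scenarios), function(nm) {
      d <- fit_sentence_nb(spec$scenarios[[nm]]$sentence_mean,
                           spec$scenarios[[nm]]$sentence_median, label = nm)
      list(label = nm, size = d$size, prob = d$prob, mean = d$mean,
           median = d$median)
    }),
    monthly_rates = as.data.frame(rate_table),
    tuned_spontaneous_rate = tuned_rate,
    scenario_seeds = stats::setNames(
      as.list(spec$base_seed + 1000L * seq_along(spec$scenarios)),
      names(spec$scenarios)),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s; outputs in %s", prov$elapsed_seconds, out_dir)
  invisible(list(population = population, ensembles = ens,
                 recidivism = recid, extra = extra, spec = spec))
}

# spec as a plain list, the same shape save_config writes
save_config_list <- function(spec) {
  out <- unclass(spec)
  out$population <- unclass(out$population)
  out$population$friend_count_pmf <- as.list(out$population$friend_count_pmf)
  out$population$children_count_pmf <- as.list(out$population$children_count_pmf)
  out
}
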