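#' Export / import a synthetic population as CSV
#'
#' Two plain CSV files: agents (id, sex, birth_year, death_year, x, y,
#' age_first_birth, n_children, mother_id, father_id) and ties (agent_a,
#' agent_b, relation, parent_endpoint). The round trip is lossless.
#'
#' @param population a \code{\link{generate_population}} result.
#' @param agents_path,ties_path output CSV paths.
#' @export
write_population <- function(population, agents_path, ties_path) {
  utils::write.csv(population$agents, agents_path, row.names = FALSE)
  utils::write.csv(population$ties, ties_path, row.names = FALSE)
  invisible(population)
}

#' @rdname write_population
#' @param retained_from,total_iterations clock metadata (years) restored on
#'   the object.
#' @export
read_population <- function(agents_path, ties_path, retained_from = 150,
                            total_iterations = 200) {
  agents <- utils::read.csv(agents_path, stringsAsFactors = FALSE)
  ties <- utils::read.csv(ties_path, stringsAsFactors = FALSE)
  out <- list(agents = agents, ties = ties, retained_from = retained_from,
              total_iterations = total_iterations, config = NULL, seed = NA)
  class(out) <- "synthetic_population"
  out
}

#' Export / import event logs as CSV
#'
#' @param x a \code{sis_run}, \code{sis_ensemble} or event-log data frame.
#' @param path CSV path.
#' @export
write_event_log <- function(x, path) {
  log <- .pool_event_logs(x)
  if (!"replicate" %in% names(log)) log$replicate <- 1L
  cols <- c("replicate", "agent", "spell_index", "start_month",
            "sentence_months", "end_month", "end_reason", "source",
            "transmitting_agent")
  utils::write.csv(log[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export an ensemble's prevalence series as CSV
#'
#' One row per (replicate, month): incarcerated count, alive count and
#' prevalence.
#'
#' @param ensemble a \code{\link{run_ensemble}} result.
#' @param path CSV path.
#' @export
write_prevalence <- function(ensemble, path) {
  reps <- nrow(ensemble$prevalence)
  months <- ensemble$months
  out <- data.frame(
    replicate = rep(seq_len(reps), each = length(months)),
    month = rep(months, reps),
    alive = rep(ensemble$alive, reps),
    prevalence = as.vector(t(ensemble$prevalence)))
  out$incarcerated <- as.integer(round(out$prevalence * out$alive))
  utils::write.csv(out[c("replicate", "month", "incarcerated", "alive",
                         "prevalence")], path, row.names = FALSE)
  invisible(path)
}

#' Export recidivism tables as CSV
#'
#' One CSV per metric: bin, mean, p2.5, p97.5 (and n_releases for the rate
#' tables).
#'
#' @param tables a \code{\link{compute_recidivism_tables}} result.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @export
write_recidivism_tables <- function(tables, dir, prefix = "recidivism") {
  for (metric in c("by_prior", "by_age", "by_sentence", "cumulative")) {
    utils::write.csv(tables[[metric]],
                     file.path(dir, paste0(prefix, "_", metric, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
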