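#' Steady state of the random-mixing SIS model
#'
#' Under random mixing with homogeneous monthly transmission rate p and
#' infectious period (sentence) s, the steady-state prevalence is 0 when
#' \eqn{ps \le 1} and \eqn{1 - 1/(ps)} otherwise: the bifurcation at
#' \eqn{s = 1/p} separates extinction from a positive endemic level.
#'
#' @param p transmissions per infected person per month (>= 0).
#' @param s sentence length in months (>= 0).
#' @return Steady-state prevalence (fraction), vectorised over p and s.
#' @examples
#' steady_state_prevalence(0.0612, 17)   # endemic, about 3.9%
#' steady_state_prevalence(0.0612, 14)   # below threshold: 0
#' @export
steady_state_prevalence <- function(p, s) {
  stopifnot(all(p >= 0), all(s >= 0))
  ps <- p * s
  ifelse(ps > 1, 1 - 1 / ps, 0)
}

#' Critical sentence length
#'
#' The sentence length \eqn{s_c = 1/p} at which the SIS steady state
#' bifurcates: shorter sentences lead to extinction, longer ones to a
#' positive endemic prevalence.
#'
#' @param p transmissions per infected person per month (> 0).
#' @return Critical sentence length in months.
#' @export
critical_sentence <- function(p) {
  if (any(p <= 0)) stop("p must be > 0: no finite critical sentence at p = 0")
  1 / p
}

#' Population-wide mean transmission rate from event logs
#'
#' Estimates p as (number of contact-source infections) divided by (total
#' incarcerated person-months), pooled over all replicates and runs
#' supplied. Months served count from a spell's start month to its end month
#' (release, death or horizon truncation).
#'
#' @param event_logs an event-log data frame, a \code{sis_run}/
#'   \code{sis_ensemble}, or a list of any of these; logs are pooled.
#' @return Estimated transmissions per infected person per month.
#' @export
calibrate_mean_rate <- function(event_logs) {
  log <- .pool_event_logs(event_logs)
  person_months <- sum(log$end_month - log$start_month)
  if (person_months <= 0) stop("event logs contain zero incarcerated person-months")
  sum(log$source == "contact") / person_months
}

.pool_event_logs <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, c("sis_run", "sis_ensemble"))) return(x$event_log)
  if (is.list(x)) return(do.call(rbind, lapply(x, .pool_event_logs)))
  stop("cannot interpret event logs of class ", paste(class(x), collapse = "/"))
}

#' Bifurcation sweep of the steady state over sentence length
#'
#' @param p transmissions per infected person per month.
#' @param s_range range of sentence lengths (months).
#' @param step grid step.
#' @return Data frame with columns \code{s} and \code{steady_state}.
#' @export
bifurcation_sweep <- function(p, s_range = c(1, 40), step = 0.1) {
  s <- seq(s_range[1], s_range[2], by = step)
  data.frame(s = s, steady_state = steady_state_prevalence(p, s))
}

#' @rdname bifurcation_sweep
#' @param sweep a \code{bifurcation_sweep} result.
#' @param ... passed to \code{plot}.
#' @export
plot_bifurcation <- function(sweep, ...) {
  plot(sweep$s, 100 * sweep$steady_state, type = "l", lwd = 2,
       xlab = "sentence length (months)",
       ylab = "steady-state prevalence (%)", ...)
  invisible(sweep)
}
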