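#' Non-contagious control model
#'
#' Identical clock and bookkeeping to the contagious engine, but the network
#' mechanism is switched off: each susceptible agent of incarcerable age is
#' incarcerated independently each month with probability
#' \code{spontaneous_rate}, and sentences are drawn from the scenario's
#' sentence-length distribution.
#'
#' @inheritParams run_epidemic
#' @param spontaneous_rate per-agent monthly incarceration probability.
#' @return A \code{sis_run} (same event-log schema as the contagious model,
#'   with \code{source = "spontaneous"} for spontaneous spells).
#' @export
run_null_epidemic <- function(population, config, spontaneous_rate,
                              seed = config$rng_seed, net = NULL) {
  stopifnot(spontaneous_rate >= 0, spontaneous_rate <= 1)
  if (is.null(net)) net <- .build_epinet(population, config)
  res <- .simulate_core(net, config, seed, "spontaneous", spontaneous_rate)
  structure(list(event_log = res$event_log, prevalence = res$prevalence,
                 months = 0:config$horizon, alive = net$alive_count,
                 agent_months = data.frame(agent = seq_len(net$n),
                                           birth_month = net$bm,
                                           death_end_month = net$de),
                 config = config, seed = seed,
                 spontaneous_rate = spontaneous_rate),
            class = "sis_run")
}

#' Equilibrium prevalence of the spontaneous model (flow balance)
#'
#' At equilibrium the inflow of new inmates, rate x susceptibles, balances
#' the outflow of releases, prevalence / mean sentence, giving prevalence
#' \eqn{\pi_0 E[s] / (1 + \pi_0 E[s])} for spontaneous rate \eqn{\pi_0} and
#' mean sentence E[s]. Used as the analytic starting point for rate tuning
#' and as an oracle in tests.
#'
#' @param spontaneous_rate per-month probability.
#' @param mean_sentence mean sentence length, months.
#' @return Equilibrium prevalence (fraction).
#' @export
null_equilibrium_prevalence <- function(spontaneous_rate, mean_sentence) {
  x <- spontaneous_rate * mean_sentence
  x / (1 + x)
}

#' Tune the spontaneous rate to a target final prevalence
#'
#' Bisection on the spontaneous monthly rate against the ensemble-mean final
#' prevalence (with a reduced replicate count for speed), starting from a
#' bracket around the flow-balance analytic guess
#' \code{target / ((1 - target) * E[s])}. Each bisection step re-uses the
#' same replicate seeds (common random numbers), so the evaluated response is
#' monotone in the rate up to Monte-Carlo noise.
#'
#' @inheritParams run_null_epidemic
#' @param target_prevalence desired ensemble-mean final prevalence.
#' @param tolerance acceptable |final - target|.
#' @param n_replicates replicates per bisection step.
#' @param max_iter maximum bisection steps.
#' @return List: \code{rate} (tuned monthly probability),
#'   \code{achieved} (final prevalence at that rate), \code{analytic_guess},
#'   \code{iterations}.
#' @export
tune_spontaneous_rate <- function(population, config, target_prevalence,
                                  tolerance = 0.003, n_replicates = 25,
                                  max_iter = 30) {
  stopifnot(target_prevalence >= 0, target_prevalence < 1)
  if (target_prevalence == 0)
    return(list(rate = 0, achieved = 0, analytic_guess = 0, iterations = 0L))
  net <- .build_epinet(population, config)
  cfg <- config
  cfg$n_replicates <- as.integer(n_replicates)
  eval_rate <- function(rate) {
    fin <- vapply(seq_len(cfg$n_replicates), function(r) {
      res <- .simulate_core(net, cfg, cfg$rng_seed + r, "spontaneous", rate)
      res$prevalence[length(res$prevalence)]
    }, numeric(1))
    mean(fin)
  }
  guess <- target_prevalence /
    ((1 - target_prevalence) * mean(config$sentence_dist))
  lo <- guess / 4; hi <- min(1, guess * 4)
  f_lo <- eval_rate(lo); f_hi <- eval_rate(hi)
  if (f_lo > target_prevalence || f_hi < target_prevalence)
    stop("bisection bounds do not bracket the target prevalence (",
         format(f_lo, digits = 4), ", ", format(f_hi, digits = 4), ")")
  it <- 0L; mid <- guess; f_mid <- eval_rate(mid)
  while (abs(f_mid - target_prevalence) > tolerance && it < max_iter) {
    if (f_mid < target_prevalence) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    f_mid <- eval_rate(mid)
    it <- it + 1L
  }
  if (abs(f_mid - target_prevalence) > tolerance)
    warning("tuning stopped at max_iter with |final - target| = ",
            format(abs(f_mid - target_prevalence), digits = 3))
  list(rate = mid, achieved = f_mid, analytic_guess = guess, iterations = it)
}
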