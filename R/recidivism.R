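#' Release records from an event log
#'
#' One record per incarceration spell ending in release (spells truncated by
#' death or the simulation horizon yield no record). A release is a
#' recidivism event when the agent's next spell starts within the follow-up
#' window. Releases without a fully observable follow-up window -- because
#' the horizon ends, or the agent dies, within \code{followup} months of
#' release -- are marked incomplete and excluded from rate denominators.
#'
#' @param x a \code{sis_run}, \code{sis_ensemble}, or an event-log data frame
#'   (columns \code{agent, spell_index, start_month, sentence_months,
#'   end_month, end_reason}, optionally \code{replicate}).
#' @param horizon simulation horizon in months (taken from \code{x} when it
#'   is a run/ensemble object).
#' @param followup follow-up window in months (default 36: return within
#'   three years).
#' @param agent_months optional data frame \code{agent, birth_month,
#'   death_end_month} used for ages at release and death censoring (taken
#'   from \code{x} when available).
#' @return Data frame of release records: replicate, agent, release_month,
#'   age_at_release (years, NA without agent months), prior_spell_count
#'   (1 = first release), sentence_months, months_to_return (NA if no return
#'   within follow-up), returned (logical), followup_complete (logical).
#' @export
extract_release_records <- function(x, horizon = NULL, followup = 36,
                                    agent_months = NULL) {
  if (inherits(x, c("sis_run", "sis_ensemble"))) {
    if (is.null(horizon)) horizon <- x$config$horizon
    if (is.null(agent_months)) agent_months <- x$agent_months
    x <- x$event_log
  }
  if (is.null(horizon)) stop("horizon must be supplied with a raw event log")
  log <- as.data.frame(x)
  if (!"replicate" %in% names(log)) log$replicate <- 1L
  log <- log[order(log$replicate, log$agent, log$spell_index), ]
  if (nrow(log)) {
    same <- c(log$replicate[-1] == log$replicate[-nrow(log)] &
                log$agent[-1] == log$agent[-nrow(log)], FALSE)
    if (any(same & c(log$start_month[-1] < log$end_month[-nrow(log)], FALSE)))
      stop("malformed event log: overlapping spells for one agent")
    nxt_start <- c(log$start_month[-1], NA_integer_)
    nxt_start[!same] <- NA_integer_
  } else nxt_start <- integer(0)

  rel <- log$end_reason == "released"
  out <- data.frame(
    replicate = log$replicate[rel],
    agent = log$agent[rel],
    release_month = log$end_month[rel],
    prior_spell_count = log$spell_index[rel],
    sentence_months = log$sentence_months[rel],
    months_to_return = nxt_start[rel] - log$end_month[rel]
  )
  out$months_to_return[!is.na(out$months_to_return) &
                         out$months_to_return > followup] <- NA_integer_
  out$returned <- !is.na(out$months_to_return)
  death_end <- rep(Inf, nrow(out))
  age <- rep(NA_real_, nrow(out))
  if (!is.null(agent_months)) {
    i <- match(out$agent, agent_months$agent)
    death_end <- agent_months$death_end_month[i]
    age <- (out$release_month - agent_months$birth_month[i]) / 12
  }
  out$age_at_release <- age
  out$followup_complete <- (out$release_month + followup <= horizon) &
    (death_end > out$release_month + followup)
  attr(out, "followup") <- followup
  out
}

.bin_labels <- function(breaks, last_open) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1] - 1
  lab <- ifelse(hi == lo, as.character(lo), paste0(lo, "-", hi))
  if (last_open) lab[length(lab)] <- paste0(lo[length(lab)], "+")
  lab
}

.bin_of <- function(v, breaks) {
  findInterval(v, breaks, rightmost.closed = FALSE)
}

#' Recidivism summary tables with simulation intervals
#'
#' Computes, per replicate and then summarised across replicates
#' (mean and 2.5/97.5 empirical percentiles), the paper-style recidivism
#' statistics: the within-follow-up return rate by number of prior
#' incarcerations, by age at release, and by sentence length of the
#' completed spell, plus the cumulative fraction returned by months since
#' release among returners. Only releases with a complete follow-up window
#' enter the denominators; bins with no observations are reported as missing.
#'
#' @param records a \code{\link{extract_release_records}} data frame.
#' @param prior_breaks lower edges of the prior-incarceration bins (last bin
#'   open-ended).
#' @param age_breaks lower edges (years) of the age-at-release bins (last bin
#'   open-ended).
#' @param sentence_breaks lower edges (months) of the sentence-length bins
#'   (last bin open-ended).
#' @return Object of class \code{"recidivism_tables"}: data frames
#'   \code{by_prior}, \code{by_age}, \code{by_sentence} (bin, mean, p2.5,
#'   p97.5, n_releases) and \code{cumulative} (months_since_release, mean,
#'   p2.5, p97.5), plus the per-replicate matrices.
#' @export
compute_recidivism_tables <- function(records,
                                      prior_breaks = c(1, 2, 3, 4, 5),
                                      age_breaks = c(15, seq(20, 60, by = 5)),
                                      sentence_breaks = c(1, seq(13, 97, by = 12))) {
  followup <- attr(records, "followup")
  if (is.null(followup)) followup <- 36
  cc <- records[records$followup_complete, ]
  if (nrow(cc) == 0) stop("no release records with complete follow-up")
  reps <- sort(unique(records$replicate))

  v_prior <- pmin(cc$prior_spell_count, max(prior_breaks))
  v_age <- cc$age_at_release
  v_sent <- cc$sentence_months

  mk <- function(v, breaks, last_lab_from) {
    nb <- length(breaks)
    m <- matrix(NA_real_, length(reps), nb)
    n_rel <- integer(nb)
    bin <- .bin_of(v, breaks)
    bin[is.na(bin)] <- 0L   # unknown values (e.g. missing age) fall in no bin
    for (ri in seq_along(reps)) {
      sub <- cc$replicate == reps[ri]
      for (k in seq_len(nb)) {
        sel <- sub & bin == k
        if (any(sel)) m[ri, k] <- mean(cc$returned[sel])
      }
    }
    for (k in seq_len(nb)) n_rel[k] <- sum(bin == k, na.rm = TRUE)
    labs <- .bin_labels(c(breaks, last_lab_from), last_open = TRUE)
    colnames(m) <- labs
    si <- .sim_int(m)
    si$n_releases <- n_rel
    list(table = si, per_replicate = m)
  }
  by_prior <- mk(v_prior, prior_breaks, max(prior_breaks) + 1)
  by_age <- mk(v_age, age_breaks, max(age_breaks) + 5)
  by_sent <- mk(v_sent, sentence_breaks, max(sentence_breaks) + 12)

  # cumulative return curve among returners with complete follow-up
  cum <- matrix(NA_real_, length(reps), followup)
  for (ri in seq_along(reps)) {
    mtr <- cc$months_to_return[cc$replicate == reps[ri] & cc$returned]
    if (length(mtr))
      cum[ri, ] <- vapply(seq_len(followup), function(k) mean(mtr <= k),
                          numeric(1))
  }
  colnames(cum) <- seq_len(followup)
  cum_si <- .sim_int(cum)
  names(cum_si)[1] <- "months_since_release"
  cum_si$months_since_release <- seq_len(followup)

  out <- list(by_prior = by_prior$table, by_age = by_age$table,
              by_sentence = by_sent$table, cumulative = cum_si,
              per_replicate = list(by_prior = by_prior$per_replicate,
                                   by_age = by_age$per_replicate,
                                   by_sentence = by_sent$per_replicate,
                                   cumulative = cum),
              followup = followup, n_replicates = length(reps))
  class(out) <- "recidivism_tables"
  out
}

#' Cross-replicate mean and 95% simulation interval
#'
#' Empirical 2.5th and 97.5th percentiles (linear interpolation between order
#' statistics) and the mean of a per-replicate statistic, per column.
#'
#' @param per_replicate matrix: replicates in rows, bins in columns.
#' @return Data frame: bin, mean, p2.5, p97.5.
#' @export
simulation_intervals <- function(per_replicate) {
  m <- as.matrix(per_replicate)
  if (nrow(m) < 2) stop("simulation intervals need at least 2 replicates")
  .sim_int(m)
}

# as simulation_intervals, but tolerates a single replicate (degenerate band)
.sim_int <- function(m) {
  qs <- apply(m, 2, function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, type = 7, names = FALSE)
  })
  data.frame(bin = colnames(m) %||% as.character(seq_len(ncol(m))),
             mean = colMeans(m, na.rm = TRUE),
             p2.5 = qs[1, ], p97.5 = qs[2, ],
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recidivism_tables <- function(x, ...) {
  cat("Recidivism tables (", x$n_replicates, "replicates, follow-up",
      x$followup, "months )\n\nby prior incarcerations:\n")
  print(x$by_prior, digits = 3)
  cat("\nby age at release:\n")
  print(x$by_age, digits = 3)
  cat("\nby sentence length (months):\n")
  print(x$by_sentence, digits = 3)
  invisible(x)
}

#' @export
plot.recidivism_tables <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  bar_panel <- function(tab, xlab) {
    ok <- !is.na(tab$mean)
    bp <- graphics::barplot(tab$mean[ok], names.arg = tab$bin[ok],
                            ylim = c(0, max(tab$p97.5[ok], na.rm = TRUE) * 1.1),
                            xlab = xlab, ylab = "recidivism rate")
    wid <- ok & !is.na(tab$p2.5) & tab$p97.5 - tab$p2.5 > 0
    if (any(wid))
      graphics::arrows(bp[wid[ok]], tab$p2.5[wid], bp[wid[ok]], tab$p97.5[wid],
                       angle = 90, code = 3, length = 0.03)
  }
  bar_panel(x$by_prior, "prior incarcerations")
  bar_panel(x$by_age, "age at release")
  bar_panel(x$by_sentence, "sentence length (months)")
  cs <- x$cumulative
  plot(cs$months_since_release, cs$mean, type = "l", lwd = 2,
       ylim = c(0, 1), xlab = "months since release",
       ylab = "cumulative fraction returned")
  graphics::lines(cs$months_since_release, cs$p2.5, lty = 2)
  graphics::lines(cs$months_since_release, cs$p97.5, lty = 2)
  invisible(x)
}
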