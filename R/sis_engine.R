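#' Configuration of one epidemic scenario
#'
#' @param sentence_dist a \code{\link{fit_sentence_nb}} object (the scenario's
#'   sentence-length distribution; also the infectious-period law).
#' @param rate_table a \code{\link{monthly_rate_table}} of monthly
#'   transmission probabilities.
#' @param init_prevalence target fraction of the alive population
#'   incarcerated at month 0 (inmates are drawn among agents of incarcerable
#'   age).
#' @param horizon simulated months (prevalence is recorded at months
#'   \code{0..horizon}).
#' @param n_replicates ensemble size for \code{\link{run_ensemble}}.
#' @param min_incarcerable_age youngest age (years) at which an agent can be
#'   incarcerated.
#' @param adult_child_age age (years) from which an inmate's child is a
#'   transmission target (adult-child row).
#' @param epidemic_start_year population-clock year mapped to month 0
#'   (default: the population's burn-in year, so the retained window covers
#'   the epidemic).
#' @param rng_seed base seed; replicate r uses \code{rng_seed + r}.
#' @param label optional scenario label (e.g. "black", "white").
#' @return List of class \code{"epidemic_config"}.
#' @export
epidemic_config <- function(sentence_dist, rate_table = monthly_rate_table(),
                            init_prevalence = 0.01, horizon = 600,
                            n_replicates = 250, min_incarcerable_age = 15,
                            adult_child_age = 18,
                            epidemic_start_year = NULL, rng_seed = 1L,
                            label = sentence_dist$label) {
  stopifnot(inherits(sentence_dist, "sentence_dist"),
            init_prevalence >= 0, init_prevalence <= 1,
            horizon >= 1, n_replicates >= 1)
  out <- list(sentence_dist = sentence_dist, rate_table = rate_table,
              init_prevalence = init_prevalence, horizon = as.integer(horizon),
              n_replicates = as.integer(n_replicates),
              min_incarcerable_age = min_incarcerable_age,
              adult_child_age = adult_child_age,
              epidemic_start_year = epidemic_start_year,
              rng_seed = as.integer(rng_seed), label = label)
  class(out) <- "epidemic_config"
  out
}

# Precompute the epidemic view of a population: per-agent month bounds and a
# CSR directed-edge structure with per-edge monthly rates and activation
# months (the first month the susceptible endpoint is an eligible target).
# The epidemic clock is months; population year Y maps to month (Y - start)*12.
.build_epinet <- function(population, config) {
  ag <- population$agents
  start_year <- config$epidemic_start_year
  if (is.null(start_year)) start_year <- population$retained_from
  n <- nrow(ag)
  sexc <- .sex_code(ag$sex)
  bm <- (ag$birth_year - start_year) * 12L            # first alive month
  de <- (ag$death_year + 1L - start_year) * 12L       # first month not alive
  elig <- bm + as.integer(round(config$min_incarcerable_age * 12))
  adult <- bm + as.integer(round(config$adult_child_age * 12))

  tab <- config$rate_table
  Tm <- as.matrix(tab[, c("female", "male")])
  cell <- function(row, col_sex) Tm[cbind(match(row, tab$relation), col_sex)]

  ties <- population$ties
  a <- ties$agent_a; b <- ties$agent_b; rel <- ties$relation
  sis_row <- function(dst) ifelse(sexc[dst] == 1L, "sister", "brother")
  par_row <- function(dst) ifelse(sexc[dst] == 1L, "mother", "father")

  mk_dir <- function(src, dst, is_child_target) {
    row <- character(length(src))
    sibf <- rel %in% c("sibling", "friend")
    row[sibf] <- sis_row(dst[sibf])
    row[rel == "spouse"] <- "spouse"
    pc <- rel == "parent_child"
    row[pc & is_child_target] <- "adult_child"
    row[pc & !is_child_target] <- par_row(dst[pc & !is_child_target])
    rate <- cell(row, sexc[src])
    act <- ifelse(rel == "parent_child" & is_child_target, adult[dst], elig[dst])
    data.frame(src = src, dst = dst, rate = rate, act = act)
  }
  # parent_child ties store the parent as agent_a, so a->b targets the child
  ed <- rbind(mk_dir(a, b, rep(TRUE, length(a))),
              mk_dir(b, a, rep(FALSE, length(a))))
  ed <- ed[ed$rate > 0, ]
  ed <- ed[order(ed$src, ed$dst), ]
  deg <- tabulate(ed$src, nbins = n)
  ptr <- c(0L, cumsum(deg))

  months <- 0:config$horizon
  alive_count <- vapply(months, function(m) sum(bm <= m & m < de), integer(1))

  list(n = n, sex = sexc, bm = bm, de = de, elig = elig,
       ptr = ptr, e_dst = ed$dst, e_src = ed$src,
       e_rate = ed$rate, e_act = ed$act,
       alive_count = alive_count, start_year = start_year)
}

# Core monthly-step simulator shared by the contact (SIS) and spontaneous
# (null) mechanisms. Spell convention: a spell starting at month s0 with
# sentence s is infectious during months s0 .. s0+s-1 and the agent is
# susceptible again at s0+s; an infection detected at month m starts its
# spell at m+1. Death truncates a spell at the first non-alive month.
.simulate_core <- function(net, config, seed,
                           mechanism = c("contact", "spontaneous"),
                           spontaneous_rate = 0) {
  mechanism <- match.arg(mechanism)
  set.seed(as.integer(seed))
  n <- net$n; horizon <- config$horizon
  dist <- config$sentence_dist

  remaining <- integer(n)
  spell_count <- integer(n)
  cur_start <- integer(n); cur_sentence <- integer(n)
  cur_source <- integer(n); cur_trans <- integer(n)  # source codes below
  SRC <- c("initial", "contact", "spontaneous")

  logs <- list(); log_i <- 0L
  push_log <- function(agent, spell_index, start, sentence, end, reason,
                       source, trans) {
    log_i <<- log_i + 1L
    logs[[log_i]] <<- data.frame(
      agent = agent, spell_index = spell_index, start_month = start,
      sentence_months = sentence, end_month = end, end_reason = reason,
      source = SRC[source],
      transmitting_agent = ifelse(trans == 0L, NA_integer_, trans))
  }

  # month 0: about init_prevalence of the whole alive population (the scale
  # prevalence is reported on), drawn among agents of incarcerable age
  alive0 <- sum(net$bm <= 0L & net$de > 0L)
  eligible0 <- which(net$bm <= 0L & net$de > 0L & net$elig <= 0L)
  if (length(eligible0) == 0L) stop("no agents eligible for incarceration at month 0")
  n_init <- min(round(config$init_prevalence * alive0), length(eligible0))
  if (n_init > 0) {
    sel <- sort(sample(eligible0, n_init))
    s0 <- sample_sentence(dist, n_init)
    remaining[sel] <- s0
    spell_count[sel] <- 1L
    cur_start[sel] <- 0L; cur_sentence[sel] <- s0
    cur_source[sel] <- 1L; cur_trans[sel] <- 0L
  }
  prevalence <- numeric(horizon + 1L)

  pend_agent <- integer(0); pend_sent <- integer(0)
  pend_src <- integer(0); pend_trans <- integer(0)

  for (m in 0:horizon) {
    if (m > 0L) {
      # 1. serve a month; completed sentences are released this month
      act <- which(remaining > 0L)
      if (length(act)) {
        remaining[act] <- remaining[act] - 1L
        rel <- act[remaining[act] == 0L]
        if (length(rel))
          push_log(rel, spell_count[rel], cur_start[rel], cur_sentence[rel],
                   m, "released", cur_source[rel], cur_trans[rel])
      }
      # 2. infections detected last month begin their spells now
      if (length(pend_agent)) {
        remaining[pend_agent] <- pend_sent
        spell_count[pend_agent] <- spell_count[pend_agent] + 1L
        cur_start[pend_agent] <- m; cur_sentence[pend_agent] <- pend_sent
        cur_source[pend_agent] <- pend_src; cur_trans[pend_agent] <- pend_trans
        pend_agent <- integer(0)
      }
      # 3. deaths due this month truncate open spells
      dying <- which(net$de == m & remaining > 0L)
      if (length(dying)) {
        push_log(dying, spell_count[dying], cur_start[dying],
                 cur_sentence[dying], m, "died", cur_source[dying],
                 cur_trans[dying])
        remaining[dying] <- 0L
      }
    }
    # 4. new infections from the set infectious during month m (detected at
    # m, spells begin at m+1)
    if (m < horizon) {
      if (mechanism == "contact") {
        inf <- which(remaining > 0L)
        if (length(inf)) {
          lens <- net$ptr[inf + 1L] - net$ptr[inf]
          haveedges <- lens > 0L
          if (any(haveedges)) {
            ei <- sequence(lens[haveedges], from = net$ptr[inf[haveedges]] + 1L)
            dst <- net$e_dst[ei]
            ok <- remaining[dst] == 0L & net$bm[dst] <= m & net$de[dst] > m &
              net$e_act[ei] <= m
            ei <- ei[ok]; dst <- dst[ok]
            if (length(ei)) {
              hit <- stats::runif(length(ei)) < net$e_rate[ei]
              if (any(hit)) {
                dsth <- dst[hit]; srch <- net$e_src[ei][hit]
                o <- order(dsth, srch)
                first <- !duplicated(dsth[o])
                new_agent <- dsth[o][first]
                new_trans <- srch[o][first]
                new_sent <- sample_sentence(dist, length(new_agent))
                pend_agent <- new_agent; pend_sent <- new_sent
                pend_src <- rep(2L, length(new_agent)); pend_trans <- new_trans
              }
            }
          }
        }
      } else if (spontaneous_rate > 0) {
        sus <- which(remaining == 0L & net$bm <= m & net$de > m & net$elig <= m)
        if (length(sus)) {
          hit <- stats::runif(length(sus)) < spontaneous_rate
          if (any(hit)) {
            new_agent <- sus[hit]
            new_sent <- sample_sentence(dist, length(new_agent))
            pend_agent <- new_agent; pend_sent <- new_sent
            pend_src <- rep(3L, length(new_agent))
            pend_trans <- rep(0L, length(new_agent))
          }
        }
      }
    }
    prevalence[m + 1L] <- sum(remaining > 0L) / net$alive_count[m + 1L]
  }
  open <- which(remaining > 0L)
  if (length(open))
    push_log(open, spell_count[open], cur_start[open], cur_sentence[open],
             horizon + 1L, "horizon", cur_source[open], cur_trans[open])

  log <- if (log_i) do.call(rbind, logs[seq_len(log_i)]) else
    data.frame(agent = integer(0), spell_index = integer(0),
               start_month = integer(0), sentence_months = integer(0),
               end_month = integer(0), end_reason = character(0),
               source = character(0), transmitting_agent = integer(0))
  log <- log[order(log$agent, log$spell_index), ]
  rownames(log) <- NULL
  list(event_log = log, prevalence = prevalence)
}

#' Initial epidemic state
#'
#' Seeds \code{round(init_prevalence * alive)} agents as incarcerated -- so
#' the month-0 prevalence over the whole alive population is approximately
#' \code{init_prevalence} -- drawn uniformly among alive agents of
#' incarcerable age, each with a freshly drawn full sentence starting at
#' month 0.
#'
#' @param population a \code{\link{generate_population}} result.
#' @param config an \code{\link{epidemic_config}}.
#' @param seed integer seed.
#' @return List with \code{incarcerated} (agent ids), \code{sentences}
#'   (months), \code{n_alive} and \code{n_eligible}.
#' @export
initialize_states <- function(population, config, seed = config$rng_seed) {
  net <- .build_epinet(population, config)
  set.seed(as.integer(seed))
  alive0 <- sum(net$bm <= 0L & net$de > 0L)
  eligible0 <- which(net$bm <= 0L & net$de > 0L & net$elig <= 0L)
  if (length(eligible0) == 0L) stop("no agents eligible for incarceration at month 0")
  n_init <- min(round(config$init_prevalence * alive0), length(eligible0))
  sel <- if (n_init > 0) sort(sample(eligible0, n_init)) else integer(0)
  list(incarcerated = sel,
       sentences = if (n_init > 0) sample_sentence(config$sentence_dist, n_init)
                   else integer(0),
       n_alive = alive0, n_eligible = length(eligible0))
}

#' Run one epidemic replicate
#'
#' @inheritParams initialize_states
#' @param seed replicate seed (all randomness derives from it).
#' @param net optional precomputed internal network (used by
#'   \code{\link{run_ensemble}} to avoid rebuilding).
#' @return Object of class \code{"sis_run"}: \code{event_log} (one row per
#'   incarceration spell), \code{prevalence} (months \code{0..horizon}),
#'   \code{alive} (alive count per month) and \code{agent_months} (per-agent
#'   birth/death months, used by the recidivism statistics).
#' @export
run_epidemic <- function(population, config, seed = config$rng_seed,
                         net = NULL) {
  if (is.null(net)) net <- .build_epinet(population, config)
  res <- .simulate_core(net, config, seed, "contact")
  structure(list(event_log = res$event_log, prevalence = res$prevalence,
                 months = 0:config$horizon, alive = net$alive_count,
                 agent_months = data.frame(agent = seq_len(net$n),
                                           birth_month = net$bm,
                                           death_end_month = net$de),
                 config = config, seed = seed),
            class = "sis_run")
}

#' @export
print.sis_run <- function(x, ...) {
  cat("SIS epidemic run (", length(x$months) - 1, "months )\n")
  cat("  spells:", nrow(x$event_log),
      " final prevalence:", sprintf("%.3f%%", 100 * utils::tail(x$prevalence, 1)),
      "\n")
  invisible(x)
}

#' Run an ensemble of epidemic replicates
#'
#' Replicate r (r = 1..n_replicates) is simulated with seed
#' \code{rng_seed + r} on one shared network; the per-month ensemble mean and
#' 2.5/97.5 percentile band are computed across replicates.
#'
#' @inheritParams initialize_states
#' @param mechanism \code{"contact"} for the SIS contagion, or
#'   \code{"spontaneous"} for the non-contagious control.
#' @param spontaneous_rate per-agent monthly infection probability (only used
#'   by the spontaneous mechanism).
#' @return Object of class \code{"sis_ensemble"}: \code{prevalence} (matrix,
#'   replicates x months), \code{summary} (month, mean, p2.5, p97.5),
#'   \code{event_log} (all replicates, with a \code{replicate} column),
#'   \code{alive}, \code{agent_months}, \code{config}.
#' @export
run_ensemble <- function(population, config, mechanism = c("contact", "spontaneous"),
                         spontaneous_rate = 0) {
  mechanism <- match.arg(mechanism)
  if (config$n_replicates < 2) stop("an ensemble needs at least 2 replicates")
  net <- .build_epinet(population, config)
  prev <- matrix(NA_real_, config$n_replicates, config$horizon + 1L)
  logs <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    res <- .simulate_core(net, config, config$rng_seed + r, mechanism,
                          spontaneous_rate)
    prev[r, ] <- res$prevalence
    if (nrow(res$event_log)) res$event_log$replicate <- r
    logs[[r]] <- res$event_log
  }
  log <- do.call(rbind, logs)
  months <- 0:config$horizon
  summ <- data.frame(
    month = months,
    mean = colMeans(prev),
    p2.5 = apply(prev, 2, stats::quantile, probs = 0.025, type = 7),
    p97.5 = apply(prev, 2, stats::quantile, probs = 0.975, type = 7))
  structure(list(prevalence = prev, summary = summ, event_log = log,
                 months = months, alive = net$alive_count,
                 agent_months = data.frame(agent = seq_len(net$n),
                                           birth_month = net$bm,
                                           death_end_month = net$de),
                 config = config, mechanism = mechanism,
                 spontaneous_rate = spontaneous_rate),
            class = "sis_ensemble")
}

#' @export
print.sis_ensemble <- function(x, ...) {
  cat("SIS ensemble:", nrow(x$prevalence), "replicates,",
      length(x$months) - 1, "months,",
      if (!is.null(x$config$label)) paste0("scenario '", x$config$label, "',"),
      "mechanism", x$mechanism, "\n")
  fin <- x$summary[nrow(x$summary), ]
  cat(sprintf("  final prevalence: mean %.3f%% (95%% band %.3f%% - %.3f%%)\n",
              100 * fin$mean, 100 * fin$p2.5, 100 * fin$p97.5))
  invisible(x)
}

#' @export
summary.sis_ensemble <- function(object, ...) object$summary

#' Final ensemble-mean prevalence
#'
#' @param ensemble a \code{\link{run_ensemble}} result.
#' @return Mean prevalence across replicates at the final month (fraction).
#' @export
final_prevalence <- function(ensemble) {
  mean(ensemble$prevalence[, ncol(ensemble$prevalence)])
}

#' Per-month Welch tests between two ensembles
#'
#' Compares per-replicate prevalence at each month with a two-sample Welch
#' t-test. Months where both ensembles have zero variance are flagged as
#' degenerate (p = NA) rather than failing.
#'
#' @param series_a,series_b \code{sis_ensemble} objects with equal horizons.
#' @return Data frame: month, mean_a, mean_b, t, df, p_value, degenerate.
#' @export
compare_ensembles <- function(series_a, series_b) {
  A <- series_a$prevalence; B <- series_b$prevalence
  if (ncol(A) != ncol(B)) stop("ensembles must share the same horizon")
  na <- nrow(A); nb <- nrow(B)
  if (na < 2 || nb < 2) stop("need at least 2 replicates per ensemble")
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen] <- NA_real_
  data.frame(month = series_a$months, mean_a = ma, mean_b = mb,
             t = tstat, df = df, p_value = p, degenerate = degen)
}

#' @export
plot.sis_ensemble <- function(x, col = "black", band_col = grDevices::adjustcolor(col, 0.2),
                              add = FALSE, ylim = NULL, ...) {
  s <- x$summary
  if (!add) {
    if (is.null(ylim)) ylim <- c(0, max(s$p97.5, na.rm = TRUE) * 1.05)
    plot(s$month, 100 * s$mean, type = "n", ylim = 100 * ylim,
         xlab = "month", ylab = "prevalence (%)", ...)
  }
  graphics::polygon(c(s$month, rev(s$month)), 100 * c(s$p2.5, rev(s$p97.5)),
                    border = NA, col = band_col)
  graphics::lines(s$month, 100 * s$mean, col = col, lwd = 2)
  invisible(x)
}
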