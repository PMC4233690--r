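#' Configuration for the synthetic population generator
#'
#' Collects every tunable of the demographic generator. Defaults reflect the
#' study design: 1500 founders born uniformly over the 60 years before
#' iteration 0, a 200-year run with a 150-year burn-in, age at first birth
#' 15 + Poisson(10.6) years (mean 25.6), completed family size with mean 2.07
#' children, Poisson(4.5) inter-birth spacing, friendships formed at the 10th
#' birthday among non-siblings aged 9--11, and spouses chosen among unrelated
#' non-friend males 0--9 years older.
#'
#' @param seed_size number of founding agents (>= 2).
#' @param birth_range length-2 numeric, (L, U): founders' birth years are
#'   uniform on this interval (years; iteration 0 is the start of the run).
#' @param total_iterations total simulated years.
#' @param burn_in years discarded; agents alive at any time >= burn_in are
#'   retained.
#' @param friend_count_pmf named numeric vector: probability of forming each
#'   possible number of close friendships.
#' @param children_count_pmf named numeric vector: distribution of a woman's
#'   completed number of children.
#' @param age_first_birth_offset_mean mean of the Poisson offset r in
#'   h = 15 + r, the age at first birth (years).
#' @param interbirth_mean Poisson mean of the gap (years) between the first
#'   birth year and each subsequent child's birth year.
#' @param partner_age_gap length-2 numeric: allowed (male age - female age)
#'   window, in years, at partnering.
#' @param friend_age_range length-2 integer: candidate friend ages (years).
#' @param child_location_noise half-width of the uniform noise added per axis
#'   to the parents' midpoint when placing a child (unit-square coordinates).
#' @return A validated list of class \code{"population_config"}.
#' @export
population_config <- function(seed_size = 1500,
                              birth_range = c(-60, 0),
                              total_iterations = 200,
                              burn_in = 150,
                              friend_count_pmf = c("0" = 0.25, "1" = 0.30,
                                                   "2" = 0.25, "3" = 0.15,
                                                   "4" = 0.04, "5" = 0.01),
                              children_count_pmf = c("0" = 0.15, "1" = 0.17,
                                                     "2" = 0.33, "3" = 0.21,
                                                     "4" = 0.09, "5" = 0.05),
                              age_first_birth_offset_mean = 10.6,
                              interbirth_mean = 4.5,
                              partner_age_gap = c(0, 9),
                              friend_age_range = c(9, 11),
                              child_location_noise = 0.05) {
  cfg <- list(seed_size = as.integer(seed_size),
              birth_range = as.numeric(birth_range),
              total_iterations = as.integer(total_iterations),
              burn_in = as.integer(burn_in),
              friend_count_pmf = friend_count_pmf,
              children_count_pmf = children_count_pmf,
              age_first_birth_offset_mean = age_first_birth_offset_mean,
              interbirth_mean = interbirth_mean,
              partner_age_gap = as.numeric(partner_age_gap),
              friend_age_range = as.integer(friend_age_range),
              child_location_noise = child_location_noise)
  validate_population_config(cfg)
  class(cfg) <- "population_config"
  cfg
}

#' @rdname population_config
#' @param config a candidate configuration list.
#' @export
validate_population_config <- function(config) {
  chk_pmf <- function(pmf, what) {
    if (is.null(names(pmf)) || anyNA(suppressWarnings(as.integer(names(pmf)))))
      stop(what, " must be a named vector with integer-valued names")
    if (any(pmf < 0)) stop(what, " has negative probabilities")
    if (abs(sum(pmf) - 1) > 1e-9)
      stop(what, " must sum to 1 (got ", format(sum(pmf), digits = 12), ")")
  }
  chk_pmf(config$friend_count_pmf, "friend_count_pmf")
  chk_pmf(config$children_count_pmf, "children_count_pmf")
  if (config$seed_size < 2) stop("seed_size must be >= 2")
  if (config$burn_in >= config$total_iterations)
    stop("burn_in must be smaller than total_iterations")
  if (config$birth_range[1] > config$birth_range[2])
    stop("birth_range must be ordered (L <= U)")
  if (config$partner_age_gap[1] > config$partner_age_gap[2])
    stop("partner_age_gap must be ordered")
  if (config$child_location_noise < 0) stop("child_location_noise must be >= 0")
  invisible(config)
}

.sample_pmf <- function(pmf, n) {
  vals <- as.integer(names(pmf))
  if (length(vals) == 1L) return(rep(vals, n))
  vals[sample.int(length(vals), size = n, replace = TRUE, prob = pmf)]
}

.sample_lifespans_by_sex <- function(sex, pmf_f, pmf_m) {
  out <- integer(length(sex))
  nf <- sum(sex == 1L)
  if (nf) out[sex == 1L] <- sample.int(120L, nf, TRUE, prob = pmf_f) - 1L
  nm <- sum(sex == 2L)
  if (nm) out[sex == 2L] <- sample.int(120L, nm, TRUE, prob = pmf_m) - 1L
  out
}

# Draw attributes for n new agents. sex coding: 1 female, 2 male.
# Draw order per call: sex, lifespan (females then males), age-at-first-birth
# offset, children count.
.draw_personal <- function(n, config, pmf_f, pmf_m) {
  sex <- 1L + (stats::runif(n) >= 0.5)
  lifespan <- .sample_lifespans_by_sex(sex, pmf_f, pmf_m)
  h <- rep(NA_integer_, n)
  nk <- rep(NA_integer_, n)
  fem <- which(sex == 1L)
  if (length(fem)) {
    h[fem] <- 15L + stats::rpois(length(fem), config$age_first_birth_offset_mean)
    nk[fem] <- .sample_pmf(config$children_count_pmf, length(fem))
  }
  list(sex = sex, lifespan = lifespan, h = h, nk = nk)
}

# ---- selection rules shared by the generator and the exported operations ----

# Siblings share a recorded mother (or father). Under monogamy a shared father
# implies a shared mother, so the mother id suffices.
.is_sibling <- function(mother_i, mother_vec) {
  !is.na(mother_i) & !is.na(mother_vec) & mother_vec == mother_i
}

# Ancestors within two generations: self, parents, grandparents.
.ancestor_set <- function(i, mother, father) {
  par <- c(mother[i], father[i])
  par <- par[!is.na(par)]
  gp <- c(mother[par], father[par])
  c(i, par, gp[!is.na(gp)])
}

.nearest_by_distance <- function(from_x, from_y, cand, x, y, k) {
  if (length(cand) == 0L || k <= 0L) return(integer(0))
  d2 <- (x[cand] - from_x)^2 + (y[cand] - from_y)^2
  cand[order(d2, cand)][seq_len(min(k, length(cand)))]
}

# Candidate friends for agent i at year t: alive non-siblings (self excluded)
# whose integer age lies in the configured window.
.friend_candidates <- function(i, t, b, d, mother, alive, friend_age_range) {
  age <- t - b
  ok <- alive & age >= friend_age_range[1] & age <= friend_age_range[2]
  ok[i] <- FALSE
  ok[.is_sibling(mother[i], mother)] <- FALSE
  which(ok)
}

# Eligible partners for female i at year t: alive males, 0-9 years older,
# not a friend, not related within two generations, not already married.
.partner_candidates <- function(i, t, b, d, sex, mother, father, alive,
                                spouse_of, friends_i, gap) {
  older <- b[i] - b        # male age minus female age
  ok <- alive & sex == 2L & older >= gap[1] & older <= gap[2] &
    is.na(spouse_of)
  ok[friends_i] <- FALSE
  cand <- which(ok)
  if (length(cand) == 0L) return(cand)
  anc_i <- .ancestor_set(i, mother, father)
  related <- vapply(cand, function(m) {
    any(.ancestor_set(m, mother, father) %in% anc_i)
  }, logical(1))
  cand[!related]
}

# ---- exported single-step operations (thin views over the shared rules) ----

#' Friendship formation for one agent
#'
#' Applies the friendship rule at the agent's formation year: draw the number
#' of friends from the configured distribution (unless supplied), restrict
#' candidates to alive non-siblings aged within the configured window, and
#' pick the nearest candidates in Euclidean distance on the unit square.
#'
#' @param population a \code{synthetic_population} or a data frame of agents
#'   (columns \code{id, sex, birth_year, death_year, x, y, mother_id,
#'   father_id}).
#' @param agent id of the agent forming friendships.
#' @param year current year on the population clock.
#' @param config a \code{\link{population_config}}.
#' @param n_friends optional fixed friend count (otherwise drawn from
#'   \code{friend_count_pmf}).
#' @return Integer vector of chosen friend ids (possibly empty).
#' @export
assign_friends <- function(population, agent, year, config = population_config(),
                           n_friends = NULL) {
  ag <- .as_agents_df(population)
  if (is.null(n_friends)) n_friends <- .sample_pmf(config$friend_count_pmf, 1L)
  i <- match(agent, ag$id)
  alive <- ag$birth_year <= year & year <= ag$death_year
  cand <- .friend_candidates(i, year, ag$birth_year, ag$death_year,
                             match(ag$mother_id, ag$id), alive,
                             config$friend_age_range)
  ag$id[.nearest_by_distance(ag$x[i], ag$y[i], cand, ag$x, ag$y, n_friends)]
}

#' Partner assignment for a female agent at her first-birth year
#'
#' Selects, among alive males whose age exceeds the female's by 0--9 years and
#' who are neither friends nor relatives within two generations nor already
#' married, the candidate nearest in Euclidean distance. Returns \code{NA} if
#' no candidate exists (single mother).
#'
#' @inheritParams assign_friends
#' @param female id of the female agent.
#' @param spouse_of optional integer vector (parallel to the agent table)
#'   giving each agent's current spouse id, \code{NA} if unmarried.
#' @param friends_of_female integer vector of the female's friend ids.
#' @return The chosen partner's id, or \code{NA_integer_}.
#' @export
assign_partner <- function(population, female, year,
                           config = population_config(),
                           spouse_of = NULL, friends_of_female = integer(0)) {
  ag <- .as_agents_df(population)
  i <- match(female, ag$id)
  alive <- ag$birth_year <= year & year <= ag$death_year
  if (is.null(spouse_of)) spouse_of <- .spouse_index(population, ag)
  cand <- .partner_candidates(i, year, ag$birth_year, ag$death_year,
                              .sex_code(ag$sex),
                              match(ag$mother_id, ag$id),
                              match(ag$father_id, ag$id),
                              alive, spouse_of,
                              match(friends_of_female, ag$id),
                              config$partner_age_gap)
  sel <- .nearest_by_distance(ag$x[i], ag$y[i], cand, ag$x, ag$y, 1L)
  if (length(sel)) ag$id[sel] else NA_integer_
}

#' Create the children of a couple (or single mother)
#'
#' The first child is born in the current year; each subsequent child's birth
#' year is the current year plus an independent Poisson draw with the
#' configured inter-birth mean. Each child's location is the parents'
#' midpoint (the mother's location if single) plus uniform noise of the
#' configured half-width per axis, clipped to the unit square. Children
#' receive a full set of personal attributes; sibling ties link all children
#' of the mother.
#'
#' @param mother a one-row list/data frame with \code{id, x, y}.
#' @param father optional one-row list/data frame with \code{id, x, y}, or
#'   \code{NULL} for a single mother.
#' @param n_children number of children to create.
#' @param year current year (the first child's birth year).
#' @param config a \code{\link{population_config}}.
#' @param life_table a \code{\link{default_life_table}}-style table.
#' @param id_start id assigned to the first child (ids are sequential).
#' @return List with \code{agents} (data frame of new children) and
#'   \code{ties} (parent-child and sibling ties).
#' @export
spawn_children <- function(mother, father = NULL, n_children, year,
                           config = population_config(),
                           life_table = default_life_table(),
                           id_start = 1L) {
  pmf_f <- .lt_pmf(.lt_q(life_table, "female"))
  pmf_m <- .lt_pmf(.lt_q(life_table, "male"))
  .spawn_children_draw(mother_x = mother$x, mother_y = mother$y,
                       father_x = if (is.null(father)) NA_real_ else father$x,
                       father_y = if (is.null(father)) NA_real_ else father$y,
                       mother_id = mother$id,
                       father_id = if (is.null(father)) NA_integer_ else father$id,
                       n_children = n_children, year = year, config = config,
                       pmf_f = pmf_f, pmf_m = pmf_m, id_start = id_start)
}

# RNG order: inter-birth offsets, then personal attributes (see
# .draw_personal), then location noise x, then y.
.spawn_children_draw <- function(mother_x, mother_y, father_x, father_y,
                                 mother_id, father_id, n_children, year,
                                 config, pmf_f, pmf_m, id_start) {
  nk <- as.integer(n_children)
  stopifnot(nk >= 1L)
  offs <- c(0L, if (nk > 1L) stats::rpois(nk - 1L, config$interbirth_mean))
  pers <- .draw_personal(nk, config, pmf_f, pmf_m)
  m1 <- if (is.na(father_x)) mother_x else (mother_x + father_x) / 2
  m2 <- if (is.na(father_y)) mother_y else (mother_y + father_y) / 2
  w <- config$child_location_noise
  cx <- pmin(1, pmax(0, m1 + stats::runif(nk, -w, w)))
  cy <- pmin(1, pmax(0, m2 + stats::runif(nk, -w, w)))
  ids <- id_start + seq_len(nk) - 1L
  agents <- data.frame(
    id = ids,
    sex = c("female", "male")[pers$sex],
    birth_year = year + offs,
    death_year = year + offs + pers$lifespan,
    x = cx, y = cy,
    age_first_birth = pers$h,
    n_children = pers$nk,
    mother_id = mother_id,
    father_id = father_id
  )
  pc <- data.frame(agent_a = rep(c(mother_id, if (!is.na(father_id)) father_id),
                                 each = nk),
                   agent_b = rep(ids, times = if (is.na(father_id)) 1L else 2L),
                   relation = "parent_child", parent_endpoint = "a")
  sib <- NULL
  if (nk > 1L) {
    pr <- utils::combn(ids, 2L)
    sib <- data.frame(agent_a = pr[1, ], agent_b = pr[2, ],
                      relation = "sibling", parent_endpoint = NA_character_)
  }
  list(agents = agents, ties = rbind(pc, sib))
}

.sex_code <- function(sex) ifelse(sex == "female", 1L, 2L)

.as_agents_df <- function(population) {
  if (inherits(population, "synthetic_population")) population$agents
  else population
}

.spouse_index <- function(population, ag) {
  spouse_of <- rep(NA_integer_, nrow(ag))
  if (inherits(population, "synthetic_population")) {
    sp <- population$ties[population$ties$relation == "spouse", ]
    ia <- match(sp$agent_a, ag$id); ib <- match(sp$agent_b, ag$id)
    spouse_of[ia] <- ib; spouse_of[ib] <- ia
  }
  spouse_of
}

#' Generate the synthetic multi-generational population
#'
#' Initialises the founders, then advances a yearly clock for
#' \code{total_iterations} years. Each year, in order: scheduled births occur,
#' agents reaching their 10th birthday form friendships, females reaching
#' their age at first birth are assigned a partner and their children are
#' scheduled, and deaths due that year occur. Agents alive at any time at or
#' after \code{burn_in} are retained, together with all ties among retained
#' agents.
#'
#' @param config a \code{\link{population_config}}.
#' @param life_table a life table (see \code{\link{default_life_table}}).
#' @param seed integer seed; the output is fully reproducible from
#'   \code{(config, life_table, seed)}.
#' @return A \code{synthetic_population}: list with \code{agents} and
#'   \code{ties} data frames, \code{retained_from} (= \code{burn_in}) and the
#'   generating configuration. Tie relations are \code{parent_child} (parent
#'   stored as \code{agent_a}), \code{sibling}, \code{spouse}, \code{friend}.
#' @examples
#' cfg <- population_config(seed_size = 80, total_iterations = 60, burn_in = 30)
#' pop <- generate_population(cfg, seed = 1)
#' pop
#' @export
generate_population <- function(config = population_config(),
                                life_table = default_life_table(),
                                seed = 1L) {
  validate_population_config(config)
  validate_life_table(life_table)
  set.seed(as.integer(seed))
  pmf_f <- .lt_pmf(.lt_q(life_table, "female"))
  pmf_m <- .lt_pmf(.lt_q(life_table, "male"))

  cap <- max(4L * config$seed_size, 4096L)
  n <- config$seed_size
  sex <- integer(cap); b <- integer(cap); d <- integer(cap)
  x <- numeric(cap); y <- numeric(cap)
  h <- rep(NA_integer_, cap); nk <- rep(NA_integer_, cap)
  mother <- rep(NA_integer_, cap); father <- rep(NA_integer_, cap)
  spouse_of <- rep(NA_integer_, cap)
  friends <- vector("list", cap)

  grow <- function(need) {
    while (need > cap) {
      add <- cap
      sex <<- c(sex, integer(add)); b <<- c(b, integer(add))
      d <<- c(d, integer(add)); x <<- c(x, numeric(add)); y <<- c(y, numeric(add))
      h <<- c(h, rep(NA_integer_, add)); nk <<- c(nk, rep(NA_integer_, add))
      mother <<- c(mother, rep(NA_integer_, add))
      father <<- c(father, rep(NA_integer_, add))
      spouse_of <<- c(spouse_of, rep(NA_integer_, add))
      friends <<- c(friends, vector("list", add))
      cap <<- cap + add
    }
  }

  # Founders. RNG order: personal attributes, then birth years, then x, then y.
  pers <- .draw_personal(n, config, pmf_f, pmf_m)
  sex[1:n] <- pers$sex
  h[1:n] <- pers$h; nk[1:n] <- pers$nk
  b[1:n] <- as.integer(floor(stats::runif(
    n, config$birth_range[1], config$birth_range[2])))
  d[1:n] <- b[1:n] + pers$lifespan
  x[1:n] <- stats::runif(n); y[1:n] <- stats::runif(n)

  # Tie store (parent_child rows keep the parent as agent_a).
  t_cap <- 8L * cap; t_n <- 0L
  ta <- integer(t_cap); tb <- integer(t_cap); trel <- integer(t_cap)
  REL <- c("parent_child", "sibling", "spouse", "friend")
  push_ties <- function(a2, b2, rel) {
    k <- length(a2)
    if (k == 0L) return(invisible())
    while (t_n + k > t_cap) {
      ta <<- c(ta, integer(t_cap)); tb <<- c(tb, integer(t_cap))
      trel <<- c(trel, integer(t_cap)); t_cap <<- 2L * t_cap
    }
    ta[t_n + seq_len(k)] <<- a2; tb[t_n + seq_len(k)] <<- b2
    trel[t_n + seq_len(k)] <<- rel
    t_n <<- t_n + k
  }

  for (t in 0:(config$total_iterations - 1L)) {
    idx <- seq_len(n)
    alive <- b[idx] <= t & t <= d[idx]
    if (!any(alive)) {
      if (t <= config$burn_in)
        stop("population went extinct in year ", t, ", before burn-in ended")
      break
    }

    # 2. friendship formation at the 10th birthday (id order)
    formers <- idx[alive & (t - b[idx]) == 10L]
    for (i in formers) {
      fi <- .sample_pmf(config$friend_count_pmf, 1L)
      cand <- .friend_candidates(i, t, b[idx], d[idx], mother[idx], alive,
                                 config$friend_age_range)
      sel <- .nearest_by_distance(x[i], y[i], cand, x, y, fi)
      sel <- setdiff(sel, friends[[i]])
      if (length(sel)) {
        push_ties(rep(i, length(sel)), sel, 4L)
        friends[[i]] <- c(friends[[i]], sel)
        for (j in sel) friends[[j]] <- c(friends[[j]], i)
      }
    }

    # 3. partner assignment + child scheduling for females reaching h (id
    # order). Founders already past their first-birth age when the clock
    # starts begin their families at year 0: the recorded population growth
    # (1500 founders -> five-figure totals over 200 years) requires all
    # founding lineages to reproduce, not only those whose h falls inside
    # the simulated window.
    due <- (b[idx] + h[idx]) == t
    if (t == 0L) due <- due | (b[idx] + h[idx]) < 0L
    mothers <- idx[alive & sex[idx] == 1L & !is.na(h[idx]) &
                     due & nk[idx] >= 1L]
    for (i in mothers) {
      alive_now <- b[idx] <= t & t <= d[idx]
      cand <- .partner_candidates(i, t, b[idx], d[idx], sex[idx], mother[idx],
                                  father[idx], alive_now, spouse_of[idx],
                                  friends[[i]], config$partner_age_gap)
      sel <- .nearest_by_distance(x[i], y[i], cand, x, y, 1L)
      pid <- if (length(sel)) sel else NA_integer_
      if (!is.na(pid)) {
        spouse_of[i] <- pid; spouse_of[pid] <- i
        push_ties(min(i, pid), max(i, pid), 3L)
      }
      born <- .spawn_children_draw(
        mother_x = x[i], mother_y = y[i],
        father_x = if (is.na(pid)) NA_real_ else x[pid],
        father_y = if (is.na(pid)) NA_real_ else y[pid],
        mother_id = i, father_id = pid,
        n_children = nk[i], year = t, config = config,
        pmf_f = pmf_f, pmf_m = pmf_m, id_start = n + 1L)
      k <- nrow(born$agents)
      grow(n + k)
      at <- n + seq_len(k)
      sex[at] <- .sex_code(born$agents$sex)
      b[at] <- born$agents$birth_year; d[at] <- born$agents$death_year
      x[at] <- born$agents$x; y[at] <- born$agents$y
      h[at] <- born$agents$age_first_birth; nk[at] <- born$agents$n_children
      mother[at] <- i; father[at] <- pid
      n <- n + k
      push_ties(born$ties$agent_a, born$ties$agent_b,
                match(born$ties$relation, REL))
    }
    # 4. deaths due this year happen implicitly via the death-year comparison.
  }

  # Retention: alive at any time >= burn_in, and actually born during the run.
  idx <- seq_len(n)
  keep <- d[idx] >= config$burn_in & b[idx] < config$total_iterations
  keep_ids <- idx[keep]
  remap <- rep(NA_integer_, n); remap[keep_ids] <- seq_along(keep_ids)

  agents <- data.frame(
    id = seq_along(keep_ids),
    sex = c("female", "male")[sex[keep_ids]],
    birth_year = b[keep_ids], death_year = d[keep_ids],
    x = x[keep_ids], y = y[keep_ids],
    age_first_birth = h[keep_ids], n_children = nk[keep_ids],
    mother_id = remap[ifelse(is.na(mother[keep_ids]), n + 1L, mother[keep_ids])],
    father_id = remap[ifelse(is.na(father[keep_ids]), n + 1L, father[keep_ids])]
  )
  tt <- seq_len(t_n)
  ka <- remap[ta[tt]]; kb <- remap[tb[tt]]
  ok <- !is.na(ka) & !is.na(kb)
  ties <- data.frame(agent_a = ka[ok], agent_b = kb[ok],
                     relation = REL[trel[tt][ok]],
                     parent_endpoint = ifelse(REL[trel[tt][ok]] == "parent_child",
                                              "a", NA_character_))
  out <- list(agents = agents, ties = ties,
              retained_from = config$burn_in,
              total_iterations = config$total_iterations,
              config = config, seed = as.integer(seed))
  class(out) <- "synthetic_population"
  out
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("Synthetic population\n")
  cat("  retained agents:", nrow(x$agents), "\n")
  cat("  ties:", nrow(x$ties),
      sprintf("(%s)", paste(names(table(x$ties$relation)),
                            table(x$ties$relation), collapse = ", ")), "\n")
  cat("  clock: years", x$retained_from, "to", x$total_iterations,
      "retained (burn-in", x$retained_from, "years)\n")
  invisible(x)
}

#' @export
summary.synthetic_population <- function(object, ...) {
  ag <- object$agents
  alive_at <- function(t) sum(ag$birth_year <= t & t <= ag$death_year)
  out <- list(
    n_agents = nrow(ag),
    n_ties = nrow(object$ties),
    ties_by_relation = table(object$ties$relation),
    frac_female = mean(ag$sex == "female"),
    alive_at_epidemic_start = alive_at(object$retained_from)
  )
  class(out) <- "summary.synthetic_population"
  out
}

#' @export
print.summary.synthetic_population <- function(x, ...) {
  cat("agents:", x$n_agents, " ties:", x$n_ties, "\n")
  print(x$ties_by_relation)
  cat("fraction female:", round(x$frac_female, 3), "\n")
  cat("alive at epidemic start:", x$alive_at_epidemic_start, "\n")
  invisible(x)
}
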