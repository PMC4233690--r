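# Shared fixtures, memoised so expensive objects are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

white_dist <- function() cached("white", fit_sentence_nb(14, 10, label = "white"))
black_dist <- function() cached("black", fit_sentence_nb(17, 12, label = "black"))

# a one-month point-mass sentence law (degenerate corner of the fitted family)
unit_dist <- function() fit_sentence_nb(1, 1, label = "unit")

# Small population for structural tests: ~1 minute-scale everything.
small_population <- function() cached("small_pop", {
  cfg <- population_config(seed_size = 250, total_iterations = 120,
                           burn_in = 70)
  generate_population(cfg, seed = 42)
})

# Full study-scale population shared by the acceptance checks.
default_population <- function() cached("default_pop",
                                        generate_population(seed = 1))

# Study-scale ensembles shared across acceptance criteria (50 replicates).
scenario_ensemble <- function(name) {
  cached(paste0("ens_", name), {
    pop <- default_population()
    rt <- monthly_rate_table()
    cfg <- switch(name,
      white_50y = epidemic_config(white_dist(), rt, init_prevalence = 0.01,
                                  horizon = 600, n_replicates = 50,
                                  rng_seed = 2000),
      black_50y = epidemic_config(black_dist(), rt, init_prevalence = 0.01,
                                  horizon = 600, n_replicates = 50,
                                  rng_seed = 1000),
      black_cal = epidemic_config(black_dist(), rt, init_prevalence = 0.01,
                                  horizon = 300, n_replicates = 50,
                                  rng_seed = 3000),
      white_cal = epidemic_config(white_dist(), rt, init_prevalence = 0.0015,
                                  horizon = 300, n_replicates = 50,
                                  rng_seed = 4000))
    run_ensemble(pop, cfg)
  })
}

null_tuning <- function() {
  cached("null_tuning", {
    pop <- default_population()
    cfg <- epidemic_config(black_dist(), monthly_rate_table(),
                           init_prevalence = 0.01, horizon = 600,
                           n_replicates = 25, rng_seed = 5000)
    tune_spontaneous_rate(pop, cfg, target_prevalence = 0.03,
                          tolerance = 0.003)
  })
}

null_ensemble <- function(name) {
  cached(paste0("null_", name), {
    pop <- default_population()
    dist <- if (name == "black") black_dist() else white_dist()
    cfg <- epidemic_config(dist, monthly_rate_table(),
                           init_prevalence = 0.01, horizon = 600,
                           n_replicates = 25,
                           rng_seed = if (name == "black") 5000 else 6000)
    run_ensemble(pop, cfg, mechanism = "spontaneous",
                 spontaneous_rate = null_tuning()$rate)
  })
}

# Hand-built populations with known structure (all coordinates chosen so the
# network and ages are fully controlled). birth years are on the population
# clock with retained_from = 0, so epidemic month 0 is year 0.
toy_population <- function(agents, ties = NULL) {
  defaults <- data.frame(id = agents$id, sex = agents$sex,
                         birth_year = agents$birth_year,
                         death_year = agents$death_year)
  defaults$x <- if ("x" %in% names(agents)) agents$x else 0.5
  defaults$y <- if ("y" %in% names(agents)) agents$y else 0.5
  defaults$age_first_birth <- NA_integer_
  defaults$n_children <- NA_integer_
  defaults$mother_id <- if ("mother_id" %in% names(agents)) agents$mother_id else NA_integer_
  defaults$father_id <- if ("father_id" %in% names(agents)) agents$father_id else NA_integer_
  if (is.null(ties))
    ties <- data.frame(agent_a = integer(0), agent_b = integer(0),
                       relation = character(0),
                       parent_endpoint = character(0))
  if (!"parent_endpoint" %in% names(ties))
    ties$parent_endpoint <- ifelse(ties$relation == "parent_child", "a",
                                   NA_character_)
  structure(list(agents = defaults, ties = ties, retained_from = 0,
                 total_iterations = max(defaults$death_year) + 1,
                 config = NULL, seed = NA),
            class = "synthetic_population")
}

# n unrelated adult males on a line: 1 - 2 - 3 - ... joined by sibling ties.
line_population <- function(n = 3) {
  ag <- data.frame(id = seq_len(n), sex = "male",
                   birth_year = -30L, death_year = 300L)
  ties <- data.frame(agent_a = seq_len(n - 1), agent_b = 2:n,
                     relation = "sibling")
  toy_population(ag, ties)
}

# Exhaustive Markov-chain enumeration for an SIS epidemic with one-month
# sentences on an arbitrary undirected graph with homogeneous monthly rate p:
# with unit sentences the state is exactly the current infectious set, and
# I(t+1) = {j not in I(t) infected by some neighbour in I(t)}. Returns the
# expected prevalence at months 0..horizon given a uniformly chosen single
# initial infectious agent.
enumerate_unit_sis <- function(adj, p, horizon) {
  n <- nrow(adj)
  n_states <- 2^n
  members <- function(s) which(bitwAnd(s, 2^(seq_len(n) - 1)) > 0)
  trans <- matrix(0, n_states, n_states)
  for (s in 0:(n_states - 1)) {
    inf <- members(s)
    sus <- setdiff(seq_len(n), inf)
    # probability each susceptible becomes infected next month
    pj <- vapply(sus, function(j) {
      k <- sum(adj[j, inf])
      1 - (1 - p)^k
    }, numeric(1))
    # enumerate outcomes over susceptibles
    n_sus <- length(sus)
    for (mask in 0:(2^n_sus - 1)) {
      picked <- bitwAnd(mask, 2^(seq_len(n_sus) - 1)) > 0
      prob <- prod(ifelse(picked, pj, 1 - pj))
      s_next <- sum(2^(sus[picked] - 1))
      trans[s + 1, s_next + 1] <- trans[s + 1, s_next + 1] + prob
    }
  }
  # uniform single-seed initial distribution
  dist <- numeric(n_states)
  for (j in seq_len(n)) dist[2^(j - 1) + 1] <- 1 / n
  sizes <- vapply(0:(n_states - 1), function(s) length(members(s)), numeric(1))
  prev <- numeric(horizon + 1); prev_var <- numeric(horizon + 1)
  moments <- function(d) {
    m1 <- sum(d * sizes) / n
    m2 <- sum(d * sizes^2) / n^2
    c(m1, m2 - m1^2)
  }
  mm <- moments(dist)
  prev[1] <- mm[1]; prev_var[1] <- mm[2]
  for (m in seq_len(horizon)) {
    dist <- as.vector(dist %*% trans)
    mm <- moments(dist)
    prev[m + 1] <- mm[1]; prev_var[m + 1] <- mm[2]
  }
  list(mean = prev, var = prev_var)
}
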