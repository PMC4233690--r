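test_that("configuration invariants are enforced", {
  expect_error(population_config(friend_count_pmf = c("0" = 0.5, "1" = 0.4)),
               "sum to 1")
  expect_error(population_config(seed_size = 1), "seed_size")
  expect_error(population_config(burn_in = 200, total_iterations = 200),
               "burn_in")
  expect_error(population_config(partner_age_gap = c(9, 0)), "ordered")
})

test_that("agent attributes follow the configured distributions", {
  cfg <- population_config()
  set.seed(7)
  pers <- incarcsim:::.draw_personal(1e5, cfg,
                                     incarcsim:::.lt_pmf(incarcsim:::.lt_q(default_life_table(), "female")),
                                     incarcsim:::.lt_pmf(incarcsim:::.lt_q(default_life_table(), "male")))
  expect_lt(abs(mean(pers$sex == 1L) - 0.5), 0.01)
  fem <- pers$sex == 1L
  # age at first birth: 15 + Poisson(10.6), mean 25.6 years
  expect_lt(abs(mean(pers$h[fem]) - 25.6), 0.1)
  expect_true(all(pers$h[fem] >= 15))
  # completed fertility mean 2.07 children per woman
  expect_lt(abs(mean(pers$nk[fem]) - 2.07), 0.03)
})

test_that("friendship selection follows the nearest-candidate rule", {
  # agent 1 at its 10th birthday; candidates aged 9-11 at controlled distances
  ag <- data.frame(id = 1:7,
                   sex = c(rep("male", 6), "female"),
                   birth_year = c(-10, -9, -10, -11, -10, -30, -40),
                   death_year = 100,
                   x = c(0.5, 0.6, 0.7, 0.8, 0.55, 0.51, 0.9), y = 0.5,
                   mother_id = c(7L, NA, NA, NA, 7L, NA, NA),
                   father_id = NA_integer_)
  pop <- toy_population(ag)
  # agent 5 shares agent 1's mother: a sibling is never a candidate, even at
  # the smallest distance; agent 6 is outside the age window
  got <- assign_friends(pop, agent = 1, year = 0, n_friends = 2)
  expect_equal(sort(got), c(2, 3))
  got3 <- assign_friends(pop, agent = 1, year = 0, n_friends = 10)
  expect_equal(sort(got3), c(2, 3, 4))   # min(f, |candidates|) ties
  # empty candidate set
  got0 <- assign_friends(pop, agent = 1, year = 50, n_friends = 3)
  expect_length(got0, 0)
})

test_that("partner selection respects the age window, kinship and distance", {
  # female 1 (age 25 at year 0); males at varying ages/distances
  ag <- data.frame(id = c(1:5, 9L),
                   sex = c("female", "male", "male", "male", "male", "female"),
                   birth_year = c(-25, -35, -27, -26, -30, -60),
                   death_year = 100,
                   x = c(0.5, 0.52, 0.55, 0.60, 0.505, 0.9), y = 0.5,
                   mother_id = c(9L, NA, NA, NA, 9L, NA),
                   father_id = NA_integer_)
  pop <- toy_population(ag)
  # agent 2 is 10 years older (outside [0, 9]); agent 5 is her brother and
  # nearest of all; agent 3 (age 27, distance 0.05) beats agent 4 (0.10)
  expect_equal(assign_partner(pop, female = 1, year = 0), 3)
  # sole candidate outside the window -> single mother
  ag2 <- ag[1:2, ]
  expect_true(is.na(assign_partner(toy_population(ag2), female = 1, year = 0)))
})

test_that("children are scheduled and placed per the birth-spacing model", {
  cfg <- population_config()
  mother <- list(id = 1L, x = 0.3, y = 0.4)
  father <- list(id = 2L, x = 0.5, y = 0.8)
  set.seed(21)
  one <- spawn_children(mother, father, n_children = 1, year = 37, config = cfg,
                        id_start = 10L)
  expect_equal(nrow(one$agents), 1L)
  expect_equal(one$agents$birth_year, 37)   # first child born this year
  expect_equal(sum(one$ties$relation == "parent_child"), 2L)

  set.seed(22)
  out <- spawn_children(mother, father, n_children = 5, year = 37, config = cfg,
                        id_start = 10L)
  expect_equal(out$agents$birth_year[1], 37)
  expect_true(all(out$agents$birth_year >= 37))
  # locations inside the 0.05 box around the parents' midpoint
  expect_true(all(abs(out$agents$x - 0.4) <= 0.05 + 1e-12))
  expect_true(all(abs(out$agents$y - 0.6) <= 0.05 + 1e-12))
  # sibling ties among all children of the mother
  expect_equal(sum(out$ties$relation == "sibling"), choose(5, 2))

  # inter-birth offsets are Poisson with the configured mean
  set.seed(23)
  offs <- replicate(2e4, {
    ch <- incarcsim:::.spawn_children_draw(0.5, 0.5, NA_real_, NA_real_, 1L,
                                           NA_integer_, 2L, 0L, cfg,
                                           c(1, rep(0, 119)), c(1, rep(0, 119)),
                                           1L)
    ch$agents$birth_year[2]
  })
  expect_lt(abs(mean(offs) - 4.5), 0.05)
})

test_that("generated populations are reproducible and internally consistent", {
  pop <- small_population()
  cfg <- population_config(seed_size = 250, total_iterations = 120,
                           burn_in = 70)
  pop2 <- generate_population(cfg, seed = 42)
  expect_identical(pop$agents, pop2$agents)   # determinism
  expect_identical(pop$ties, pop2$ties)

  ag <- pop$agents; ties <- pop$ties
  # referential integrity: every tie joins retained agents, no self ties,
  # no duplicate unordered pairs
  expect_true(all(c(ties$agent_a, ties$agent_b) %in% ag$id))
  expect_true(all(ties$agent_a != ties$agent_b))
  key <- paste(pmin(ties$agent_a, ties$agent_b),
               pmax(ties$agent_a, ties$agent_b))
  expect_false(any(duplicated(key)))

  # retention: alive at any point at or after burn-in
  expect_true(all(ag$death_year >= pop$retained_from))
  expect_true(all(ag$birth_year < cfg$total_iterations))

  # locations stay in the unit square
  expect_true(all(ag$x >= 0 & ag$x <= 1 & ag$y >= 0 & ag$y <= 1))

  # age logic: parents are at least 15 years older than their children
  pc <- ties[ties$relation == "parent_child", ]
  expect_true(all(ag$birth_year[pc$agent_a] + 15 <= ag$birth_year[pc$agent_b]))

  # sibling closure: any two retained agents sharing a recorded mother are
  # joined by a sibling tie
  sibs <- split(ag$id[!is.na(ag$mother_id)], ag$mother_id[!is.na(ag$mother_id)])
  sib_key <- unlist(lapply(sibs[lengths(sibs) > 1], function(ids) {
    pr <- utils::combn(sort(ids), 2)
    paste(pr[1, ], pr[2, ])
  }))
  expect_true(all(sib_key %in% key[ties$relation == "sibling"]))

  # friendships joined agents within one year of age at formation
  fr <- ties[ties$relation == "friend", ]
  expect_true(all(abs(ag$birth_year[fr$agent_a] - ag$birth_year[fr$agent_b]) <= 2))

  # monogamy: no agent appears in two spouse ties
  sp <- ties[ties$relation == "spouse", ]
  expect_false(any(duplicated(c(sp$agent_a, sp$agent_b))))
})

test_that("extinction before the burn-in end is reported with the year", {
  lt <- expand.grid(age = 0:119, sex = c("female", "male"),
                    stringsAsFactors = FALSE)
  lt$q_death <- 1    # everyone dies at age 0
  cfg <- population_config(seed_size = 10, birth_range = c(-5, 0),
                           total_iterations = 50, burn_in = 30)
  expect_error(generate_population(cfg, lt, seed = 3), "extinct")
})
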