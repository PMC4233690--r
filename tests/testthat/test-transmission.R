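test_that("monthly rates invert the whole-sentence probability", {
  # survey brother/women cell 0.377 at the 14-month calibration sentence
  expect_equal(round(derive_monthly_rate(0.377, 14), 3), 0.033)
  expect_equal(round(derive_monthly_rate(0.147, 14), 3), 0.011)
  expect_identical(derive_monthly_rate(0, 7), 0)
  expect_error(derive_monthly_rate(1, 14), "undefined")

  expect_equal(cumulative_probability(0.25, 1), 0.25)   # one-month identity
  expect_equal(cumulative_probability(0.01, 14), 1 - 0.99^14)

  # algebraic inverse round trip
  set.seed(41)
  P <- runif(50, 0, 0.999); s <- sample(1:60, 50, replace = TRUE)
  expect_equal(cumulative_probability(derive_monthly_rate(P, s), s), P,
               tolerance = 1e-12)
})

test_that("rate table round-trips to the survey to machine precision", {
  sv <- survey_table()
  rt <- monthly_rate_table(sv, 14)
  expect_equal(cumulative_probability(rt$female, 14), sv$female,
               tolerance = 1e-12)
  expect_equal(cumulative_probability(rt$male, 14), sv$male,
               tolerance = 1e-12)
})

test_that("marginal probability reduces to the cumulative form for a point mass", {
  unit <- fit_sentence_nb(1, 1)
  m <- marginal_probability(0.033, unit, n_mc = 1e4)
  expect_equal(m$exact, cumulative_probability(0.033, 1), tolerance = 1e-10)
  expect_equal(m$estimate, m$exact, tolerance = 1e-12)  # all draws identical
})

test_that("Monte-Carlo marginals agree with the exact summation oracle", {
  rt <- monthly_rate_table()
  set.seed(42)
  for (d in list(white_dist(), black_dist())) {
    for (p in c(rt$female, rt$male)) {
      m <- marginal_probability(p, d, n_mc = 2e4)
      expect_lt(abs(m$estimate - m$exact), 4 * m$se)
    }
  }
})

test_that("black marginals exceed white marginals cell-wise, about 20% overall", {
  rt <- monthly_rate_table()
  mw <- marginal_table(rt, white_dist())
  mb <- marginal_table(rt, black_dist())
  expect_true(all(mb$female > mw$female))
  expect_true(all(mb$male > mw$male))
  ratio <- mean(c(mb$female / mw$female, mb$male / mw$male))
  expect_lt(abs(ratio - 1.2), 0.05)
})

test_that("marginal probability increases with the monthly rate", {
  d <- white_dist()
  ps <- seq(0.001, 0.05, by = 0.007)
  ex <- vapply(ps, function(p) marginal_probability(p, d, 1e4)$exact,
               numeric(1))
  expect_true(all(diff(ex) > 0))
})

test_that("pair rates resolve by role, sex and the adult-child rule", {
  rt <- monthly_rate_table()
  cell <- function(rel, col) rt[[col]][rt$relation == rel]
  fem_i <- list(id = 1L, sex = "female")
  male_i <- list(id = 1L, sex = "male")

  # female inmate -> her brother: brother row, women column
  tie <- list(agent_a = 1L, agent_b = 2L, relation = "sibling",
              parent_endpoint = NA)
  expect_equal(resolve_rate(fem_i, list(id = 2L, sex = "male"), tie, rt),
               cell("brother", "female"))
  expect_equal(round(resolve_rate(fem_i, list(id = 2L, sex = "male"), tie, rt), 3),
               0.033)
  # male inmate -> his female friend: treated as a sister
  tie$relation <- "friend"
  expect_equal(resolve_rate(male_i, list(id = 2L, sex = "female"), tie, rt),
               cell("sister", "male"))
  # spouse row keyed by inmate sex
  tie$relation <- "spouse"
  expect_equal(resolve_rate(fem_i, list(id = 2L, sex = "male"), tie, rt),
               cell("spouse", "female"))
  # inmate's parent: mother/father row by the parent's own sex
  tie <- list(agent_a = 2L, agent_b = 1L, relation = "parent_child",
              parent_endpoint = "a")
  expect_equal(resolve_rate(male_i, list(id = 2L, sex = "female"), tie, rt),
               cell("mother", "male"))
  # inmate's own child: adult-child row at 20, nothing at 10
  tie <- list(agent_a = 1L, agent_b = 2L, relation = "parent_child",
              parent_endpoint = "a")
  expect_equal(resolve_rate(fem_i, list(id = 2L, sex = "male"), tie, rt,
                            susceptible_age = 20),
               cell("adult_child", "female"))
  expect_identical(resolve_rate(fem_i, list(id = 2L, sex = "male"), tie, rt,
                                susceptible_age = 10), 0)
  # unknown relation label
  tie$relation <- "cousin"
  expect_error(resolve_rate(fem_i, list(id = 2L, sex = "male"), tie, rt),
               "unknown relation")
})

test_that("survey tables round-trip through CSV and are validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_relation_table(survey_table(), path)
  back <- read_survey_table(path)
  expect_equal(as.data.frame(back), as.data.frame(survey_table()))
  bad <- survey_table(); bad$female[1] <- 1.2
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_survey_table(path), "\\[0, 1\\]")
})
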