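#' Co-incarceration survey marginals
#'
#' Packaged default: the surveyed probability that an inmate's mother, father,
#' sister, brother, spouse or adult child is also incarcerated, by inmate sex.
#' These whole-sentence probabilities are the calibration source for the
#' monthly transmission rates.
#'
#' @return Data frame with columns \code{relation}, \code{female},
#'   \code{male} (the inmate's sex), class \code{"survey_table"}.
#' @export
survey_table <- function() {
  out <- data.frame(
    relation = c("mother", "father", "sister", "brother", "spouse",
                 "adult_child"),
    female = c(0.012, 0.147, 0.107, 0.377, 0.059, 0.213),
    male   = c(0.048, 0.148, 0.059, 0.349, 0.011, 0.085)
  )
  class(out) <- c("survey_table", "data.frame")
  out
}

.validate_relation_table <- function(tab, what) {
  need <- c("mother", "father", "sister", "brother", "spouse", "adult_child")
  if (!all(c("relation", "female", "male") %in% names(tab)))
    stop(what, " needs columns relation, female, male")
  if (!setequal(tab$relation, need) || nrow(tab) != 6L)
    stop(what, " must contain exactly the six relations: ",
         paste(need, collapse = ", "))
  vals <- c(tab$female, tab$male)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1))
    stop(what, " probabilities must lie in [0, 1]")
  invisible(tab)
}

#' Read / write relation-by-sex probability tables as CSV
#'
#' @param path CSV path; columns \code{relation}, \code{female}, \code{male}.
#' @return \code{read_survey_table}: a validated \code{survey_table}.
#' @export
read_survey_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_relation_table(tab, "survey table")
  class(tab) <- c("survey_table", "data.frame")
  tab
}

#' @rdname read_survey_table
#' @param table a \code{survey_table} or \code{rate_table}.
#' @export
write_relation_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("relation", "female", "male")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Monthly transmission probability from a whole-sentence probability
#'
#' Inverts the cumulative-transmission relation: if transmission occurs
#' independently each month with probability p over an s-month sentence, the
#' whole-sentence probability is \eqn{P = 1-(1-p)^s}, so
#' \eqn{p = 1-(1-P)^{1/s}}.
#'
#' @param p_total whole-sentence transmission probability, in \code{[0, 1)}.
#' @param s calibration sentence length in months (>= 1).
#' @return Monthly probability.
#' @export
derive_monthly_rate <- function(p_total, s) {
  if (any(p_total < 0 | p_total >= 1))
    stop("p_total must lie in [0, 1); a monthly rate is undefined at 1")
  if (any(s < 1)) stop("s must be >= 1 month")
  1 - (1 - p_total)^(1 / s)
}

#' Cumulative transmission probability over a sentence
#'
#' The complement of the probability that no transmission occurs in any of
#' the s months of the sentence: \eqn{1-(1-p)^s}.
#'
#' @param p_monthly monthly transmission probability in \code{[0, 1]}.
#' @param s sentence length in months (integer >= 0).
#' @return Probability of at least one transmission during the sentence.
#' @export
cumulative_probability <- function(p_monthly, s) {
  if (any(p_monthly < 0 | p_monthly > 1)) stop("p_monthly must lie in [0, 1]")
  if (any(s < 0)) stop("s must be >= 0")
  1 - (1 - p_monthly)^s
}

#' Derive the monthly transmission-rate table from survey marginals
#'
#' Applies \code{\link{derive_monthly_rate}} to every cell of the survey
#' table at the calibration sentence length (default 14 months, between the
#' two race-specific means). Full precision is kept internally; the
#' round-trip \eqn{1-(1-p)^s} reproduces each survey cell exactly.
#'
#' @param survey a \code{\link{survey_table}}.
#' @param calibration_sentence s used in the derivation, months.
#' @return Data frame with class \code{"rate_table"}: columns
#'   \code{relation}, \code{female}, \code{male} (monthly rates, columns
#'   indexed by the inmate's sex) and attribute \code{calibration_sentence}.
#' @examples
#' monthly_rate_table()    # the study's monthly rates at s = 14
#' @export
monthly_rate_table <- function(survey = survey_table(),
                               calibration_sentence = 14) {
  .validate_relation_table(survey, "survey table")
  out <- data.frame(
    relation = survey$relation,
    female = derive_monthly_rate(survey$female, calibration_sentence),
    male = derive_monthly_rate(survey$male, calibration_sentence)
  )
  attr(out, "calibration_sentence") <- calibration_sentence
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Sentence-marginalised transmission probability
#'
#' The probability of at least one transmission over a whole sentence drawn
#' from a fitted sentence-length distribution:
#' \eqn{\sum_s \pi(s)\,[1-(1-p)^s]}. Returns a Monte-Carlo estimate with its
#' standard error alongside an exact summation over the support (truncated
#' where the survivor mass falls below \code{tail_mass}).
#'
#' @param p_monthly monthly transmission probability.
#' @param sentence_dist a \code{\link{fit_sentence_nb}} object.
#' @param n_mc number of Monte-Carlo draws (>= 1e4).
#' @param tail_mass truncation point for the exact summation.
#' @return List with \code{estimate}, \code{se} (Monte Carlo) and
#'   \code{exact} (deterministic oracle).
#' @export
marginal_probability <- function(p_monthly, sentence_dist, n_mc = 1e5,
                                 tail_mass = 1e-10) {
  if (n_mc < 1e4) stop("n_mc must be at least 1e4")
  s_max <- stats::qnbinom(tail_mass, size = sentence_dist$size,
                          prob = sentence_dist$prob, lower.tail = FALSE) + 2L
  s <- seq_len(s_max)
  exact <- sum(dsentence(s, sentence_dist) * (1 - (1 - p_monthly)^s))
  draws <- 1 - (1 - p_monthly)^sample_sentence(sentence_dist, n_mc)
  list(estimate = mean(draws),
       se = stats::sd(draws) / sqrt(n_mc),
       exact = exact)
}

#' Marginal probabilities for every cell of a rate table
#'
#' @param rate_table a \code{\link{monthly_rate_table}}.
#' @param sentence_dist a fitted sentence distribution (one race scenario).
#' @param n_mc Monte-Carlo draws per cell; \code{0} to report only the exact
#'   summation.
#' @return Data frame: relation, female, male (marginal probabilities).
#' @export
marginal_table <- function(rate_table, sentence_dist, n_mc = 0) {
  cell <- if (n_mc > 0) {
    function(p) marginal_probability(p, sentence_dist, n_mc)$estimate
  } else {
    function(p) marginal_probability(p, sentence_dist, 1e4)$exact
  }
  data.frame(relation = rate_table$relation,
             female = vapply(rate_table$female, cell, numeric(1)),
             male = vapply(rate_table$male, cell, numeric(1)))
}

#' Resolve the monthly transmission rate for an (infectious, susceptible) pair
#'
#' The table row is the susceptible's role relative to the inmate: a
#' susceptible parent takes the mother/father row by the parent's own sex; a
#' sibling -- and, equivalently, a close friend -- takes the sister/brother
#' row by the susceptible's sex; a spouse takes the spouse row; the inmate's
#' own child takes the adult-child row only once the child has reached
#' \code{adult_child_age}, and transmits nothing before that. The column is
#' always the inmate's sex.
#'
#' @param infectious,susceptible one-row lists/data frames with at least
#'   \code{id} and \code{sex}.
#' @param tie a one-row list/data frame with \code{agent_a}, \code{agent_b},
#'   \code{relation} and (for parent-child ties) \code{parent_endpoint}
#'   ("a" if \code{agent_a} is the parent).
#' @param table a \code{\link{monthly_rate_table}}.
#' @param susceptible_age the susceptible's current age in years (needed only
#'   for the adult-child rule).
#' @param adult_child_age age (years) at which an inmate's child becomes a
#'   transmission target.
#' @return Monthly transmission probability.
#' @export
resolve_rate <- function(infectious, susceptible, tie, table,
                         susceptible_age = NA, adult_child_age = 18) {
  if (!tie$relation %in% c("parent_child", "sibling", "spouse", "friend"))
    stop("unknown relation label: ", tie$relation)
  if (!all(c(infectious$id, susceptible$id) %in% c(tie$agent_a, tie$agent_b)))
    stop("tie does not join the two agents")
  row <- switch(
    tie$relation,
    spouse = "spouse",
    sibling = ,
    friend = if (susceptible$sex == "female") "sister" else "brother",
    parent_child = {
      parent_id <- if (identical(tie$parent_endpoint, "a")) tie$agent_a else tie$agent_b
      if (susceptible$id == parent_id) {
        if (susceptible$sex == "female") "mother" else "father"
      } else {
        if (is.na(susceptible_age) || susceptible_age < adult_child_age)
          return(0)
        "adult_child"
      }
    })
  col <- if (infectious$sex == "female") "female" else "male"
  table[[col]][match(row, table$relation)]
}
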