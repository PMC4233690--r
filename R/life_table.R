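#' Sex-specific annual life tables
#'
#' A life table gives, for each sex and each integer age 0--119, the
#' probability of dying before the next birthday. Age 119 is absorbing
#' (probability 1), so every sampled lifespan lies in \code{[0, 120)}.
#'
#' The packaged default is a Gompertz--Makeham table: the annual hazard at age
#' x is \eqn{A + R e^{\theta x}}, with the level parameter R calibrated by
#' bisection (separately per sex) so that life expectancy at birth is
#' approximately 81 years for females and 76 for males, matching 2009-era US
#' values. Users may replace it with an official table via
#' \code{\link{read_life_table}}.
#'
#' @param e0_female,e0_male target life expectancy at birth, in years.
#' @param makeham background (age-independent) annual hazard.
#' @param theta Gompertz log-slope of the senescent hazard, per year of age.
#' @return A data frame with columns \code{sex} ("female"/"male"), \code{age}
#'   (0--119) and \code{q_death}, carrying class \code{"life_table"}.
#' @examples
#' lt <- default_life_table()
#' life_expectancy(lt, "female")
#' @export
default_life_table <- function(e0_female = 81, e0_male = 76,
                               makeham = 2e-4, theta = 0.095) {
  ages <- 0:119
  q_for <- function(R) {
    haz <- makeham + R * exp(theta * ages) * (exp(theta) - 1) / theta
    q <- 1 - exp(-haz)
    q[length(q)] <- 1
    q
  }
  calibrate <- function(target) {
    f <- function(logR) .lt_expectation(q_for(exp(logR))) - target
    r <- stats::uniroot(f, lower = log(1e-8), upper = log(1e-2), tol = 1e-12)
    q_for(exp(r$root))
  }
  out <- data.frame(
    sex = rep(c("female", "male"), each = 120),
    age = rep(ages, 2),
    q_death = c(calibrate(e0_female), calibrate(e0_male))
  )
  class(out) <- c("life_table", "data.frame")
  out
}

#' Read a life table from CSV
#'
#' Expected columns: \code{sex}, \code{age}, \code{q_death}; ages 0--119 must
#' be complete for each sex and probabilities must lie in \code{[0,1]} with
#' \code{q_death = 1} at age 119.
#'
#' @param path path to a CSV file.
#' @return A validated \code{life_table} data frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(lt)
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' @rdname read_life_table
#' @param life_table a candidate life table.
#' @export
validate_life_table <- function(life_table) {
  need <- c("sex", "age", "q_death")
  if (!all(need %in% names(life_table)))
    stop("life table must have columns: ", paste(need, collapse = ", "))
  for (sx in c("female", "male")) {
    sub <- life_table[life_table$sex == sx, ]
    sub <- sub[order(sub$age), ]
    if (!identical(as.integer(sub$age), 0:119))
      stop("life table for ", sx, " must cover ages 0-119 exactly once")
    if (any(sub$q_death < 0 | sub$q_death > 1) || any(!is.finite(sub$q_death)))
      stop("death probabilities must lie in [0, 1]")
    if (sub$q_death[120] != 1)
      stop("death probability at age 119 must be 1 (absorbing)")
  }
  invisible(life_table)
}

# Lifespan pmf over ages 0..119 implied by sequential survival through q.
.lt_pmf <- function(q) {
  surv <- cumprod(c(1, 1 - q[-length(q)]))
  surv * q
}

.lt_expectation <- function(q) {
  sum((0:119) * .lt_pmf(q))
}

.lt_q <- function(life_table, sex) {
  sub <- life_table[life_table$sex == sex, ]
  sub$q_death[order(sub$age)]
}

#' Expected lifespan under a life table
#'
#' Computes the exact expectation of the integer lifespan (age in completed
#' years at death) by direct summation over the survival distribution.
#'
#' @param life_table a \code{life_table}.
#' @param sex "female" or "male".
#' @return Expected lifespan in years.
#' @export
life_expectancy <- function(life_table, sex = c("female", "male")) {
  sex <- match.arg(sex)
  validate_life_table(life_table)
  .lt_expectation(.lt_q(life_table, sex))
}

#' Sample integer lifespans from a life table
#'
#' Lifespans follow the distribution induced by surviving each year of age
#' with probability \code{1 - q_death(age)}: the probability of dying at age x
#' is \eqn{q(x)\prod_{a<x}(1-q(a))}.
#'
#' @param life_table a \code{life_table}.
#' @param sex "female" or "male".
#' @param n number of draws.
#' @return Integer vector of lifespans in \code{[0, 120)}.
#' @export
sample_lifespan <- function(life_table, sex = c("female", "male"), n = 1) {
  sex <- match.arg(sex)
  validate_life_table(life_table)
  pmf <- .lt_pmf(.lt_q(life_table, sex))
  sample.int(120L, size = n, replace = TRUE, prob = pmf) - 1L
}
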