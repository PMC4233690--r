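#' Fit a sentence-length distribution to a target mean and median
#'
#' Sentences served (in months) are modelled as \eqn{S = 1 + X} with
#' \eqn{X \sim \mathrm{NB}(r, q)} on \{0, 1, 2, ...\}; the +1 shift guarantees
#' every sentence lasts at least one month, so the infectious period is never
#' empty. The fit scans a grid of the dispersion parameter r; for each r the
#' success probability is solved exactly from the mean constraint
#' (\eqn{E[S] = 1 + r(1-q)/q =} \code{target_mean}), and among grid points
#' whose CDF-based integer median equals \code{target_median} the smallest r
#' is chosen (all grid points match the mean exactly, so the tie-break on the
#' mean error reduces to preferring the smallest dispersion). The procedure is
#' deterministic.
#'
#' @param target_mean target mean sentence, months.
#' @param target_median target integer median sentence, months. Must satisfy
#'   \code{target_mean > target_median >= 1} (right skew) or
#'   \code{target_mean == target_median} (degenerate point mass allowed).
#' @param label optional label (e.g. "white", "black") carried in the object.
#' @param dispersion_grid grid of dispersion values scanned.
#' @return An object of class \code{"sentence_dist"} with elements
#'   \code{size}, \code{prob} (NB parameters of the unshifted variable),
#'   \code{mean}, \code{median} (achieved values on the shifted scale) and the
#'   targets.
#' @examples
#' white <- fit_sentence_nb(14, 10, label = "white")
#' white
#' mean(white); median(white)
#' @export
fit_sentence_nb <- function(target_mean, target_median, label = NULL,
                            dispersion_grid = seq(0.055, 50, by = 0.005)) {
  if (target_median < 1) stop("target_median must be >= 1 month")
  if (target_median != floor(target_median))
    stop("target_median must be a whole number of months")
  if (target_mean < target_median)
    stop("target_mean must be >= target_median (right-skewed or degenerate)")
  m <- target_mean - 1   # mean of the unshifted NB variable
  if (m == 0 || target_mean == target_median && target_median == 1) {
    # point mass at 1 month: NB with success probability 1
    out <- list(label = label, size = 1, prob = 1,
                mean = 1, median = 1L,
                target_mean = target_mean, target_median = target_median)
    class(out) <- "sentence_dist"
    return(out)
  }
  q <- dispersion_grid / (dispersion_grid + m)
  med <- stats::qnbinom(0.5, size = dispersion_grid, prob = q) + 1L
  hit <- which(med == as.integer(target_median))
  if (length(hit) == 0L) {
    attainable <- sort(unique(med))
    nearest <- attainable[which.min(abs(attainable - target_median))]
    stop("no negative-binomial parameterisation with mean ", target_mean,
         " attains median ", target_median,
         "; nearest attainable median: ", nearest)
  }
  r <- dispersion_grid[hit[1L]]
  qq <- q[hit[1L]]
  out <- list(label = label, size = r, prob = qq,
              mean = 1 + r * (1 - qq) / qq,
              median = as.integer(stats::qnbinom(0.5, size = r, prob = qq)) + 1L,
              target_mean = target_mean, target_median = target_median)
  class(out) <- "sentence_dist"
  out
}

#' @export
print.sentence_dist <- function(x, ...) {
  cat("Sentence-length distribution",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  shifted negative binomial: size =", format(x$size),
      " prob =", format(x$prob, digits = 6), "\n")
  cat("  mean =", format(x$mean, digits = 6), "months; median =",
      x$median, "months\n")
  invisible(x)
}

#' @export
mean.sentence_dist <- function(x, ...) x$mean

#' @importFrom stats median
#' @export
median.sentence_dist <- function(x, na.rm = FALSE, ...) x$median

#' Probability mass and distribution functions of a fitted sentence law
#'
#' @param k integer sentence lengths (months, >= 1).
#' @param dist a \code{\link{fit_sentence_nb}} object.
#' @return \code{dsentence}: P(S = k); \code{psentence}: P(S <= k).
#' @export
dsentence <- function(k, dist) {
  out <- numeric(length(k))
  ok <- k >= 1 & k == floor(k)
  out[ok] <- stats::dnbinom(k[ok] - 1, size = dist$size, prob = dist$prob)
  out
}

#' @rdname dsentence
#' @export
psentence <- function(k, dist) {
  out <- numeric(length(k))
  out[k >= 1] <- stats::pnbinom(floor(k[k >= 1]) - 1,
                                size = dist$size, prob = dist$prob)
  out
}

#' Sample sentences from a fitted distribution
#'
#' @param dist a \code{\link{fit_sentence_nb}} object.
#' @param n number of draws.
#' @return Integer vector of sentence lengths in months (all >= 1).
#' @export
sample_sentence <- function(dist, n = 1) {
  stats::rnbinom(n, size = dist$size, prob = dist$prob) + 1L
}

#' @importFrom stats simulate
#' @export
simulate.sentence_dist <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sample_sentence(object, nsim)
}
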