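#' Combinatorics of the Alda scale item structure
#'
#' The Alda score of lithium responsiveness combines an "A" subscale (a
#' single ordinal rating of overall response, 0--10) with a "B" subscale of
#' five criteria (each scored 0--2) that discount improvement not causally
#' attributable to lithium.  The total score is the A score minus the sum of
#' the B items, floored at zero.  Because high totals require both a high A
#' score and a near-zero B sum, far fewer item combinations can produce a
#' high score than a low one -- the combinatorial root of the scale's
#' asymmetric reliability.
#'
#' @name alda-scale
NULL

.validate_alda_items <- function(a_score, b_items) {
  if (length(a_score) != 1L || is.na(a_score) || a_score != as.integer(a_score))
    stop("`a_score` must be a single integer", call. = FALSE)
  if (a_score < 0 || a_score > 10)
    stop("`a_score` out of range: must lie in 0..10, got ", a_score, call. = FALSE)
  if (length(b_items) != 5L || anyNA(b_items) || any(b_items != as.integer(b_items)))
    stop("`b_items` must be five integers", call. = FALSE)
  if (any(b_items < 0 | b_items > 2))
    stop("`b_items` out of range: each must lie in 0..2", call. = FALSE)
  invisible(NULL)
}

#' Total Alda score from subscale items
#'
#' @param a_score Integer in 0..10, the A-subscale rating.
#' @param b_items Integer vector of length 5, each element in 0..2.
#' @return Integer total score in 0..10: `max(0, a_score - sum(b_items))`.
#' @examples
#' alda_total_score(9, c(1, 1, 0, 0, 0))  # 7
#' alda_total_score(5, c(2, 2, 2, 2, 2))  # floored at 0
#' @export
alda_total_score <- function(a_score, b_items) {
  .validate_alda_items(a_score, b_items)
  max(0L, as.integer(a_score) - as.integer(sum(b_items)))
}

#' Enumerate all Alda item combinations
#'
#' Exhaustively enumerates the 11 x 3^5 = 2673 distinct item tuples
#' (A, B1..B5) and their total scores.
#'
#' @return A data frame with columns `a`, `b1`..`b5`, `b_sum`, `total`,
#'   one row per combination (2673 rows).
#' @export
alda_combinations <- function() {
  g <- expand.grid(a = 0:10, b1 = 0:2, b2 = 0:2, b3 = 0:2, b4 = 0:2, b5 = 0:2,
                   KEEP.OUT.ATTRS = FALSE)
  g$b_sum <- g$b1 + g$b2 + g$b3 + g$b4 + g$b5
  g$total <- pmax(0L, g$a - g$b_sum)
  g
}

#' Count item combinations yielding a range of total scores
#'
#' @param min_total,max_total Integers, 0 <= min_total <= max_total <= 10.
#' @return Integer count of item tuples whose total score lies in
#'   `[min_total, max_total]`.
#' @examples
#' count_combinations(7, 10)  # 79 ways to be a lithium responder
#' count_combinations(0, 3)   # 2159 ways to score at most 3
#' @export
count_combinations <- function(min_total = 0L, max_total = 10L) {
  for (v in list(min_total, max_total))
    if (length(v) != 1L || is.na(v) || v != as.integer(v))
      stop("score bounds must be single integers", call. = FALSE)
  if (min_total < 0 || max_total > 10 || min_total > max_total)
    stop("invalid range: need 0 <= min_total <= max_total <= 10", call. = FALSE)
  tot <- alda_combinations()$total
  sum(tot >= min_total & tot <= max_total)
}

#' Distribution of the B-subscale sum
#'
#' Counts, over all 3^5 = 243 B-item tuples, how many have each possible
#' sum 0..10.  Equals the coefficients of (1 + x + x^2)^5.
#'
#' @return Named integer vector (names "0".."10") summing to 243.
#' @export
b_sum_distribution <- function() {
  s <- alda_combinations()
  s <- s[s$a == 0L, "b_sum"]  # one copy of each B tuple
  tab <- tabulate(s + 1L, nbins = 11L)
  names(tab) <- as.character(0:10)
  tab
}

# The subtract-and-floor scoring rule is adopted because it uniquely
# reproduces both published combination counts; assert that at install.
local({
  cmb <- expand.grid(a = 0:10, b1 = 0:2, b2 = 0:2, b3 = 0:2, b4 = 0:2, b5 = 0:2)
  total <- pmax(0L, cmb$a - (cmb$b1 + cmb$b2 + cmb$b3 + cmb$b4 + cmb$b5))
  stopifnot(sum(total >= 7) == 79L, sum(total <= 3) == 2159L, length(total) == 2673L)
})
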