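#' Dirichlet-multinomial model of observed ratings given gold standards
#'
#' The empirical stage models the count vector of observed scores for each
#' gold-standard score k as multinomial with a symmetric Dirichlet prior of
#' concentration alpha (a pseudocount acting as a priori observation
#' noise).  The dichotomized scale gets its own concentration xi; setting
#' xi = 11 * alpha / 2 equalizes the total prior mass between the
#' 11-category and 2-category representations, so the two mutual-information
#' curves can be compared on one axis.
#'
#' @name rating-model
NULL

#' Consensus gold-standard scores for the twelve assessment vignettes
#'
#' Integer Alda scores assigned by consensus to the twelve standardized
#' case vignettes used in the multi-site inter-rater reliability study.
#' @format Integer vector of length 12.
#' @export
alda_gold_standard <- c(8L, 9L, 6L, 7L, 9L, 3L, 5L, 9L, 3L, 9L, 5L, 1L)

#' Read an inter-rater rating matrix from CSV
#'
#' Expected layout: a header row of vignette identifiers, one row per rater,
#' optionally preceded by a `site` column.  Cells are integer scores 0--10;
#' blank cells are treated as missing and dropped from downstream counts.
#'
#' @param path Path to the CSV file.
#' @param gold Integer vector of gold-standard scores, one per vignette
#'   column (default: the study's twelve consensus scores).
#' @return A `rating_matrix` object: list with `scores` (raters x vignettes
#'   integer matrix, `NA` for missing), `site` (character per rater or
#'   `NULL`), `gold`, `n_raters`, `vignette_ids`, `dropped_cells`.
#' @export
read_ratings <- function(path, gold = alda_gold_standard) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  site <- NULL
  if (ncol(raw) > 0 && tolower(names(raw)[1]) == "site") {
    site <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  }
  if (ncol(raw) != length(gold))
    stop("schema error: found ", ncol(raw), " vignette columns, expected ",
         length(gold), call. = FALSE)
  scores <- as.matrix(raw)
  storage.mode(scores) <- "double"
  bad <- which(!is.na(scores) & (scores != round(scores) | scores < 0 | scores > 10),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("parse error: score out of range or non-integer at rater row ",
         bad[1, 1], ", vignette column '", colnames(raw)[bad[1, 2]], "'",
         call. = FALSE)
  storage.mode(scores) <- "integer"
  new_rating_matrix(scores, gold, site = site,
                    vignette_ids = colnames(raw))
}

new_rating_matrix <- function(scores, gold, site = NULL, vignette_ids = NULL) {
  if (is.null(vignette_ids))
    vignette_ids <- paste0("V", seq_len(ncol(scores)))
  structure(list(
    scores = scores,
    site = site,
    gold = as.integer(gold),
    n_raters = nrow(scores),
    vignette_ids = vignette_ids,
    dropped_cells = sum(is.na(scores))
  ), class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat("Inter-rater rating matrix:", x$n_raters, "raters x",
      length(x$vignette_ids), "vignettes\n")
  cat("  gold standards:", paste(x$gold, collapse = " "), "\n")
  if (x$dropped_cells > 0)
    cat("  missing cells dropped from counts:", x$dropped_cells, "\n")
  invisible(x)
}

#' Write a rating matrix to CSV
#'
#' Inverse of [read_ratings()]: header row of vignette ids, one row per
#' rater, with a leading `site` column when site labels are present.
#'
#' @param ratings A `rating_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(inherits(ratings, "rating_matrix"))
  df <- as.data.frame(ratings$scores)
  names(df) <- ratings$vignette_ids
  if (!is.null(ratings$site)) df <- cbind(site = ratings$site, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Build per-gold-score observed-rating count tables
#'
#' For each gold-standard score k in 0..10, tallies how many (rater,
#' vignette) ratings took each observed value i in 0..10, across the
#' vignettes whose gold standard is k.  Missing cells are dropped.
#'
#' @param ratings A `rating_matrix`.
#' @return A `count_table_set`: list with `counts` (11 x 11 matrix, rows =
#'   gold score 0..10, columns = observed score 0..10), `observed` (logical,
#'   which gold scores have at least one vignette), `imputed` (logical, all
#'   `FALSE` here), and `n_ratings` (total tallied ratings).
#' @export
build_count_tables <- function(ratings) {
  stopifnot(inherits(ratings, "rating_matrix"))
  counts <- matrix(0, 11, 11, dimnames = list(gold = 0:10, observed = 0:10))
  for (j in seq_along(ratings$gold)) {
    obs <- ratings$scores[, j]
    obs <- obs[!is.na(obs)]
    if (length(obs) > 0)
      counts[ratings$gold[j] + 1L, ] <- counts[ratings$gold[j] + 1L, ] +
        tabulate(obs + 1L, nbins = 11L)
  }
  structure(list(
    counts = counts,
    observed = (0:10) %in% ratings$gold,
    imputed = rep(FALSE, 11),
    n_ratings = sum(counts)
  ), class = "count_table_set")
}

#' @export
print.count_table_set <- function(x, ...) {
  cat("Count table set:", x$n_ratings, "ratings;",
      sum(x$observed), "gold scores observed,",
      sum(x$imputed), "imputed\n")
  invisible(x)
}

is_complete_tables <- function(tables) all(tables$observed | tables$imputed)

#' Impute count vectors for unobserved gold-standard scores
#'
#' Gold scores with no vignette get a count vector borrowed from their
#' neighbours: the boundary scores copy their single neighbour
#' (`n(0) <- n(1)`, `n(10) <- n(9)`) and interior scores take the
#' element-wise mean of the two flanking vectors, filled in ascending
#' order of k.  With the study's gold standards this imputes k in
#' {0, 2, 4, 10}.  Patterns that would require an unobserved, not-yet-filled
#' neighbour are rejected rather than chain-imputed silently.
#'
#' @param tables A `count_table_set`.
#' @return The completed `count_table_set` (counts may be fractional on
#'   imputed rows; `imputed` flags which rows were filled).
#' @export
impute_missing_counts <- function(tables) {
  stopifnot(inherits(tables, "count_table_set"))
  if (!any(tables$observed))
    stop("no observed gold-standard scores to impute from", call. = FALSE)
  counts <- tables$counts
  avail <- tables$observed
  imputed <- tables$imputed
  for (k in 0:10) {
    if (avail[k + 1L]) next
    if (k == 0L) {
      if (!tables$observed[2L])
        stop("unsupported missingness pattern: k = 0 and k = 1 both unobserved",
             call. = FALSE)
      counts[1L, ] <- counts[2L, ]
    } else if (k == 10L) {
      if (!avail[10L])
        stop("unsupported missingness pattern: k = 10 and k = 9 both unavailable",
             call. = FALSE)
      counts[11L, ] <- counts[10L, ]
    } else {
      if (!avail[k] || !tables$observed[k + 2L])
        stop("unsupported missingness pattern at gold score k = ", k,
             ": both neighbours must be observed (or already imputed, below k)",
             call. = FALSE)
      counts[k + 1L, ] <- (counts[k, ] + counts[k + 2L, ]) / 2
    }
    avail[k + 1L] <- TRUE
    imputed[k + 1L] <- TRUE
  }
  tables$counts <- counts
  tables$imputed <- imputed
  tables
}

#' MAP estimate of a smoothed categorical conditional
#'
#' Mode of the Dirichlet posterior for a multinomial count vector under a
#' symmetric Dirichlet(alpha) prior: each cell is proportional to
#' `alpha + n_i - 1`, clamped at zero before normalization (the simplex
#' boundary solution, needed when `alpha < 1`).
#'
#' @param counts Non-negative numeric vector of category counts.
#' @param alpha Non-negative prior concentration (pseudocount).
#' @return Probability vector of the same length, summing to 1.
#' @export
map_conditional <- function(counts, alpha) {
  stopifnot(is.numeric(counts), all(counts >= 0), length(alpha) == 1L, alpha >= 0)
  w <- pmax(0, alpha + counts - 1)
  s <- sum(w)
  if (s <= 0)
    stop("degenerate distribution: all posterior-mode weights clamped to zero ",
         "(alpha = ", alpha, ")", call. = FALSE)
  w / s
}

#' MAP estimate for the dichotomized (2-category) conditional
#'
#' Same posterior-mode rule as [map_conditional()] restricted to the
#' responder / non-responder split, with its own concentration `xi`.
#'
#' @param counts Length-2 non-negative counts (below-threshold,
#'   at-or-above-threshold).
#' @param xi Non-negative prior concentration for the binary scale.
#' @return Length-2 probability vector.
#' @export
map_binary <- function(counts, xi) {
  stopifnot(length(counts) == 2L)
  map_conditional(counts, xi)
}

#' Collapse count tables to a 2 x 2 dichotomized table
#'
#' Aggregates the 11 x 11 gold-by-observed counts into the four cells
#' (gold < tau / >= tau) x (observed < tau / >= tau).  Responders are
#' scores >= tau.  Grand totals are preserved exactly.
#'
#' @param tables A completed (imputed) `count_table_set`.
#' @param tau Integer dichotomization threshold, 0 < tau <= 10.
#' @return 2 x 2 matrix, rows = gold class (`"lt_tau"`, `"ge_tau"`),
#'   columns = observed class.
#' @export
dichotomize_counts <- function(tables, tau = 7L) {
  stopifnot(inherits(tables, "count_table_set"), length(tau) == 1L,
            tau > 0, tau <= 10)
  if (!is_complete_tables(tables))
    stop("count tables must be imputed first (see impute_missing_counts)",
         call. = FALSE)
  lo <- seq_len(tau)              # scores 0 .. tau-1
  hi <- seq.int(tau + 1L, 11L)    # scores tau .. 10
  m <- matrix(c(sum(tables$counts[lo, lo]), sum(tables$counts[lo, hi]),
                sum(tables$counts[hi, lo]), sum(tables$counts[hi, hi])),
              nrow = 2, byrow = TRUE,
              dimnames = list(gold = c("lt_tau", "ge_tau"),
                              observed = c("lt_tau", "ge_tau")))
  m
}

#' Joint distribution of (gold, observed) raw scores
#'
#' Rows of `conditionals` are the smoothed per-gold-score conditionals over
#' observed scores; the gold prior is uniform over the 11 scores, so the
#' joint is simply each row divided by 11.
#'
#' @param conditionals 11 x 11 matrix, each row a probability vector.
#' @return 11 x 11 joint probability matrix summing to 1.
#' @export
joint_raw <- function(conditionals) {
  stopifnot(is.matrix(conditionals), nrow(conditionals) == 11L,
            ncol(conditionals) == 11L)
  if (any(abs(rowSums(conditionals) - 1) > 1e-8))
    stop("each conditional row must sum to 1", call. = FALSE)
  conditionals / 11
}

#' Joint distribution of (gold class, observed class) dichotomized scores
#'
#' The binary prior follows from the uniform prior over the 11 scores:
#' with tau = 7, seven scores fall below threshold and four at or above,
#' giving (7/11, 4/11).
#'
#' @param conditionals 2 x 2 matrix, rows = smoothed class conditionals.
#' @param prior Length-2 prior over the gold classes.
#' @return 2 x 2 joint probability matrix summing to 1.
#' @export
joint_binary <- function(conditionals, prior = c(7, 4) / 11) {
  stopifnot(is.matrix(conditionals), all(dim(conditionals) == 2L),
            length(prior) == 2L, abs(sum(prior) - 1) < 1e-8)
  if (any(abs(rowSums(conditionals) - 1) > 1e-8))
    stop("each conditional row must sum to 1", call. = FALSE)
  conditionals * prior
}

#' Mutual information of a discrete joint distribution
#'
#' `sum p(x, y) log(p(x, y) / (p(x) p(y)))` in nats, with `0 log 0 = 0`.
#'
#' @param joint Non-negative matrix summing to 1.
#' @return Non-negative scalar MI in nats (0 iff the joint factorizes).
#' @export
discrete_mi <- function(joint) {
  stopifnot(is.matrix(joint), all(joint >= -1e-12))
  if (abs(sum(joint) - 1) > 1e-8)
    stop("joint distribution must sum to 1", call. = FALSE)
  pr <- rowSums(joint)
  pc <- colSums(joint)
  keep <- joint > 0
  ref <- outer(pr, pc)
  max(0, sum(joint[keep] * log(joint[keep] / ref[keep])))
}

smoothed_joint_raw <- function(tables, alpha) {
  theta <- t(apply(tables$counts, 1, map_conditional, alpha = alpha))
  joint_raw(theta)
}

smoothed_joint_binary <- function(tables, xi, tau = 7L) {
  cc <- dichotomize_counts(tables, tau)
  phi <- rbind(map_binary(cc[1, ], xi), map_binary(cc[2, ], xi))
  joint_binary(phi, prior = c(tau, 11 - tau) / 11)
}

#' Mutual-information curves for raw and dichotomized representations
#'
#' For each prior concentration alpha on the grid, computes the MI between
#' gold-standard and observed scores under the raw 11-point representation
#' and under the dichotomized representation with matched total prior mass
#' (xi = 11 * alpha / 2).
#'
#' @param tables A completed `count_table_set`.
#' @param alpha_grid Increasing positive concentrations.
#' @param tau Dichotomization threshold (default 7, the responder cut-off).
#' @return Data frame (class `mi_curve`) with columns `alpha`, `xi`,
#'   `mi_raw`, `mi_binary`, and attribute `crossover_alpha`.
#' @export
mi_curves <- function(tables, alpha_grid = seq(0.5, 100, length.out = 200),
                      tau = 7L) {
  stopifnot(!is.unsorted(alpha_grid), all(alpha_grid >= 0))
  if (!is_complete_tables(tables))
    stop("count tables must be imputed first (see impute_missing_counts)",
         call. = FALSE)
  mi_r <- mi_b <- numeric(length(alpha_grid))
  for (i in seq_along(alpha_grid)) {
    a <- alpha_grid[i]
    res <- tryCatch({
      c(discrete_mi(smoothed_joint_raw(tables, a)),
        discrete_mi(smoothed_joint_binary(tables, 11 * a / 2, tau)))
    }, error = function(e)
      stop("at alpha = ", a, ": ", conditionMessage(e), call. = FALSE))
    mi_r[i] <- res[1]
    mi_b[i] <- res[2]
  }
  out <- data.frame(alpha = alpha_grid, xi = 11 * alpha_grid / 2,
                    mi_raw = mi_r, mi_binary = mi_b)
  attr(out, "crossover_alpha") <- crossover_alpha(tables, tau = tau,
    alpha_min = max(min(alpha_grid), 1e-6), alpha_max = max(alpha_grid))
  class(out) <- c("mi_curve", "data.frame")
  out
}

#' First concentration at which the dichotomized MI overtakes the raw MI
#'
#' Scans alpha on a dense log-spaced grid for the first sign change of
#' `mi_binary(alpha) - mi_raw(alpha)` from <= 0 to > 0 and refines it by
#' root bisection.  Absence of a crossover on the bracket is a valid
#' result, reported as `NA`.
#'
#' @param tables A completed `count_table_set`.
#' @param tau Dichotomization threshold.
#' @param alpha_min,alpha_max Search bracket (default 0.5 to 100).
#' @param tol Absolute refinement tolerance on alpha.
#' @return The crossover concentration, or `NA_real_` if none.
#' @export
crossover_alpha <- function(tables, tau = 7L, alpha_min = 0.5,
                            alpha_max = 100, tol = 1e-3) {
  if (!is_complete_tables(tables))
    stop("count tables must be imputed first (see impute_missing_counts)",
         call. = FALSE)
  f <- function(a)
    discrete_mi(smoothed_joint_binary(tables, 11 * a / 2, tau)) -
      discrete_mi(smoothed_joint_raw(tables, a))
  grid <- exp(seq(log(alpha_min), log(alpha_max), length.out = 400L))
  v <- vapply(grid, f, numeric(1))
  i <- which(v[-length(v)] <= 0 & v[-1] > 0)
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = tol)$root
}

#' @export
print.mi_curve <- function(x, ...) {
  co <- attr(x, "crossover_alpha")
  cat("MI curves over", nrow(x), "concentrations, alpha in [",
      min(x$alpha), ",", max(x$alpha), "]\n")
  if (is.na(co)) cat("  no raw/dichotomized crossover on the grid\n")
  else cat(sprintf("  dichotomized MI overtakes raw MI at alpha ~ %.3f\n", co))
  invisible(x)
}
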