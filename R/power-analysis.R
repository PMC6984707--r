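#' Analytic power of continuous and dichotomized tests of association
#'
#' For continuous data, the power of the two-tailed test that the Pearson
#' correlation differs from zero follows from Fisher's variance-stabilizing
#' Z-transform: power = Phi(sqrt(n - 3) |zeta(rho)| - z_{1 - alpha/2}).
#' For dichotomized data, association is tested with Fisher's exact test;
#' its power is computed exactly from Fisher's noncentral hypergeometric
#' distribution -- the distribution of one cell of a 2 x 2 table with both
#' margins fixed and odds-ratio parameter eta -- using the plug-in odds
#' ratio estimated from the observed table as the alternative.
#'
#' @name power-analysis
NULL

#' Fisher Z-transform of a correlation coefficient
#'
#' `zeta(rho) = 0.5 * log((1 + rho) / (1 - rho))`; odd and strictly
#' increasing on (-1, 1).
#'
#' @param rho Correlation(s) with `|rho| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1))
    stop("domain error: |rho| must be < 1", call. = FALSE)
  0.5 * log((1 + rho) / (1 - rho))
}

#' Power of the two-tailed Pearson correlation test
#'
#' @param rho_hat Estimated (plug-in) correlation, `|rho_hat| < 1`.
#' @param n Sample size (>= 4).
#' @param alpha_level Two-tailed significance level (default 0.05).
#' @param sample_size_scaled If `TRUE` (default) use the standard Fisher-Z
#'   power with the sqrt(n - 3) factor; if `FALSE`, drop the factor, making
#'   power independent of n (kept for auditability against formulations
#'   that omit it).
#' @return A `power_result`: list with `method = "pearson"`, `estimate`
#'   (rho_hat), `power`, `alpha_level`.
#' @export
pearson_power <- function(rho_hat, n, alpha_level = 0.05,
                          sample_size_scaled = TRUE) {
  stopifnot(n >= 4, alpha_level > 0, alpha_level < 1)
  z <- abs(fisher_z(rho_hat))
  scale <- if (sample_size_scaled) sqrt(n - 3) else 1
  structure(list(method = "pearson", tau = NA_real_, estimate = rho_hat,
                 power = stats::pnorm(scale * z - stats::qnorm(1 - alpha_level / 2)),
                 alpha_level = alpha_level),
            class = "power_result")
}

#' Sample odds ratio of a 2 x 2 table
#'
#' `(a d) / (b c)`; when any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe correction), so the result is always finite and
#' positive.
#'
#' @param table 2 x 2 non-negative matrix `rbind(c(a, b), c(c, d))`.
#' @return Positive scalar odds ratio.
#' @export
odds_ratio <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  t2 <- if (any(table == 0)) table + 0.5 else table
  (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
}

#' Fisher's noncentral hypergeometric distribution
#'
#' Distribution of the count T in one cell of a 2 x 2 table with fixed
#' margins and odds ratio `eta`: P(T = t) is proportional to
#' `choose(m1, t) * choose(total - m1, n1 - t) * eta^t` over the support
#' `max(0, n1 + m1 - total) <= t <= min(n1, m1)`.  `eta = 1` recovers the
#' central hypergeometric of Fisher's exact test.  Computed in log space
#' for numerical stability.
#'
#' @param m1 First margin (e.g. number of ground-truth values below the
#'   threshold).
#' @param n1 Second margin (e.g. number of observed values below the
#'   threshold).
#' @param total Table total N.
#' @param eta Positive odds-ratio parameter.
#' @return List with `support` (integer vector) and `pmf` (probabilities
#'   summing to 1).
#' @export
fnch_pmf <- function(m1, n1, total, eta = 1) {
  stopifnot(m1 >= 0, n1 >= 0, total >= 1, m1 <= total, n1 <= total, eta > 0)
  lo <- max(0L, as.integer(n1 + m1 - total))
  hi <- min(as.integer(n1), as.integer(m1))
  t <- lo:hi
  lw <- lchoose(m1, t) + lchoose(total - m1, n1 - t) + t * log(eta)
  w <- exp(lw - max(lw))
  list(support = t, pmf = w / sum(w))
}

#' Survival function of Fisher's noncentral hypergeometric distribution
#'
#' `P(T >= t)` under the distribution of [fnch_pmf()].
#'
#' @param t Quantile(s).
#' @inheritParams fnch_pmf
#' @return `P(T >= t)` for each element of `t`.
#' @export
fnch_survival <- function(t, m1, n1, total, eta = 1) {
  d <- fnch_pmf(m1, n1, total, eta)
  vapply(t, function(ti) sum(d$pmf[d$support >= ti]), numeric(1))
}

#' Exact power of the two-tailed Fisher exact test at a plug-in odds ratio
#'
#' The null cell-count distribution is central hypergeometric with the
#' observed margins; the alternative is Fisher's noncentral hypergeometric
#' with the same margins and the plug-in odds ratio from [odds_ratio()].
#' The rejection region is the tail in the direction of the estimated
#' effect at level alpha/2, with the conservative discrete convention (the
#' critical value is the first support point whose null tail probability
#' drops to or below alpha/2), so the size at eta = 1 never exceeds the
#' nominal level.
#'
#' @param table 2 x 2 contingency table `rbind(c(a, b), c(c, d))`, rows =
#'   ground-truth class, columns = observed class (below / at-or-above the
#'   threshold).
#' @param alpha_level Two-tailed significance level.
#' @return A `power_result` with `method = "fisher-exact"` and `estimate`
#'   = the plug-in odds ratio.
#' @export
fisher_exact_power <- function(table, alpha_level = 0.05) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0),
            sum(table) > 0)
  m1 <- sum(table[1, ])  # ground-truth margin, below threshold
  n1 <- sum(table[, 1])  # observed margin, below threshold
  N <- sum(table)
  if (m1 == 0 || n1 == 0 || m1 == N || n1 == N)
    stop("undefined test: a table margin is zero", call. = FALSE)
  eta_hat <- odds_ratio(table)
  null_d <- fnch_pmf(m1, n1, N, 1)
  alt_d <- fnch_pmf(m1, n1, N, eta_hat)
  surv_null <- rev(cumsum(rev(null_d$pmf)))   # P0(T >= t)
  cdf_null <- cumsum(null_d$pmf)              # P0(T <= t)
  if (eta_hat >= 1) {
    i <- which(surv_null <= alpha_level / 2)[1]
    pw <- if (is.na(i)) 0 else sum(alt_d$pmf[alt_d$support >= null_d$support[i]])
  } else {
    i <- which(cdf_null <= alpha_level / 2)
    pw <- if (length(i) == 0) 0 else {
      i <- i[length(i)]
      sum(alt_d$pmf[alt_d$support <= null_d$support[i]])
    }
  }
  structure(list(method = "fisher-exact", tau = NA_real_, estimate = eta_hat,
                 power = pw, alpha_level = alpha_level),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  eff <- if (x$method == "pearson") sprintf("rho_hat = %.4f", x$estimate)
         else sprintf("odds ratio = %.4f", x$estimate)
  cat(sprintf("%s test: power %.4f at alpha = %g (%s)\n",
              x$method, x$power, x$alpha_level, eff))
  invisible(x)
}

#' Dichotomize a continuous dataset into a 2 x 2 contingency table
#'
#' @param dataset A `synthetic_dataset` (or data frame / matrix with
#'   columns `x`, `y`).
#' @param tau Threshold strictly inside (0, 10).
#' @return 2 x 2 integer matrix, rows = x-class, columns = y-class, in the
#'   order (below threshold, at-or-above threshold).
#' @export
dichotomize_dataset <- function(dataset, tau) {
  stopifnot(length(tau) == 1L, tau > 0, tau < 10)
  d <- as_xy_matrix(dataset)
  m <- table(factor(d[, 1] < tau, c(TRUE, FALSE)),
             factor(d[, 2] < tau, c(TRUE, FALSE)))
  m <- unclass(m)
  dimnames(m) <- list(x = c("lt_tau", "ge_tau"), y = c("lt_tau", "ge_tau"))
  storage.mode(m) <- "integer"
  m
}

#' Power experiment over the synthetic-reliability grid
#'
#' For every (beta, omega, sigma) cell and each of `runs` independent
#' datasets, computes the Pearson-correlation power at the sample
#' correlation and the exact Fisher power at each dichotomization
#' threshold, then summarizes per cell by mean and 95% confidence
#' half-width.
#'
#' @param betas,omegas,sigmas Grid of generator settings.
#' @param taus Dichotomization thresholds for the Fisher tests (default
#'   the tail split 3 and the median split 5).
#' @param runs Independent datasets per cell (default 100).
#' @param n Samples per dataset (default 750).
#' @param alpha_level Significance level for both tests.
#' @param seed Optional master seed (reproduces every dataset).
#' @return A `power_sweep`: list with `runs` (long data frame: beta, omega,
#'   sigma, method, tau, run, power) and `summary` (means with `ci_low`,
#'   `ci_high`).
#' @export
power_experiment <- function(betas = c(0, 1), omegas = c(0.3, 0.5, 0.7),
                             sigmas = 1:20, taus = c(3, 5), runs = 100L,
                             n = 750L, alpha_level = 0.05, seed = NULL) {
  stopifnot(runs >= 2L)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (beta in betas) for (omega in omegas) for (sig in sigmas) {
    for (r in seq_len(runs)) {
      d <- sample_dataset(beta, omega, sig, n = n)
      pw_p <- pearson_power(stats::cor(d$x, d$y), n,
                            alpha_level = alpha_level)$power
      pw_f <- vapply(taus, function(t) {
        tab <- dichotomize_dataset(d, t)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
        else fisher_exact_power(tab, alpha_level = alpha_level)$power
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        beta = beta, omega = omega, sigma = sig,
        method = c("pearson", rep("fisher", length(taus))),
        tau = c(NA_real_, taus), run = r, power = c(pw_p, pw_f))
    }
  }
  long <- do.call(rbind, rows)
  key <- interaction(long$beta, long$omega, long$sigma, long$method,
                     ifelse(is.na(long$tau), -1, long$tau), drop = TRUE)
  summ <- do.call(rbind, lapply(split(long, key), function(g) {
    mu <- mean(g$power, na.rm = TRUE)
    hw <- 1.96 * stats::sd(g$power, na.rm = TRUE) / sqrt(sum(!is.na(g$power)))
    data.frame(beta = g$beta[1], omega = g$omega[1], sigma = g$sigma[1],
               method = g$method[1], tau = g$tau[1], mean_power = mu,
               ci_low = max(0, mu - hw), ci_high = min(1, mu + hw),
               n_runs = sum(!is.na(g$power)))
  }))
  summ <- summ[order(summ$beta, summ$omega, summ$sigma, summ$method, summ$tau), ]
  rownames(summ) <- NULL
  structure(list(runs = long, summary = summ,
                 params = list(betas = betas, omegas = omegas, sigmas = sigmas,
                               taus = taus, runs = runs, n = n,
                               alpha_level = alpha_level, seed = seed)),
            class = "power_sweep")
}

#' @export
print.power_sweep <- function(x, ...) {
  p <- x$params
  cat("Power experiment:", length(p$betas), "x", length(p$omegas), "x",
      length(p$sigmas), "grid,", p$runs, "runs of n =", p$n, "\n")
  print(utils::head(x$summary, 12), row.names = FALSE)
  if (nrow(x$summary) > 12) cat("  ...", nrow(x$summary), "summary cells\n")
  invisible(x)
}
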