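# Shared fixture builders.  Everything is generated in code at test time.

study_gold <- c(8L, 9L, 6L, 7L, 9L, 3L, 5L, 9L, 3L, 9L, 5L, 1L)

# wrap a raw 11x11 count matrix as a complete count_table_set
make_tables <- function(counts, observed = rep(TRUE, 11),
                        imputed = rep(FALSE, 11)) {
  structure(list(counts = counts, observed = observed, imputed = imputed,
                 n_ratings = sum(counts)),
            class = "count_table_set")
}

# random complete count tables with EQUAL per-gold-score totals (each row a
# multinomial draw), so the dichotomized table is an exact coarsening of
# the raw joint at alpha = xi = 1
random_equal_row_tables <- function(row_total = 59L) {
  counts <- t(vapply(1:11, function(k) {
    p <- stats::rgamma(11, shape = 0.8)
    as.numeric(stats::rmultinom(1, row_total, p / sum(p)))
  }, numeric(11)))
  make_tables(counts)
}

# independent dense-grid scan for the MI crossover (oracle for the
# bisection-based crossover_alpha)
scan_crossover <- function(tables, tau = 7L, alpha_min = 0.5,
                           alpha_max = 100, n_grid = 3000L) {
  mi_raw_at <- function(a) {
    theta <- t(apply(tables$counts, 1, map_conditional, alpha = a))
    discrete_mi(joint_raw(theta))
  }
  mi_bin_at <- function(a) {
    cc <- dichotomize_counts(tables, tau)
    xi <- 11 * a / 2
    phi <- rbind(map_binary(cc[1, ], xi), map_binary(cc[2, ], xi))
    discrete_mi(joint_binary(phi, prior = c(tau, 11 - tau) / 11))
  }
  grid <- exp(seq(log(alpha_min), log(alpha_max), length.out = n_grid))
  dif <- vapply(grid, function(a) mi_bin_at(a) - mi_raw_at(a), numeric(1))
  i <- which(dif[-length(dif)] <= 0 & dif[-1] > 0)
  if (length(i) == 0) NA_real_ else grid[i[1] + 1L]
}

# direct-summation oracle for the noncentral hypergeometric pmf/survival,
# written independently of the package's log-space implementation
oracle_fnch_survival <- function(m1, n1, total, eta) {
  lo <- max(0, n1 + m1 - total); hi <- min(n1, m1)
  t <- lo:hi
  w <- choose(m1, t) * choose(total - m1, n1 - t) * eta^t
  p <- w / sum(w)
  rev(cumsum(rev(p)))  # P(T >= t) over the support
}

# draw a bivariate normal sample with correlation r
rbvn <- function(n, r) {
  z <- matrix(stats::rnorm(2 * n), n, 2)
  z[, 2] <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
  data.frame(x = z[, 1], y = z[, 2])
}
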