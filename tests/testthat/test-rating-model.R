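test_that("rating CSVs round-trip and are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  fx <- generate_rating_fixture(seed = 7L)
  write_ratings(fx, path)
  back <- read_ratings(path)
  expect_identical(unname(back$scores), unname(fx$scores))
  expect_identical(back$n_raters, 59L)
  expect_identical(back$gold, study_gold)
  expect_identical(back$dropped_cells, 0L)

  # 2-rater toy file without a site column
  toy <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(paste0("V", 1:12), collapse = ","),
               paste(rep(5, 12), collapse = ","),
               paste(c(9, rep(4, 10), ""), collapse = ",")), toy)
  r <- read_ratings(toy)
  expect_identical(r$n_raters, 2L)
  expect_identical(r$dropped_cells, 1L)

  # score out of the 0..10 range is a parse error naming the location
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(paste0("V", 1:12), collapse = ","),
               paste(c(11, rep(4, 11)), collapse = ",")), bad)
  expect_error(read_ratings(bad), "out of range.*V1")

  # wrong vignette count is a schema error
  narrow <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("V1,V2", "5,5"), narrow)
  expect_error(read_ratings(narrow), "schema error")
})

test_that("count tables tally ratings by gold score and conserve totals", {
  m <- matrix(9L, nrow = 2, ncol = 2)
  toy <- structure(list(scores = m, site = NULL, gold = c(9L, 9L),
                        n_raters = 2L, vignette_ids = c("a", "b"),
                        dropped_cells = 0L), class = "rating_matrix")
  tabs <- build_count_tables(toy)
  expect_equal(tabs$counts[10, 10], 4)          # all four ratings were 9
  expect_equal(sum(tabs$counts), 4)

  one <- structure(list(scores = matrix(7L, 1, 1), site = NULL, gold = 5L,
                        n_raters = 1L, vignette_ids = "a",
                        dropped_cells = 0L), class = "rating_matrix")
  t1 <- build_count_tables(one)
  expect_equal(t1$counts[6, 8], 1)              # gold 5, observed 7
  expect_equal(sum(t1$counts), 1)

  fx <- generate_rating_fixture(seed = 3L)
  full <- build_count_tables(fx)
  expect_equal(sum(full$counts), 59 * 12)       # conservation
  expect_identical(which(full$observed) - 1L, sort(unique(study_gold)))
})

test_that("unobserved gold scores are imputed from neighbours", {
  fx <- generate_rating_fixture(seed = 5L)
  tabs <- build_count_tables(fx)
  imp <- impute_missing_counts(tabs)
  expect_identical(which(imp$imputed) - 1L, c(0L, 2L, 4L, 10L))
  expect_equal(imp$counts[1, ], imp$counts[2, ])    # n(0) <- n(1)
  expect_equal(imp$counts[11, ], imp$counts[10, ])  # n(10) <- n(9)
  expect_equal(imp$counts[3, ], (imp$counts[2, ] + imp$counts[4, ]) / 2)
  expect_equal(imp$counts[5, ], (imp$counts[4, ] + imp$counts[6, ]) / 2)

  # element-wise mean example
  cnt <- matrix(0, 11, 11)
  cnt[2, 1] <- 2                      # n(1) = (2, 0, ...)
  cnt[4, 2] <- 2                      # n(3) = (0, 2, ...)
  obs <- rep(TRUE, 11); obs[3] <- FALSE
  mid <- impute_missing_counts(make_tables(cnt, observed = obs))
  expect_equal(mid$counts[3, 1:2], c(1, 1))

  # a gap with an unobserved upper neighbour is rejected
  obs2 <- rep(FALSE, 11); obs2[6] <- TRUE   # only k = 5 observed
  cnt2 <- matrix(0, 11, 11); cnt2[6, 6] <- 10
  expect_error(impute_missing_counts(make_tables(cnt2, observed = obs2)),
               "unsupported missingness")
})

test_that("MAP smoothing matches closed-form arithmetic", {
  n <- c(3, 0, 2)
  expect_equal(map_conditional(n, 1), n / sum(n))       # alpha = 1: empirical
  expect_equal(map_conditional(rep(0, 11), 2), rep(1 / 11, 11))
  expect_equal(map_conditional(c(rep(0, 9), 3, 1), 2),
               c(rep(1 / 15, 9), 4 / 15, 2 / 15))
  # clamping: alpha = 0 with a bare single count leaves no mass anywhere
  expect_error(map_conditional(c(rep(0, 10), 1), 0), "degenerate")
  # alpha = 0.5 clamps empty cells at zero instead of going negative
  th <- map_conditional(c(0, 4, 0), 0.5)
  expect_equal(th, c(0, 1, 0))
  expect_equal(map_binary(c(5, 5), 3.7), c(0.5, 0.5))
  expect_equal(map_binary(c(3, 1), 1), c(3 / 4, 1 / 4))
  expect_equal(map_binary(c(3, 1), 2), c(4 / 6, 2 / 6))
})

test_that("dichotomized counts aggregate the four threshold blocks", {
  cnt <- matrix(0, 11, 11)
  cnt[6, 7] <- 10   # gold 5, observed 6  -> both below tau = 7
  cnt[6, 9] <- 2    # gold 5, observed 8  -> observed above
  tabs <- make_tables(cnt)
  cc <- dichotomize_counts(tabs, 7)
  expect_equal(cc, matrix(c(10, 2, 0, 0), 2, byrow = TRUE), ignore_attr = TRUE)
  # conservation for an arbitrary table
  set.seed(42)
  rt <- random_equal_row_tables()
  for (tau in c(3, 5, 7))
    expect_equal(sum(dichotomize_counts(rt, tau)), sum(rt$counts))
  # unimputed tables are refused
  incomplete <- make_tables(cnt, observed = c(rep(TRUE, 10), FALSE))
  expect_error(dichotomize_counts(incomplete, 7), "imputed")
})

test_that("joint distributions carry the correct priors", {
  ident <- diag(11)
  expect_equal(joint_raw(ident), diag(11) / 11)
  unif <- matrix(1 / 11, 11, 11)
  expect_equal(joint_raw(unif), matrix(1 / 121, 11, 11))
  perfect <- diag(2)
  jb <- joint_binary(perfect)
  expect_equal(jb, diag(c(7, 4) / 11))
  flat <- matrix(0.5, 2, 2)
  expect_equal(discrete_mi(joint_binary(flat)), 0)
  expect_error(joint_raw(ident * 2), "sum to 1")
})

test_that("discrete MI matches entropy and direct-summation oracles", {
  # independence
  p <- outer(c(0.2, 0.3, 0.5), c(0.6, 0.4))
  expect_equal(discrete_mi(p), 0, tolerance = 1e-12)
  # diagonal binary joint: MI equals the marginal entropy H(4/11)
  d <- diag(c(4, 7) / 11)
  expect_equal(discrete_mi(d), -sum(c(4, 7) / 11 * log(c(4, 7) / 11)),
               tolerance = 1e-12)
  expect_equal(discrete_mi(d), 0.6554818, tolerance = 1e-6)
  # direct-summation value
  expect_equal(discrete_mi(matrix(c(0.4, 0.1, 0.1, 0.4), 2)),
               0.1927448, tolerance = 1e-6)
  expect_error(discrete_mi(matrix(0.3, 2, 2)), "sum to 1")
})

test_that("coarsening cannot increase MI when smoothing is equalized", {
  # with alpha = xi = 1 and equal row totals the 2x2 joint is exactly the
  # block aggregation of the 11x11 joint, so the data-processing
  # inequality applies
  set.seed(99)
  for (i in 1:25) {
    rt <- random_equal_row_tables()
    theta <- t(apply(rt$counts, 1, map_conditional, alpha = 1))
    mi_raw <- discrete_mi(joint_raw(theta))
    cc <- dichotomize_counts(rt, 7)
    phi <- rbind(map_binary(cc[1, ], 1), map_binary(cc[2, ], 1))
    mi_bin <- discrete_mi(joint_binary(phi))
    expect_lte(mi_bin, mi_raw + 1e-12)
  }
})

test_that("MI curves decay with prior noise and locate the crossover", {
  fx <- generate_rating_fixture(seed = 11L)
  tabs <- impute_missing_counts(build_count_tables(fx))
  curve <- mi_curves(tabs, alpha_grid = c(1, 5, 20, 1e6))
  expect_true(all(curve$mi_raw >= 0) && all(curve$mi_binary >= 0))
  expect_equal(curve$xi, 11 * curve$alpha / 2)
  expect_lt(curve$mi_raw[4], 1e-6)      # smoothing washes out the signal
  expect_lt(curve$mi_binary[4], 1e-6)
  expect_true(all(diff(curve$mi_raw) < 0))

  co <- crossover_alpha(tabs)
  expect_true(is.finite(co) && co > 0.5 && co < 100)
  # bisection agrees with an independent dense-grid scan
  expect_equal(co, scan_crossover(tabs), tolerance = 0.02)
  # the curve really changes sign there
  dif <- function(a)
    discrete_mi(joint_binary(rbind(
      map_binary(dichotomize_counts(tabs, 7)[1, ], 11 * a / 2),
      map_binary(dichotomize_counts(tabs, 7)[2, ], 11 * a / 2)))) -
    discrete_mi(joint_raw(t(apply(tabs$counts, 1, map_conditional, alpha = a))))
  expect_lt(dif(co - 0.05), 0)
  expect_gt(dif(co + 0.05), 0)
})

test_that("asymmetric dispersion accelerates the crossover (seed-mean)", {
  co_asym <- co_sym <- numeric(10)
  for (s in 1:10) {
    asym <- impute_missing_counts(build_count_tables(
      generate_rating_fixture(seed = 200 + s)))          # sd 2.0 / 0.8
    sym <- impute_missing_counts(build_count_tables(
      generate_rating_fixture(sd_low = 2, sd_high = 2, seed = 300 + s)))
    co_asym[s] <- crossover_alpha(asym)
    co_sym[s] <- crossover_alpha(sym)
  }
  expect_true(all(is.finite(co_asym)))
  expect_lt(mean(co_asym), mean(co_sym))
})
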