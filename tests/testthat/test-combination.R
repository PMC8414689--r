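test_that("grid policy follows prevalence and discreteness", {
  expect_equal(choose_grid(200, discrete = FALSE)$taus,
               c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_equal(choose_grid(200, discrete = TRUE)$taus, c(0.25, 0.5, 0.75))
  expect_equal(choose_grid(25, discrete = FALSE)$taus, c(0.25, 0.5, 0.75))
  low <- choose_grid(10, discrete = FALSE)
  expect_true(low$low_prevalence)
  expect_length(low$taus, 0)
  ug <- choose_grid(50, FALSE, user_grid = c(0.2, 0.4, 0.6))
  expect_equal(ug$origin, "user")
  expect_equal(ug$taus, c(0.2, 0.4, 0.6))
  expect_error(choose_grid(4, FALSE, user_grid = seq(0.1, 0.9, 0.2)),
               "less than the number of non-zero")
})

test_that("Cauchy weights follow the central-quantile formula and sum to 1", {
  w <- cauchy_weights(c(0.1, 0.25, 0.5, 0.75, 0.9), r_hat = 0.3)
  expect_equal(w$w, 0.7 * c(0.1, 0.25, 0.5, 0.25, 0.1) / 1.2,
               tolerance = 1e-12)
  expect_equal(w$w[3], 0.7 * 0.5 / 1.2, tolerance = 1e-10)
  set.seed(47)
  for (rep in 1:20) {
    taus <- sort(sample(seq(0.05, 0.95, by = 0.05), sample(1:8, 1)))
    r <- runif(1)
    ww <- cauchy_weights(taus, r)
    expect_equal(r + sum(ww$w), 1, tolerance = 1e-12)
  }
  expect_equal(sum(cauchy_weights(c(0.25, 0.5), 0)$w), 1)
})

test_that("Cauchy combination matches hand-computed cases", {
  # all p = 0.5: T = 0, combined p = 0.5
  expect_equal(combine_cauchy(0.5, c(0.5, 0.5),
                              list(r_hat = 0.4, w = c(0.3, 0.3))), 0.5)
  # a single component with weight 1 is the identity
  expect_equal(combine_cauchy(NA, 0.037, list(r_hat = 0, w = 1)), 0.037,
               tolerance = 1e-12)
  # worked example: p_L = 0.01 with r = 0.5, one quantile p = 0.5, w = 0.5
  got <- combine_cauchy(0.01, 0.5, list(r_hat = 0.5, w = 0.5))
  expect_equal(got, 0.5 - atan(0.5 * tan(0.49 * pi)) / pi, tolerance = 1e-12)
  expect_equal(got, 0.02, tolerance = 2e-3)
  # NA components are dropped and weights renormalized
  expect_equal(combine_cauchy(0.2, c(NA, NA),
                              list(r_hat = 0.5, w = c(0.25, 0.25))), 0.2,
               tolerance = 1e-12)
  expect_true(is.na(combine_cauchy(NA, NA, list(r_hat = 0.5, w = 0.5))))
  # extreme p-values do not overflow
  expect_gt(combine_cauchy(1e-20, 0.5, list(r_hat = 0.5, w = 0.5)), 0)
})

test_that("MinP reduces to closed forms in the boundary cases", {
  # no quantile part: combined p is the logistic p
  expect_equal(combine_minp(0.031, numeric(), NULL)$p, 0.031)
  # one quantile test + logistic, independent: 1 - (1-T)^2
  res <- structure(list(quadratic_norm = 10, degenerate = FALSE),
                   class = "residualized_covariate")
  sg <- score_covariance(0.5, res, 100)
  mp <- combine_minp(0.05, 0.2, sg, B = 100000, seed = 1)
  expect_equal(mp$t_minp, 0.05)
  expect_lt(abs(mp$p - (1 - 0.95^2)), 4 * mp$mc_se + 1e-3)
})

test_that("MinP obeys the sandwich bounds on simulated taxa", {
  set.seed(53)
  for (rep in 1:25) {
    shift <- sample(c(0, 0.6), 1)
    n <- 120
    C <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, 0.7) * rlnorm(n, meanlog = shift * C)
    res <- zinq_test(y, zinq_design(C), minp_draws = 2000, seed = rep)
    if (is.na(res$p_minp)) next
    K <- length(res$taus) + is.finite(res$p_logistic)
    expect_gte(res$p_minp, res$t_minp - 1e-12)
    expect_lte(res$p_minp, min(1, K * res$t_minp) + 3 * res$minp_mc_se + 1e-12)
  }
})

test_that("rejections are monotone across significance levels", {
  set.seed(59)
  for (rep in 1:10) {
    dat <- null_taxon(n = 150, seed = 600 + rep)
    res <- zinq_test(dat$y, dat$design, minp_draws = 1000, seed = rep)
    for (p in c(res$p_cauchy, res$p_minp)) {
      if (is.na(p)) next
      expect_true(!(p < 0.01) || (p < 0.05))
    }
  }
})

test_that("per-taxon degeneracies propagate to combined p-values", {
  d <- zinq_design(rbinom(50, 1, 0.5))
  r0 <- zinq_test(rep(0, 50), d)
  expect_true(is.na(r0$p_cauchy) && is.na(r0$p_minp))
  expect_equal(r0$flags, "all_zero")

  # zero-free taxon: logistic dropped, r_hat = 0, combination runs on
  # the quantile part alone
  set.seed(61)
  y <- rlnorm(50) + 1
  r1 <- zinq_test(y, d, seed = 2, minp_draws = 1000)
  expect_equal(r1$r_hat, 0)
  expect_true(is.na(r1$p_logistic))
  expect_false(is.na(r1$p_cauchy))
  expect_false(is.na(r1$p_minp))
})

test_that("table runs preserve order and are seed-deterministic", {
  set.seed(67)
  n <- 100
  C <- rbinom(n, 1, 0.5)
  d <- zinq_design(C)
  counts <- cbind(t1 = rbinom(n, 1, .8) * rpois(n, 30),
                  t2 = rep(0L, n),
                  t3 = rbinom(n, 1, .6) * rpois(n, 10))
  tb <- taxon_table(counts, sample_ids = paste0("s", 1:n))
  res <- zinq_table(tb, d, seed = 9, minp_draws = 1000)
  expect_equal(vapply(res, `[[`, "", "taxon_id"), c("t1", "t2", "t3"))
  expect_true("all_zero" %in% res[[2]]$flags)
  res2 <- zinq_table(tb, d, seed = 9, minp_draws = 1000)
  expect_identical(extract_p <- vapply(res, `[[`, 0, "p_cauchy"),
                   vapply(res2, `[[`, 0, "p_cauchy"))
  expect_identical(vapply(res, `[[`, 0, "p_minp"),
                   vapply(res2, `[[`, 0, "p_minp"))
})
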