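test_that("perturbation breaks ties within [y, y+1) and is reproducible", {
  y <- c(0, 2, 2, 5)
  p1 <- perturb_counts(y, discrete = TRUE, seed = 3)
  expect_true(all(p1$w >= y & p1$w < y + 1))
  expect_equal(anyDuplicated(p1$w), 0)
  expect_identical(p1$w, perturb_counts(y, discrete = TRUE, seed = 3)$w)
  expect_equal(p1$nonzero_mask, y > 0)
  # continuous input is a no-op
  yc <- c(0, 1.5, 2.7)
  expect_identical(perturb_counts(yc, discrete = FALSE)$w, yc)
})

test_that("logistic score test matches the 2x2 chi-square oracle", {
  # presence table (20,10; 10,20) for C=1 / C=0
  C <- c(rep(1, 30), rep(0, 30))
  mask <- c(rep(TRUE, 20), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 20))
  res <- logistic_presence_test(mask, zinq_design(C), method = "score")
  oracle <- unname(chisq.test(table(C, mask), correct = FALSE)$statistic)
  expect_equal(res$statistic, oracle, tolerance = 1e-10)
  expect_equal(res$statistic, 60 * (20 * 20 - 10 * 10)^2 / 30^4,
               tolerance = 1e-10)
  expect_lt(res$p, 0.01)

  # identical presence proportions per group: zero score
  mask2 <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 20)  # 60% in both groups
  C2 <- rep(c(1, 0), each = 50)
  res2 <- logistic_presence_test(mask2, zinq_design(C2), method = "score")
  expect_equal(res2$statistic, 0, tolerance = 1e-10)
  expect_equal(res2$p, 1)

  # degenerate masks are flagged, not tested
  res3 <- logistic_presence_test(rep(TRUE, 30), zinq_design(rbinom(30, 1, .5)))
  expect_true(res3$degenerate)
  expect_true(is.na(res3$p))
})

test_that("lrt, wald and score p-values broadly agree on clean data", {
  set.seed(21)
  C <- rbinom(200, 1, 0.5)
  Z <- cbind(1, rnorm(200))
  d <- zinq_design(C, Z)
  mask <- rbinom(200, 1, plogis(0.3 + 0.8 * C)) == 1
  zs <- sapply(c("lrt", "wald", "score"), function(mm) {
    sqrt(logistic_presence_test(mask, d, method = mm)$statistic)
  })
  # the three classical tests are first-order equivalent
  expect_lt(max(zs) - min(zs), 0.15 * max(zs))
})

test_that("residualization projects out the covariates on the masked design", {
  d <- zinq_design(c(1, 0, 1, 0))
  r <- residualize(d, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$c_star, c(0, -1 / 3, 2 / 3, -1 / 3), tolerance = 1e-12)
  expect_equal(r$quadratic_norm, 2 / 3, tolerance = 1e-12)

  # orthogonality to the truncated covariates for random designs
  set.seed(23)
  for (rep in 1:5) {
    n <- 50
    d2 <- zinq_design(rnorm(n), cbind(1, rnorm(n), rbinom(n, 1, 0.5)))
    mask <- rbinom(n, 1, 0.7) == 1
    r2 <- residualize(d2, mask)
    Zt <- d2$covariates * mask
    expect_lt(max(abs(crossprod(Zt, r2$c_star))), 1e-8)
    expect_true(all(r2$c_star[!mask] == 0))
  }

  # constant variable on the non-zero subset
  d3 <- zinq_design(c(5, 1, 1, 1))
  r3 <- residualize(d3, c(FALSE, TRUE, TRUE, TRUE))
  expect_true(r3$degenerate)
  expect_equal(r3$quadratic_norm, 0, tolerance = 1e-20)
})

test_that("rank score matches the hand-computed example", {
  y <- c(0, 1, 2, 3, 4)
  d <- zinq_design(c(0, 1, 0, 1, 0))
  mask <- y > 0
  res <- residualize(d, mask)
  a <- fit_null_quantile(y, d, mask, 0.5)  # lower vertex: 2
  expect_equal(unname(a), 2)
  rs <- rank_score_test(y, d, mask, res, 0.5, alpha = a)
  expect_equal(rs$s, -0.5 / sqrt(5), tolerance = 1e-12)
  expect_equal(rs$t, -1, tolerance = 1e-12)
  expect_equal(rs$p, 2 * pnorm(-1), tolerance = 1e-12)

  # constant variable on nonzeros: score 0 / flagged
  d2 <- zinq_design(c(9, 1, 1, 1, 1))
  res2 <- residualize(d2, mask)
  rs2 <- rank_score_test(y, d2, mask, res2, 0.5)
  expect_true(rs2$degenerate)
})

test_that("with no zeros the zero-adjusted test equals the classical one", {
  set.seed(29)
  n <- 80
  d <- zinq_design(rbinom(n, 1, 0.5), cbind(1, rnorm(n)))
  y <- rlnorm(n) + 0.5  # strictly positive, continuous
  marg <- zinq_marginals(y, d, seed = 1)
  base <- standard_rank_score_baseline(y, d, seed = 1)
  expect_gt(length(marg$quantile), 0)
  for (k in seq_along(marg$quantile)) {
    expect_equal(marg$quantile[[k]]$s, base[[k]]$s, tolerance = 1e-10)
    expect_equal(marg$quantile[[k]]$t, base[[k]]$t, tolerance = 1e-10)
  }
  expect_equal(marg$r_hat, 0)
  expect_true("zero_free" %in% marg$flags)
})

test_that("score covariance follows the Brownian-bridge kernel and is PSD", {
  res <- structure(list(quadratic_norm = 10, degenerate = FALSE),
                   class = "residualized_covariate")
  sc <- score_covariance(c(0.25, 0.5), res, 10)
  expect_equal(sc$sigma, matrix(c(0.1875, 0.125, 0.125, 0.25), 2, 2))
  # implied correlation is design-free
  expect_equal(sc$sigma[1, 2] / sqrt(sc$sigma[1, 1] * sc$sigma[2, 2]),
               0.125 / sqrt(0.1875 * 0.25), tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:5) {
    taus <- sort(runif(sample(2:6, 1)))
    if (anyDuplicated(taus)) next
    res2 <- structure(list(quadratic_norm = runif(1, 1, 50),
                           degenerate = FALSE),
                      class = "residualized_covariate")
    ev <- eigen(score_covariance(taus, res2, 100)$sigma,
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("empirical covariance of null rank scores matches the formula", {
  # fixed design, random presence: average the per-replicate Sigma-hat
  set.seed(37)
  n <- 200
  C <- rep(c(0, 1), n / 2)
  d <- zinq_design(C)
  taus <- c(0.25, 0.5)
  reps <- 1200
  S <- matrix(0, reps, 2)
  Sig <- matrix(0, 2, 2)
  for (r in seq_len(reps)) {
    y <- rbinom(n, 1, 0.7) * rlnorm(n)
    marg <- zinq_marginals(y, d, grid = taus)
    S[r, ] <- vapply(marg$quantile, function(q) q$s, numeric(1))
    Sig <- Sig + marg$sigma$sigma / reps
  }
  emp <- cov(S)
  # entrywise within 3 Monte-Carlo SEs (normal-theory SE of a covariance)
  for (k in 1:2) for (l in 1:2) {
    se <- sqrt((Sig[k, k] * Sig[l, l] + Sig[k, l]^2) / reps)
    expect_lt(abs(emp[k, l] - Sig[k, l]), 3 * se)
  }
})

test_that("marginal layer flags degenerate taxa without aborting", {
  d <- zinq_design(rbinom(40, 1, 0.5))
  m0 <- zinq_marginals(rep(0, 40), d)
  expect_equal(m0$flags, "all_zero")
  expect_length(m0$quantile, 0)

  set.seed(41)
  ylow <- c(rlnorm(10), rep(0, 30))  # m = 10 < 15
  mlow <- zinq_marginals(ylow, d)
  expect_true("low_prevalence" %in% mlow$flags)
  expect_length(mlow$quantile, 0)
  expect_false(is.null(mlow$logistic))
})

test_that("the median rank-score statistic is null-calibrated", {
  set.seed(43)
  reps <- 600
  t_med <- numeric(reps)
  for (r in seq_len(reps)) {
    dat <- null_taxon(n = 150, seed = 5000 + r)
    marg <- zinq_marginals(dat$y, dat$design, grid = 0.5)
    t_med[r] <- marg$quantile[[1]]$t
  }
  ks <- suppressWarnings(ks.test(t_med, "pnorm"))
  expect_gt(ks$p.value, 0.001)
})
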