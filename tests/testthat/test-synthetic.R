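test_that("edf mixture sampling respects supports and proportions", {
  # disjoint supports so origin of each draw is identifiable
  pair <- edf_pair(values_a = c(100, 200, 300), values_b = c(1, 2, 3))
  s1 <- edf_mixture_sampler(pair, 50, mix = 1, seed = 1)
  expect_true(all(s1$y[s1$group == 1] >= 100))
  expect_true(all(s1$y[s1$group == 0] < 100))
  expect_equal(s1$group, c(rep(1, 50), rep(0, 50)))

  # mix = 0.8: expected fraction of group-1 draws from the primary edf
  s8 <- edf_mixture_sampler(pair, 10000, mix = 0.8, seed = 2)
  frac <- mean(s8$y[s8$group == 1] >= 100)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  frac0 <- mean(s8$y[s8$group == 0] < 100)
  expect_lt(abs(frac0 - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))

  # mix = 0.5 makes the two groups exchangeable
  s5 <- edf_mixture_sampler(pair, 20000, mix = 0.5, seed = 3)
  expect_lt(abs(mean(s5$y[s5$group == 1] >= 100) -
                mean(s5$y[s5$group == 0] >= 100)), 0.02)

  expect_error(edf_mixture_sampler(pair, 10, mix = 0.3), "mix")
  expect_identical(edf_mixture_sampler(pair, 30, 0.8, seed = 9)$y,
                   edf_mixture_sampler(pair, 30, 0.8, seed = 9)$y)
})

test_that("two-part generator honors presence and inverse-CDF sampling", {
  n <- 10000
  fg <- seq(0.01, 0.99, by = 0.01)
  # beta0(tau) = 10 tau: positive counts ~ round(10 U) clamped at 1
  pp <- two_part_params(gamma_z = qlogis(0.6), gamma_c = 0,
                        beta_z = matrix(10 * fg, ncol = 1),
                        beta_c = rep(0, 99))
  d <- zinq_design(rbinom(n, 1, 0.5))
  tb <- generate_twopart_table(pp, d, seed = 77)
  y <- tb$counts[, 1]
  expect_lt(abs(mean(y > 0) - 0.6), 3 * sqrt(0.6 * 0.4 / n))
  pos <- y[y > 0]
  expect_true(all(pos >= 1 & pos <= 10))
  # E[max(1, round(10U))] = 0.05*1 + 0.1*(1+...+9) + 0.05*10 = 5.05
  expect_lt(abs(mean(pos) - 5.05), 3 * sd(pos) / sqrt(length(pos)))

  # the all-absent limit: gamma pushed to -inf-ish
  pp0 <- two_part_params(gamma_z = -20, gamma_c = 0,
                         beta_z = matrix(10 * fg, ncol = 1),
                         beta_c = rep(0, 99))
  tb0 <- generate_twopart_table(pp0, zinq_design(rbinom(100, 1, .5)),
                                seed = 1)
  expect_true(all(tb0$counts == 0))
})

test_that("null constraint zeroes only the variable's coefficients", {
  params <- synthetic_benchmark_params(4, seed = 5)
  p1 <- params[[1]]
  p0 <- constrain_null(p1)
  expect_equal(p0$gamma_c, 0)
  expect_true(all(p0$beta_c == 0))
  expect_identical(p0$gamma_z, p1$gamma_z)
  expect_identical(p0$beta_z, p1$beta_z)
})

test_that("two-part fitting recovers known generating coefficients", {
  set.seed(83)
  n <- 4000
  fg <- seq(0.01, 0.99, by = 0.01)
  truth <- two_part_params(gamma_z = 0.85, gamma_c = 0.6,
                           beta_z = matrix(50 * qlnorm(fg), ncol = 1),
                           beta_c = rep(10, 99))
  C <- rbinom(n, 1, 0.5)
  d <- zinq_design(C)
  tb <- generate_twopart_table(truth, d, seed = 84)
  y <- tb$counts[, 1]
  fit <- fit_twopart(y, d, seed = 85)
  expect_equal(length(fit$fine_grid), 99)
  # logistic coefficient within 3 model-based SEs
  gl <- glm((y > 0) ~ C, family = binomial)
  expect_lt(abs(fit$gamma_c - 0.6), 3 * sqrt(vcov(gl)[2, 2]))
  # median coefficient within 3 Siddiqui-sandwich SEs
  mask <- y > 0
  m <- sum(mask)
  w <- y[mask] + runif(m)
  r <- w - as.vector(cbind(1, C[mask]) %*% c(fit$beta_z[50, 1],
                                             fit$beta_c[50]))
  sp <- unname(diff(quantile(r, c(0.45, 0.55)))) / 0.1
  XX <- crossprod(cbind(1, C[mask])) / m
  se <- sqrt(0.25 * sp^2 * solve(XX)[2, 2] / m)
  expect_lt(abs(fit$beta_c[50] - 10), 3 * se)
})

test_that("covariate resampling keeps marginals, breaks correlations", {
  set.seed(89)
  n <- 4000
  x <- rnorm(500)
  d <- zinq_design(variable = x + rnorm(500, sd = 0.2),
                   covariates = cbind(1, x))
  rs <- resample_covariates(d, n, seed = 7)
  expect_length(rs$variable, n)
  ks <- suppressWarnings(ks.test(rs$covariates[, 2], x))
  expect_gt(ks$p.value, 1e-4)
  expect_lt(abs(cor(rs$variable, rs$covariates[, 2])), 0.06)
  expect_identical(resample_covariates(d, n, seed = 7)$variable,
                   rs$variable)
})

test_that("joint permutation preserves cross-covariate structure", {
  set.seed(97)
  x <- rnorm(200)
  d <- zinq_design(variable = x + rnorm(200, sd = 0.3),
                   covariates = cbind(1, x, x^2))
  pm <- permute_covariates(d, seed = 11)
  expect_equal(cor(pm$variable, pm$covariates[, 2]),
               cor(d$variable, d$covariates[, 2]), tolerance = 1e-12)
  expect_equal(sort(pm$variable), sort(d$variable))
  expect_false(identical(pm$variable, d$variable))
})

test_that("Dirichlet-multinomial fitting recovers proportions and dispersion", {
  set.seed(101)
  J <- 5
  alpha <- c(4, 3, 1.5, 1, 0.5)
  truth <- dm_params(alpha)
  libs <- sample(800:1200, 2000, replace = TRUE)
  tb <- generate_dm_table(truth, rep(1, 2000), libs, seed = 13)
  expect_equal(unname(rowSums(tb$counts)), libs)
  fit <- fit_dm(tb)
  expect_equal(fit$alpha / sum(fit$alpha), alpha / sum(alpha),
               tolerance = 0.1)
  expect_equal(fit$total_mass, sum(alpha), tolerance = 0.25 * sum(alpha))

  # equal-abundance symmetry
  tbe <- generate_dm_table(dm_params(rep(2, 4)), rep(1, 1500),
                           rep(1000, 1500), seed = 17)
  fe <- fit_dm(tbe)
  expect_lt(max(fe$alpha) / min(fe$alpha), 1.3)

  # multinomial data: near-multinomial flag, huge total mass
  set.seed(19)
  mn <- t(rmultinom(1500, 1000, prob = c(0.4, 0.3, 0.2, 0.1)))
  fm <- fit_dm(taxon_table(mn))
  expect_true("near_multinomial" %in% fm$flags)
  expect_gt(fm$total_mass, 1e4)

  # over-dispersion relative to the multinomial
  p1 <- tb$counts[, 1] / rowSums(tb$counts)
  pbar <- mean(p1)
  expect_gt(var(p1), 1.5 * mean(pbar * (1 - pbar) / libs))
})

test_that("the benchmark catalogue spans the documented effect shapes", {
  params <- synthetic_benchmark_params(8, seed = 3)
  types <- vapply(params, `[[`, "", "effect_type")
  shift <- params[[which(types == "shift")[1]]]
  expect_true(length(unique(shift$beta_c)) == 1 && shift$beta_c[1] != 0)
  crossing <- params[[which(types == "crossing")[1]]]
  expect_true(min(crossing$beta_c) < 0 && max(crossing$beta_c) > 0)
  prevs <- plogis(vapply(params, function(p) p$gamma_z[1], numeric(1)))
  expect_gt(max(prevs) - min(prevs), 0.4)
  p2 <- synthetic_benchmark_params(8, seed = 3)
  expect_identical(params[[5]]$beta_z, p2[[5]]$beta_z)
  # generated tables pass table validation
  tb <- generate_twopart_table(params, zinq_design(rbinom(60, 1, .5)),
                               seed = 23)
  expect_s3_class(tb, "taxon_table")
  expect_true(all(tb$counts >= 0))
})
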