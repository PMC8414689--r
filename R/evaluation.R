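#' Fraction of p-values below a significance cutoff
#'
#' NA p-values (degenerate taxa) count as non-rejections; their number is
#' reported in the attribute `"n_na"`.
#'
#' @param pvals Numeric vector of p-values (NA allowed).
#' @param alpha Significance cutoff.
#' @return Scalar rejection rate with attribute `n_na`.
#' @export
rejection_rate <- function(pvals, alpha) {
  if (!length(pvals)) stop("empty p-value vector")
  out <- sum(pvals < alpha, na.rm = TRUE) / length(pvals)
  attr(out, "n_na") <- sum(is.na(pvals))
  out
}

#' Replicated calibration / power study
#'
#' Runs `reps` independent replicates: each draws a dataset from
#' `generator(seed_r)` (per-replicate seeds derived deterministically from
#' the master seed, so results do not depend on any chunking of the loop)
#' and computes one p-value with `test(data)`. Replicates that raise an
#' error are recorded and skipped. Rejection rates at each `alpha` are
#' reported with binomial Monte-Carlo standard errors.
#'
#' @param generator Function of one argument (an integer seed) returning a
#'   dataset.
#' @param test Function of one argument (the dataset) returning a scalar
#'   p-value.
#' @param reps Number of replicates.
#' @param alphas Numeric vector of significance cutoffs.
#' @param seed Master integer seed.
#' @param label Optional scenario descriptor stored in the report.
#' @return An object of class `zinq_sim_report`: list with `rates` (data
#'   frame of `alpha`, `rate`, `se`), `reps`, `n_failed`, `n_na`, `pvals`,
#'   `seed`, `label`.
#' @export
run_calibration_study <- function(generator, test, reps,
                                  alphas = c(0.05, 0.01), seed = 1,
                                  label = "") {
  if (reps < 1) stop("reps must be at least 1")
  pvals <- rep(NA_real_, reps)
  failed <- 0L
  for (r in seq_len(reps)) {
    seed_r <- (seed + 104729 * r) %% 2147483647
    p <- tryCatch(test(generator(seed_r)), error = function(e) {
      failed <<- failed + 1L
      NA_real_
    })
    pvals[r] <- if (is.null(p)) NA_real_ else as.numeric(p)
  }
  rates <- data.frame(
    alpha = alphas,
    rate = vapply(alphas, function(a) as.numeric(rejection_rate(pvals, a)),
                  numeric(1))
  )
  rates$se <- sqrt(rates$rate * (1 - rates$rate) / reps)
  structure(
    list(rates = rates, reps = reps, n_failed = failed,
         n_na = sum(is.na(pvals)) - failed, pvals = pvals, seed = seed,
         label = label, degenerate_se = reps == 1L),
    class = "zinq_sim_report"
  )
}

#' @export
print.zinq_sim_report <- function(x, ...) {
  cat(sprintf("zinq_sim_report%s: %d replicates (%d failed, %d NA)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$reps, x$n_failed, x$n_na))
  for (i in seq_len(nrow(x$rates))) {
    cat(sprintf("  alpha=%.3g  rate=%.4f  (MC-SE %.4f)\n",
                x$rates$alpha[i], x$rates$rate[i], x$rates$se[i]))
  }
  invisible(x)
}

# Extract one p-value per taxon from a list of zinq_result objects (or pass
# a numeric vector through).
extract_pvalues <- function(x, which = c("cauchy", "minp", "logistic")) {
  which <- match.arg(which)
  if (is.numeric(x)) return(x)
  field <- switch(which, cauchy = "p_cauchy", minp = "p_minp",
                  logistic = "p_logistic")
  vapply(x, function(r) r[[field]], numeric(1))
}

#' False/true positive rates from null and alternative tables
#'
#' FPR is the proportion of positive calls among the taxa of a null table
#' and TPR among an alternative table; with several tables per side the
#' per-table rates are averaged. Taxa with NA p-values (degenerate) are
#' excluded from the denominators and counted separately.
#'
#' @param results_null,results_alt A list of `zinq_result` objects (one
#'   table), a numeric p-value vector, or a list of such tables.
#' @param alphas Significance cutoffs.
#' @param which Which per-taxon p-value to use (for `zinq_result` input).
#' @return Data frame with `alpha`, `fpr`, `tpr`, `n_na_null`, `n_na_alt`.
#' @export
fpr_tpr_table <- function(results_null, results_alt,
                          alphas = c(0.05, 0.01), which = "cauchy") {
  as_tables <- function(x) {
    if (is.numeric(x)) return(list(x))
    if (is.list(x) && length(x) && inherits(x[[1]], "zinq_result")) {
      return(list(extract_pvalues(x, which)))
    }
    lapply(x, extract_pvalues, which = which)
  }
  nulls <- as_tables(results_null)
  alts <- as_tables(results_alt)
  if (!length(nulls) || !length(alts)) stop("empty input")
  rate_one <- function(p, a) mean(p[!is.na(p)] < a)
  out <- data.frame(alpha = alphas)
  out$fpr <- vapply(alphas, function(a) {
    mean(vapply(nulls, rate_one, numeric(1), a = a))
  }, numeric(1))
  out$tpr <- vapply(alphas, function(a) {
    mean(vapply(alts, rate_one, numeric(1), a = a))
  }, numeric(1))
  out$n_na_null <- sum(vapply(nulls, function(p) sum(is.na(p)), numeric(1)))
  out$n_na_alt <- sum(vapply(alts, function(p) sum(is.na(p)), numeric(1)))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; NA entries are passed
#' through and the original order is preserved.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Coefficient of variation of a coefficient vector
#'
#' `|sd / mean|` with sample standard deviation (denominator `n - 1`);
#' `Inf` when the mean is within `1e-12` of zero.
#'
#' @param coefs Numeric vector of coefficients.
#' @return Scalar coefficient of variation.
#' @export
coefficient_cv <- function(coefs) {
  m <- mean(coefs)
  if (abs(m) < 1e-12) return(Inf)
  abs(stats::sd(coefs) / m)
}

#' Heterogeneity of a taxon's association with the variable of interest
#'
#' Fits the full two-part model (logistic presence/absence coefficient of
#' the variable, plus its quantile-regression coefficients at the grid
#' `0.05, 0.10, ..., 0.95` on the non-zero part) and returns the
#' coefficient of variation of the resulting coefficients. Homogeneous
#' (pure location-shift) associations give small values; sign-changing or
#' quantile-concentrated effects give large ones.
#'
#' @param y Non-negative outcome vector (one taxon).
#' @param design A [zinq_design()].
#' @param cv_grid Quantile levels for the coefficient profile.
#' @param discrete Logical or `NULL` (auto-detect).
#' @param seed Optional seed (tie-breaking perturbation).
#' @return Scalar coefficient of variation (`Inf` if the mean coefficient
#'   is numerically zero).
#' @export
heterogeneity_cv <- function(y, design, cv_grid = seq(0.05, 0.95, by = 0.05),
                             discrete = NULL, seed = NULL) {
  stopifnot(inherits(design, "zinq_design"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(discrete)) discrete <- all(abs(y - round(y)) < 1e-8)
  mask <- y > 0
  m <- sum(mask)
  p <- ncol(design$covariates)
  if (m < max(15L, p + 2L)) stop("taxon below the prevalence guard")
  X <- cbind(design$covariates, design$variable)
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(mask), family = stats::binomial())
  )
  gamma1 <- if (all(mask)) NULL else fit$coefficients[p + 1]
  w <- perturb_counts(y, discrete)$w
  Xs <- X[mask, , drop = FALSE]
  ws <- w[mask]
  betas <- vapply(cv_grid, function(tau) {
    qr_fit_br(Xs, ws, tau)$coefficients[p + 1]
  }, numeric(1))
  coefficient_cv(c(gamma1, betas))
}

#' Run a packaged benchmark scenario
#'
#' Convenience wrappers over the generators and the per-taxon test, one per
#' simulation design:
#' \describe{
#'   \item{`s1-edf`}{single-taxon two-group sampling from empirical
#'     distributions, null plus mixture settings `mix = 1, 0.8, 0.6`;
#'     reports per-setting rejection rates.}
#'   \item{`s2-twopart`}{table-wide two-part model simulation with
#'     covariates; reports average FPR (null tables) and TPR (alternative
#'     tables).}
#'   \item{`s3-dm`}{Dirichlet-multinomial tables, shared model under the
#'     null versus group-specific models; average FPR/TPR.}
#'   \item{`s4-permute`}{covariates jointly permuted over the samples of an
#'     alternative table; average FPR.}
#' }
#'
#' @param scenario One of `"s1-edf"`, `"s2-twopart"`, `"s3-dm"`,
#'   `"s4-permute"`.
#' @param reps Replicates (datasets per condition).
#' @param n Total sample size per dataset.
#' @param taxa Number of taxa for table scenarios.
#' @param alphas Significance cutoffs.
#' @param seed Master seed.
#' @param combine Which combined p-value to evaluate.
#' @return A data frame of rejection rates by condition and alpha.
#' @export
benchmark_scenario <- function(scenario = c("s1-edf", "s2-twopart", "s3-dm",
                                            "s4-permute"),
                               reps = 100, n = 300, taxa = 20,
                               alphas = c(0.05, 0.01), seed = 1,
                               combine = c("cauchy", "minp")) {
  scenario <- match.arg(scenario)
  combine <- match.arg(combine)
  pfield <- combine
  if (scenario == "s1-edf") {
    pair <- benchmark_edf_pair(seed)
    conds <- list(null = NA, mix1 = 1, mix0.8 = 0.8, mix0.6 = 0.6)
    out <- do.call(rbind, lapply(names(conds), function(nm) {
      mix <- conds[[nm]]
      gen <- function(s) {
        if (is.na(mix)) {
          p0 <- edf_pair(pair$values_b, pair$values_b)
          edf_mixture_sampler(p0, n %/% 2, mix = 1, seed = s)
        } else {
          edf_mixture_sampler(pair, n %/% 2, mix = mix, seed = s)
        }
      }
      tst <- function(d) {
        res <- zinq_test(d$y, zinq_design(d$group), combine = combine)
        extract_pvalues(list(res), pfield)
      }
      rep_ <- run_calibration_study(gen, tst, reps, alphas, seed, label = nm)
      cbind(condition = nm, rep_$rates)
    }))
    return(out)
  }
  params <- synthetic_benchmark_params(taxa, seed = seed)
  base_design <- function(s) {
    set.seed(s)
    zinq_design(stats::rbinom(n, 1, 0.5))
  }
  run_tables <- function(make_table, label) {
    rates <- matrix(0, reps, length(alphas))
    for (r in seq_len(reps)) {
      s <- (seed + 7207 * r) %% 2147483647
      tab <- make_table(s)
      res <- zinq_table(tab$table, tab$design, combine = combine,
                        seed = s)
      pv <- extract_pvalues(res, pfield)
      rates[r, ] <- vapply(alphas, function(a) mean(pv[!is.na(pv)] < a),
                           numeric(1))
    }
    data.frame(condition = label, alpha = alphas, rate = colMeans(rates),
               se = apply(rates, 2, stats::sd) / sqrt(reps))
  }
  if (scenario == "s2-twopart") {
    mk <- function(null) function(s) {
      d <- base_design(s)
      list(table = generate_twopart_table(params, d,
                                          null_constraint = null, seed = s),
           design = d)
    }
    return(rbind(run_tables(mk(TRUE), "null"), run_tables(mk(FALSE), "alt")))
  }
  if (scenario == "s3-dm") {
    d0 <- base_design(seed)
    start <- generate_twopart_table(params, d0, null_constraint = FALSE,
                                    seed = seed)
    f0 <- fit_dm(start)
    f1a <- fit_dm(taxon_table(start$counts[d0$variable == 1, , drop = FALSE]))
    f1b <- fit_dm(taxon_table(start$counts[d0$variable == 0, , drop = FALSE]))
    libs <- round(stats::median(start$library_sizes))
    mk <- function(null) function(s) {
      set.seed(s)
      grp <- stats::rbinom(n, 1, 0.5)
      ls <- sample(start$library_sizes, n, replace = TRUE)
      pars <- if (null) f0 else list(f1b, f1a)  # factor levels 0,1
      list(table = generate_dm_table(pars, grp, ls, seed = s),
           design = zinq_design(grp))
    }
    return(rbind(run_tables(mk(TRUE), "null"), run_tables(mk(FALSE), "alt")))
  }
  # s4-permute
  d0 <- base_design(seed)
  tab0 <- generate_twopart_table(params, d0, null_constraint = FALSE,
                                 seed = seed)
  mk <- function(s) {
    list(table = tab0, design = permute_covariates(d0, seed = s))
  }
  run_tables(mk, "permuted_null")
}

# Fixed synthetic two-group zero-inflated empirical distributions used by
# the s1 benchmark: group A is more prevalent and right-shifted.
benchmark_edf_pair <- function(seed = 1, m = 600) {
  set.seed(seed)
  za <- stats::rbinom(m, 1, 0.75)
  zb <- stats::rbinom(m, 1, 0.60)
  va <- za * stats::rlnorm(m, 0.5, 1)
  vb <- zb * stats::rlnorm(m, 0.0, 1)
  edf_pair(va, vb)
}
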