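#' Choose the quantile grid for a taxon
#'
#' Applies the grid policy: a user-supplied grid is honored whenever it has
#' fewer levels than the number of non-zero measurements; otherwise the
#' conservative default `0.1, 0.25, 0.5, 0.75, 0.9` is used for continuous
#' outcomes with at least 30 non-zero observations, and the central grid
#' `0.25, 0.5, 0.75` for discrete outcomes or fewer non-zeros. Below 15
#' non-zero observations (or fewer than `p + 2`) quantile testing is refused
#' and the taxon is flagged low-prevalence.
#'
#' @param m Number of non-zero observations.
#' @param discrete Logical: is the (normalized) outcome discrete?
#' @param user_grid Optional numeric vector of quantile levels in (0,1).
#' @param p Number of columns of the covariate matrix (including intercept).
#' @return List with `taus`, `origin` (`"user"`, `"default_common"`,
#'   `"default_rare_or_discrete"`), and `low_prevalence`.
#' @export
choose_grid <- function(m, discrete, user_grid = NULL, p = 1L) {
  if (m < 1) stop("m must be at least 1")
  if (!is.null(user_grid)) {
    taus <- as.numeric(user_grid)
    if (any(taus <= 0 | taus >= 1)) stop("quantile levels must lie in (0,1)")
    if (is.unsorted(taus, strictly = TRUE)) {
      stop("quantile levels must be strictly increasing")
    }
    if (length(taus) >= m) {
      stop("the number of quantile levels (", length(taus),
           ") must be less than the number of non-zero measurements (",
           m, ")")
    }
    return(list(taus = taus, origin = "user", low_prevalence = FALSE))
  }
  if (m < max(15L, p + 2L)) {
    return(list(taus = numeric(), origin = "default_rare_or_discrete",
                low_prevalence = TRUE))
  }
  if (!discrete && m >= 30) {
    list(taus = c(0.1, 0.25, 0.5, 0.75, 0.9), origin = "default_common",
         low_prevalence = FALSE)
  } else {
    list(taus = c(0.25, 0.5, 0.75), origin = "default_rare_or_discrete",
         low_prevalence = FALSE)
  }
}

#' Cauchy combination weights
#'
#' The zero part receives weight `r_hat` (the observed zero proportion) and
#' the quantile levels split the remaining `1 - r_hat` proportionally to
#' `tau_k` for levels at or below the median and `1 - tau_k` above it, so
#' central quantiles are weighted more than extreme tails and all weights
#' sum to one.
#'
#' @param taus Quantile levels (numeric vector, possibly empty).
#' @param r_hat Observed zero proportion in `[0, 1]`.
#' @return List with `r_hat` and `w` (length-`K` quantile weights).
#' @export
cauchy_weights <- function(taus, r_hat) {
  if (is.list(taus)) taus <- taus$taus
  if (r_hat < 0 || r_hat > 1) stop("r_hat must be in [0,1]")
  if (!length(taus)) return(list(r_hat = r_hat, w = numeric()))
  g <- ifelse(taus <= 0.5, taus, 1 - taus)
  list(r_hat = r_hat, w = (1 - r_hat) * g / sum(g))
}

# tan((0.5 - p) * pi) with the small-p asymptote 1/(p*pi) to avoid
# overflow/cancellation at extreme significance.
cauchy_tan <- function(p) {
  p <- pmin(p, 1 - 1e-15)
  ifelse(p < 1e-15, 1 / (p * pi), tan((0.5 - p) * pi))
}

#' Weighted Cauchy combination of the marginal p-values
#'
#' `T = r_hat tan((0.5 - p_L) pi) + sum_k w_k tan((0.5 - p_k) pi)`; under
#' the null, `T` converges to a standard Cauchy distribution whenever the
#' weights sum to one, so the combined p-value is `P(Cauchy > T)`.
#' Unavailable components (NA p-values) are dropped and the remaining
#' weights renormalized to sum to one, preserving the null law.
#'
#' @param p_l Logistic p-value (or `NA`).
#' @param p_q Numeric vector of per-quantile p-values (may contain `NA`).
#' @param weights A [cauchy_weights()] result matching `p_q`.
#' @return The combined p-value (scalar; `NA` if no component is available).
#' @export
combine_cauchy <- function(p_l, p_q, weights) {
  pv <- c(p_l, p_q)
  wt <- c(weights$r_hat, weights$w)
  keep <- is.finite(pv) & wt > 0
  if (!any(keep)) return(NA_real_)
  pv <- pv[keep]
  wt <- wt[keep] / sum(wt[keep])
  tstat <- sum(wt * cauchy_tan(pv))
  stats::pcauchy(tstat, lower.tail = FALSE)
}

#' MinP combination of the marginal p-values by resampling
#'
#' The test statistic is the smallest available marginal p-value,
#' `T_minP = min(p_L, p_1, ..., p_K)`. Its own p-value is
#' `1 - (1 - T_minP) * P(all quantile p's > T_minP | H0)`, using the
#' (conditional) independence of the logistic and quantile parts; the joint
#' probability is estimated by drawing `B` score vectors from the mean-zero
#' multivariate normal with the cross-quantile covariance, studentizing
#' them, and counting how often every two-sided p-value exceeds `T_minP`.
#' If the logistic p-value is unavailable its factor is dropped; with no
#' quantile part the combined p-value is simply `p_L`.
#'
#' @param p_l Logistic p-value (or `NA`).
#' @param p_q Numeric vector of per-quantile p-values.
#' @param sigma A [score_covariance()] result (or `NULL` if no quantile
#'   part was run).
#' @param B Number of resampling draws (at least 1000).
#' @param seed Optional integer seed.
#' @return List with `p` (combined p-value), `t_minp` (the minimum
#'   p-value statistic), `p_joint` (estimated joint exceedance
#'   probability), `mc_se` (Monte-Carlo standard error of `p`), `B`.
#' @export
combine_minp <- function(p_l, p_q, sigma, B = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  have_q <- !is.null(sigma) && length(p_q) && any(is.finite(p_q))
  if (!have_q) {
    return(list(p = p_l, t_minp = p_l, p_joint = 1, mc_se = 0, B = 0L))
  }
  if (B < 1000) stop("B must be at least 1000")
  keep <- is.finite(p_q)
  taus <- sigma$taus[keep]
  S <- sigma$sigma[keep, keep, drop = FALSE]
  t_minp <- min(c(p_l, p_q[keep]), na.rm = TRUE)
  sd_k <- sqrt(diag(S))
  R <- S / tcrossprod(sd_k)
  K <- length(taus)
  ch <- tryCatch(chol(R),
                 error = function(e) chol(R + diag(1e-10, K)))
  Tmat <- abs(matrix(stats::rnorm(B * K), B, K) %*% ch)
  zcrit <- stats::qnorm(1 - t_minp / 2)
  mx <- Tmat[, 1]
  if (K > 1) for (k in 2:K) mx <- pmax(mx, Tmat[, k])
  p_joint <- mean(mx < zcrit)
  fac <- if (is.finite(p_l)) 1 - t_minp else 1
  p <- 1 - fac * p_joint
  list(p = min(max(p, 0), 1), t_minp = t_minp, p_joint = p_joint,
       mc_se = fac * sqrt(p_joint * (1 - p_joint) / B), B = B)
}

#' Zero-inflated quantile association test for one taxon
#'
#' The end-to-end per-taxon test: marginal layer ([zinq_marginals()]) then
#' both p-value combinations. Degenerate situations are flagged, never
#' fatal, so a table-wide run always completes.
#'
#' @param y Non-negative numeric outcome vector (one taxon's normalized
#'   abundance across samples).
#' @param design A [zinq_design()].
#' @param taxon_id Identifier recorded in the result.
#' @param grid Optional user quantile grid.
#' @param discrete Logical or `NULL` (auto-detect).
#' @param combine `"both"` (default), `"cauchy"`, or `"minp"`.
#' @param minp_draws Resampling draws for the MinP combination.
#' @param seed Optional integer seed (perturbation and MinP resampling).
#' @param logistic_method Passed to [logistic_presence_test()].
#' @return An object of class `zinq_result`: list with `taxon_id`, `n`,
#'   `m`, `r_hat`, `p_logistic`, `taus`, `p_quantile`, `t_quantile`,
#'   `p_cauchy`, `p_minp`, `t_minp`, `minp_mc_se`, `flags`, `grid_origin`.
#' @export
zinq_test <- function(y, design, taxon_id = "taxon", grid = NULL,
                      discrete = NULL, combine = c("both", "cauchy", "minp"),
                      minp_draws = 10000, seed = NULL,
                      logistic_method = "lrt") {
  combine <- match.arg(combine)
  if (!is.null(seed)) set.seed(seed)
  marg <- zinq_marginals(y, design, grid = grid, discrete = discrete,
                         logistic_method = logistic_method)
  p_l <- if (!is.null(marg$logistic) && !marg$logistic$degenerate) {
    marg$logistic$p
  } else {
    NA_real_
  }
  p_q <- vapply(marg$quantile, function(q) q$p, numeric(1))
  t_q <- vapply(marg$quantile, function(q) q$t, numeric(1))
  out <- list(taxon_id = taxon_id, n = marg$n, m = marg$m,
              r_hat = marg$r_hat, p_logistic = p_l, taus = marg$taus,
              p_quantile = p_q, t_quantile = t_q,
              p_cauchy = NA_real_, p_minp = NA_real_, t_minp = NA_real_,
              minp_mc_se = NA_real_, flags = marg$flags,
              grid_origin = marg$grid_origin)
  class(out) <- "zinq_result"
  if (marg$m == 0) return(out)
  if (combine %in% c("both", "cauchy")) {
    wts <- cauchy_weights(marg$taus, marg$r_hat)
    out$p_cauchy <- combine_cauchy(p_l, p_q, wts)
  }
  if (combine %in% c("both", "minp")) {
    mp <- combine_minp(p_l, p_q, marg$sigma, B = minp_draws)
    out$p_minp <- mp$p
    out$t_minp <- mp$t_minp
    out$minp_mc_se <- mp$mc_se
  }
  out
}

#' @export
print.zinq_result <- function(x, ...) {
  cat(sprintf("zinq_result '%s': n=%d, nonzero=%d (r_hat=%.3f)\n",
              x$taxon_id, x$n, x$m, x$r_hat))
  cat(sprintf("  p_logistic=%s  p_cauchy=%s  p_minp=%s\n",
              format(x$p_logistic, digits = 4),
              format(x$p_cauchy, digits = 4),
              format(x$p_minp, digits = 4)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Run the zero-inflated quantile test on every taxon of a table
#'
#' Applies [zinq_test()] taxon by taxon, in input order, with per-taxon
#' seeds derived deterministically from a single base seed
#' (`seed_j = (seed + 7919 j) mod (2^31 - 1)`), so repeated runs are
#' bit-identical and taxa can be recomputed independently.
#'
#' @param table A `normalized_table`, [taxon_table()], or numeric matrix
#'   (samples x taxa).
#' @param design A [zinq_design()] aligned with the table.
#' @param ... Further arguments passed to [zinq_test()] (`grid`, `combine`,
#'   `minp_draws`, `logistic_method`).
#' @param discrete Logical or `NULL`; for a `normalized_table` the table's
#'   own flag is used.
#' @param seed Base seed for per-taxon seed derivation.
#' @param verbose Print a progress line every 50 taxa.
#' @return List of `zinq_result` objects, one per taxon in input order.
#' @export
zinq_table <- function(table, design, ..., discrete = NULL, seed = NULL,
                       verbose = FALSE) {
  if (inherits(table, "taxon_table")) table <- as_normalized(table)
  if (inherits(table, "normalized_table")) {
    if (is.null(discrete)) discrete <- table$discrete
    vals <- table$values
  } else {
    vals <- as.matrix(table)
  }
  J <- ncol(vals)
  ids <- colnames(vals)
  if (is.null(ids)) ids <- paste0("taxon", seq_len(J))
  out <- vector("list", J)
  for (j in seq_len(J)) {
    seed_j <- if (is.null(seed)) NULL else (seed + 7919 * j) %% 2147483647
    out[[j]] <- zinq_test(vals[, j], design, taxon_id = ids[j],
                          discrete = discrete, seed = seed_j, ...)
    if (verbose && j %% 50 == 0) {
      message("zinq_table: ", j, "/", J, " taxa done")
    }
  }
  out
}
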