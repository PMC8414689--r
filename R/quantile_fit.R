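#' Quantile check loss
#'
#' `rho_tau(u) = u * (tau - I(u < 0))`, the asymmetric absolute loss whose
#' minimizer over a location parameter is the `tau`-th quantile.
#'
#' @param u Numeric vector of residuals.
#' @param tau Quantile level in (0,1).
#' @return Numeric vector of losses.
#' @export
qr_check_loss <- function(u, tau) u * (tau - (u < 0))

# psi_tau(u) = tau - I(u < 0), the piecewise derivative of the check loss,
# with the convention psi_tau(0) = tau.
qr_psi <- function(u, tau) tau - (u < 0)

# Deterministic general-position jitter for tie-breaking inside the simplex
# solver: a fixed Park-Miller sequence (free of the linear integer relations
# that structured offsets would have), well above the residual tolerance but
# negligible against the data scale.
qr_jitter <- function(m, scale) {
  s <- 48271
  u <- numeric(m)
  for (i in seq_len(m)) {
    s <- (16807 * s) %% 2147483647
    u[i] <- s / 2147483647
  }
  scale * 1e-7 * (0.5 + u)
}

# Lower-vertex sample quantile: the smallest order statistic minimizing the
# check loss. When m*tau is an integer the minimizer is the interval
# [v_(m tau), v_(m tau + 1)]; the lower endpoint is returned.
lower_vertex_quantile <- function(v, tau) {
  m <- length(v)
  k <- m * tau
  k <- if (abs(k - round(k)) < 1e-9) round(k) else ceiling(k)
  k <- min(max(k, 1L), m)
  sort(v, method = "quick")[k]
}

#' Exact linear-programming fit of a quantile regression
#'
#' Minimizes `sum_i rho_tau(y_i - x_i' b)` by an exterior-point simplex over
#' bases of `p` interpolated observations (the classical approach for the
#' quantile-regression linear program). At each iteration the optimality of
#' the current vertex is checked via the dual multipliers
#' `lambda_j in [-tau, 1-tau]`; on violation, a directional line search over
#' residual breakpoints (a weighted-quantile step) swaps one observation in
#' the basis. The fit is deterministic: the initial basis comes from pivoted
#' QR of the design and the line search always stops at the first breakpoint
#' at which the directional derivative becomes non-negative.
#'
#' @param X Numeric design matrix (`m` by `p`), full column rank.
#' @param y Numeric response of length `m`.
#' @param tau Quantile level in (0,1).
#' @param max_iter Iteration cap (a safety guard; typical problems take
#'   far fewer steps).
#' @return List with `coefficients`, `basis` (row indices interpolated by
#'   the solution), `iterations`, and the achieved `loss`.
#' @export
qr_fit_br <- function(X, y, tau, max_iter = 10000L, .retry = TRUE) {
  X <- as.matrix(X)
  m <- nrow(X)
  p <- ncol(X)
  if (length(y) != m) stop("X and y are incompatible")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0,1)")
  if (m < p) stop("fewer observations than parameters")
  tol <- 1e-9
  tolr <- 1e-9 * max(1, max(abs(y)))
  # Tied responses create degenerate vertices where the multiplier test is
  # unreliable; resolve them by an infinitesimal deterministic jitter and
  # refit the optimal basis on the original data.
  if (.retry && anyDuplicated(y)) {
    fit2 <- qr_fit_br(X, y + qr_jitter(m, max(1, max(abs(y)))), tau,
                      max_iter, .retry = FALSE)
    h2 <- fit2$basis
    alpha2 <- solve(X[h2, , drop = FALSE], y[h2])
    return(list(coefficients = alpha2, basis = h2,
                iterations = fit2$iterations,
                loss = sum(qr_check_loss(y - as.vector(X %*% alpha2), tau))))
  }
  # initial basis: the first p linearly independent rows, found by pivoted
  # QR of the transpose (LINPACK pivoting keeps the original order except
  # for dependent columns, so the choice is deterministic)
  qtx <- qr(t(X))
  if (qtx$rank < p) stop("design matrix is rank deficient")
  h <- sort(qtx$pivot[seq_len(p)])
  idx <- seq_len(m)
  for (iter in seq_len(max_iter)) {
    Xh <- X[h, , drop = FALSE]
    alpha <- solve(Xh, y[h])
    r <- y - as.vector(X %*% alpha)
    r[h] <- 0
    nb <- idx[-h]
    psi_nb <- qr_psi(r[nb], tau)
    g <- as.vector(crossprod(X[nb, , drop = FALSE], psi_nb))
    lambda <- solve(t(Xh), g)
    viol_hi <- lambda - (1 - tau)
    viol_lo <- -tau - lambda
    viol <- pmax(viol_hi, viol_lo)
    done <- list(coefficients = alpha, basis = h, iterations = iter,
                 loss = sum(qr_check_loss(r, tau)))
    if (max(viol) <= tol) return(done)
    # try violated multipliers in decreasing order; with tied observations
    # (degenerate vertices) a flagged direction may not actually descend
    progressed <- FALSE
    for (j in order(viol, decreasing = TRUE)) {
      if (viol[j] <= tol) break
      s <- if (viol_hi[j] >= viol_lo[j]) 1 else -1
      ej <- numeric(p)
      ej[j] <- 1
      d <- s * solve(Xh, ej)
      wv <- as.vector(X %*% d)
      # directional derivative at t = 0+: non-basis points sitting exactly
      # on the current fit contribute the sign they move towards
      nbr <- r[nb]
      at_fit <- abs(nbr) <= tolr
      psi_dir <- tau - as.numeric(nbr < -tolr | (at_fit & wv[nb] > 1e-12))
      g0 <- -sum(psi_dir * wv[nb]) + (if (s > 0) 1 - tau else tau)
      if (g0 >= -tol) next
      ok <- abs(wv[nb]) > 1e-12
      tvals <- r[nb][ok] / wv[nb][ok]
      keep <- tvals > tolr / pmax(abs(wv[nb][ok]), 1e-12)
      cand <- nb[ok][keep]
      tvals <- tvals[keep]
      if (!length(cand)) {
        stop("quantile fit is unbounded along a descent direction")
      }
      ord <- order(tvals, cand)
      grad <- g0
      enter <- NA_integer_
      for (k in ord) {
        grad <- grad + abs(wv[cand[k]])
        if (grad >= -tol) {
          enter <- cand[k]
          break
        }
      }
      if (is.na(enter)) {
        stop("quantile fit is unbounded along a descent direction")
      }
      h[j] <- enter
      h <- sort(h)
      progressed <- TRUE
      break
    }
    if (!progressed) {
      # Degenerate vertex (tied observations): no tested edge descends even
      # though a multiplier is out of bounds. Re-solve in general position
      # with a deterministic infinitesimal jitter, then refit the resulting
      # basis on the original data.
      if (!.retry) return(done)
      fit2 <- qr_fit_br(X, y + qr_jitter(m, max(1, max(abs(y)))), tau,
                        max_iter, .retry = FALSE)
      h2 <- fit2$basis
      alpha2 <- solve(X[h2, , drop = FALSE], y[h2])
      loss2 <- sum(qr_check_loss(y - as.vector(X %*% alpha2), tau))
      if (loss2 <= done$loss) {
        return(list(coefficients = alpha2, basis = h2,
                    iterations = iter + fit2$iterations, loss = loss2))
      }
      return(done)
    }
  }
  stop("quantile fit did not converge in ", max_iter, " iterations")
}

#' Fit the null conditional-quantile model on the non-zero subset
#'
#' Estimates `alpha_hat(tau)`, the minimizer of the check loss
#' `sum_i rho_tau(w_i - z_i' alpha) I(y_i > 0)` over the covariate-only
#' model (the variable of interest is held out under the null). For
#' intercept-only designs the fit is the lower-vertex sample quantile of the
#' non-zero outcomes (when the minimizing set is an interval, its lower
#' endpoint is taken — a documented deterministic convention); otherwise the
#' exact simplex solver [qr_fit_br()] is used.
#'
#' @param w Numeric outcome vector (perturbed if discrete) of length `n`, or
#'   a `perturbed_outcome` from [perturb_counts()].
#' @param design A [zinq_design()].
#' @param nonzero_mask Logical length-`n` vector, `I(y > 0)` on the raw
#'   outcome.
#' @param tau Quantile level in (0,1).
#' @return Numeric coefficient vector `alpha_hat` of length `p`, with
#'   attribute `"basis"` (interpolated observation indices, full-data
#'   indexing) when the simplex path was used.
#' @export
fit_null_quantile <- function(w, design, nonzero_mask, tau) {
  if (is.list(w)) w <- w$w
  stopifnot(inherits(design, "zinq_design"))
  Z <- design$covariates
  mask <- as.logical(nonzero_mask)
  m <- sum(mask)
  p <- ncol(Z)
  if (m < p + 1) {
    stop(sprintf("only %d non-zero observations for %d parameters", m, p))
  }
  ws <- w[mask]
  Zs <- Z[mask, , drop = FALSE]
  if (p == 1L && all(Zs == Zs[1]) && Zs[1] > 0) {
    alpha <- lower_vertex_quantile(ws, tau) / Zs[1]
    names(alpha) <- colnames(Z)
    return(alpha)
  }
  fit <- qr_fit_br(Zs, ws, tau)
  alpha <- fit$coefficients
  names(alpha) <- colnames(Z)
  attr(alpha, "basis") <- which(mask)[fit$basis]
  alpha
}
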