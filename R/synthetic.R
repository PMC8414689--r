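#' Two-part generator parameters for one taxon
#'
#' Holds the fitted (or designed) parameters of the zero-inflated two-part
#' quantile model: logistic coefficients for presence/absence and quantile
#' coefficient functions evaluated on a fine grid (`tau = 0.01, ..., 0.99`
#' by default). `beta_z` has one row per grid level and one column per
#' covariate (including the intercept); `beta_c` is the coefficient function
#' of the variable of interest.
#'
#' @param gamma_z Numeric length-`p` logistic coefficients of the
#'   covariates (intercept first).
#' @param gamma_c Scalar logistic coefficient of the variable of interest.
#' @param beta_z Numeric `length(fine_grid)` by `p` matrix of quantile
#'   coefficients of the covariates.
#' @param beta_c Numeric vector of quantile coefficients of the variable.
#' @param fine_grid Quantile levels at which `beta` is evaluated.
#' @param effect_type Optional label (`"null"`, `"shift"`, `"spindle"`,
#'   `"crossing"`) used by the benchmark catalogue.
#' @param flags Character vector of fitting flags.
#' @return An object of class `two_part_params`.
#' @export
two_part_params <- function(gamma_z, gamma_c, beta_z, beta_c,
                            fine_grid = seq(0.01, 0.99, by = 0.01),
                            effect_type = NA_character_,
                            flags = character()) {
  beta_z <- as.matrix(beta_z)
  if (nrow(beta_z) != length(fine_grid) || length(beta_c) != length(fine_grid)) {
    stop("beta dimensions do not match the fine grid")
  }
  if (length(gamma_z) != ncol(beta_z)) {
    stop("gamma_z and beta_z disagree on the number of covariates")
  }
  structure(
    list(gamma_z = as.numeric(gamma_z), gamma_c = as.numeric(gamma_c),
         beta_z = beta_z, beta_c = as.numeric(beta_c),
         fine_grid = as.numeric(fine_grid), effect_type = effect_type,
         flags = flags),
    class = "two_part_params"
  )
}

#' Null-constrain two-part parameters
#'
#' Sets the variable-of-interest coefficients to zero (`gamma_c = 0`,
#' `beta_c(tau) = 0` for all `tau`) and leaves every other coefficient
#' untouched, turning a fitted model into a null generator.
#'
#' @param params A [two_part_params()].
#' @return The constrained `two_part_params`.
#' @export
constrain_null <- function(params) {
  stopifnot(inherits(params, "two_part_params"))
  params$gamma_c <- 0
  params$beta_c <- rep(0, length(params$beta_c))
  params
}

# Ridge-penalized logistic Newton iteration, used as a fall-back when the
# unpenalized fit separates.
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100) {
  p <- ncol(X)
  b <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * wt) + diag(lambda, p)
    g <- crossprod(X, y - mu) - lambda * b
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  as.numeric(b)
}

#' Fit the two-part quantile model to one taxon
#'
#' Estimates the logistic presence/absence coefficients by maximum
#' likelihood (ridge-penalized fall-back under separation, flagged) and the
#' quantile coefficient functions by quantile regression of the non-zero
#' part at every level of the fine grid. Discrete outcomes are perturbed
#' before the quantile fits to break ties.
#'
#' @param y Non-negative outcome vector (one taxon).
#' @param design A [zinq_design()].
#' @param fine_grid Quantile levels for the coefficient functions.
#' @param discrete Logical or `NULL` (auto-detect).
#' @param seed Optional seed (governs the tie-breaking perturbation).
#' @return A [two_part_params()].
#' @export
fit_twopart <- function(y, design, fine_grid = seq(0.01, 0.99, by = 0.01),
                        discrete = NULL, seed = NULL) {
  stopifnot(inherits(design, "zinq_design"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(discrete)) discrete <- all(abs(y - round(y)) < 1e-8)
  n <- length(y)
  mask <- y > 0
  m <- sum(mask)
  Z <- design$covariates
  p <- ncol(Z)
  X <- cbind(Z, design$variable)
  if (m < p + 2) stop("too few non-zero observations to fit the model")
  flags <- character()
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(mask), family = stats::binomial())
  )
  if (!fit$converged || max(abs(fit$coefficients)) > 30) {
    flags <- c(flags, "logistic_separation_penalized")
    co <- ridge_logistic(X, as.numeric(mask))
  } else {
    co <- fit$coefficients
  }
  gamma_z <- co[seq_len(p)]
  gamma_c <- co[p + 1]
  w <- perturb_counts(y, discrete)$w
  Xs <- X[mask, , drop = FALSE]
  ws <- w[mask]
  beta <- t(vapply(fine_grid, function(tau) {
    qr_fit_br(Xs, ws, tau)$coefficients
  }, numeric(p + 1)))
  two_part_params(gamma_z, gamma_c,
                  beta_z = beta[, seq_len(p), drop = FALSE],
                  beta_c = beta[, p + 1],
                  fine_grid = fine_grid, flags = flags)
}

#' Simulate a count table from two-part quantile models
#'
#' For each sample and taxon, presence is drawn from the logistic part; when
#' present, the count is drawn by inverse-CDF sampling: the conditional
#' quantile function is evaluated on the fine grid for that sample's
#' covariates, monotonized by rearrangement (sorting the evaluated
#' quantiles, which leaves every marginal quantile intact while making the
#' inverse CDF well defined), linearly interpolated at `U ~ U(0,1)`, and
#' rounded to the nearest integer. Rounded values below 1 are clamped to 1
#' so presence stays consistent with the logistic part; the number of
#' clamped draws is recorded in the attribute `"clamp_count"`.
#'
#' @param params A [two_part_params()] or a list of them (one per taxon).
#' @param design A [zinq_design()] providing the covariates.
#' @param null_constraint Logical; apply [constrain_null()] to every taxon
#'   before generating.
#' @param seed Optional integer seed.
#' @return A [taxon_table()] with attribute `"clamp_count"`.
#' @export
generate_twopart_table <- function(params, design, null_constraint = FALSE,
                                   seed = NULL) {
  stopifnot(inherits(design, "zinq_design"))
  if (inherits(params, "two_part_params")) params <- list(params)
  if (!is.null(seed)) set.seed(seed)
  n <- length(design$variable)
  J <- length(params)
  X <- cbind(design$covariates, design$variable)
  counts <- matrix(0L, n, J)
  clamp <- 0L
  for (j in seq_len(J)) {
    pj <- params[[j]]
    if (length(pj$gamma_z) != ncol(design$covariates)) {
      stop(sprintf(paste0("parameter set %d has %d covariate coefficient(s) ",
                          "but the design has %d column(s)"),
                   j, length(pj$gamma_z), ncol(design$covariates)))
    }
    if (null_constraint) pj <- constrain_null(pj)
    eta <- as.vector(design$covariates %*% pj$gamma_z) +
      pj$gamma_c * design$variable
    d <- stats::rbinom(n, 1, stats::plogis(eta))
    pos <- which(d == 1)
    if (length(pos)) {
      B <- cbind(pj$beta_z, pj$beta_c)
      Q <- X[pos, , drop = FALSE] %*% t(B)  # samples x grid
      u <- stats::runif(length(pos))
      for (k in seq_along(pos)) {
        qfun <- sort(Q[k, ])
        val <- stats::approx(pj$fine_grid, qfun, xout = u[k], rule = 2)$y
        val <- round(val)
        if (val < 1) {
          val <- 1
          clamp <- clamp + 1L
        }
        counts[pos[k], j] <- val
      }
    }
  }
  tb <- taxon_table(counts,
                    sample_ids = paste0("sample", seq_len(n)),
                    taxon_ids = paste0("taxon", seq_len(J)))
  attr(tb, "clamp_count") <- clamp
  tb
}

#' Resample design covariates independently with replacement
#'
#' Bootstrap-resamples the variable of interest and each non-intercept
#' covariate column independently to length `n`, creating "new" samples
#' whose marginal distributions match the source but whose cross-covariate
#' relationships are destroyed — the construction used to build simulated
#' null populations.
#'
#' @param design A [zinq_design()].
#' @param n Number of samples to draw.
#' @param seed Optional seed.
#' @return A new [zinq_design()].
#' @export
resample_covariates <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "zinq_design"))
  if (!is.null(seed)) set.seed(seed)
  src_n <- length(design$variable)
  variable <- design$variable[sample.int(src_n, n, replace = TRUE)]
  Z <- design$covariates
  newZ <- matrix(1, n, ncol(Z), dimnames = list(NULL, colnames(Z)))
  if (ncol(Z) > 1) {
    for (j in 2:ncol(Z)) {
      newZ[, j] <- Z[sample.int(src_n, n, replace = TRUE), j]
    }
  }
  zinq_design(variable, newZ, variable_name = design$variable_name)
}

#' Jointly permute all covariates across samples
#'
#' Applies one random row permutation simultaneously to the variable of
#' interest and every covariate column, preserving all relationships among
#' the covariates while breaking their association with the outcome table —
#' the permutation-null construction.
#'
#' @param design A [zinq_design()].
#' @param seed Optional seed.
#' @return A new [zinq_design()] with permuted rows.
#' @export
permute_covariates <- function(design, seed = NULL) {
  stopifnot(inherits(design, "zinq_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(design$variable)
  perm <- sample.int(n)
  zinq_design(design$variable[perm],
              design$covariates[perm, , drop = FALSE],
              variable_name = design$variable_name,
              sample_ids = design$sample_ids)
}

#' Dirichlet-multinomial parameters
#'
#' @param alpha Positive concentration vector (one entry per taxon).
#' @param flags Character fitting flags.
#' @return An object of class `dm_params` with `alpha`, `total_mass`
#'   (`sum(alpha)`), and `flags`.
#' @export
dm_params <- function(alpha, flags = character()) {
  if (any(alpha <= 0)) stop("Dirichlet concentrations must be positive")
  structure(list(alpha = as.numeric(alpha), total_mass = sum(alpha),
                 flags = flags),
            class = "dm_params")
}

#' Fit a Dirichlet-multinomial distribution to a count table
#'
#' Method-of-moments estimation: taxon proportions are estimated by pooled
#' relative abundance and the over-dispersion `theta` by the Weir-Hill
#' moment estimator pooled over taxa, giving concentrations
#' `alpha_j = pi_j (1 - theta) / theta`. Near-multinomial tables
#' (`theta <= 0`) are flagged and the total mass capped at a large value;
#' taxa never observed are floored at a small positive concentration and
#' flagged.
#'
#' @param table A [taxon_table()].
#' @return A [dm_params()].
#' @export
fit_dm <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  Y <- table$counts
  n <- nrow(Y)
  J <- ncol(Y)
  if (J < 2 || n < 10) stop("need at least 2 taxa and 10 samples")
  N <- rowSums(Y)
  P <- Y / N
  pi_hat <- colSums(Y) / sum(Y)
  flags <- character()
  MSP <- colSums(N * sweep(P, 2, pi_hat)^2) / (n - 1)
  MSG <- colSums(N * P * (1 - P)) / (sum(N) - n)
  nc <- (sum(N) - sum(N^2) / sum(N)) / (n - 1)
  theta <- sum(MSP - MSG) / sum(MSP + (nc - 1) * MSG)
  if (!is.finite(theta) || theta < 1e-4) flags <- c(flags, "near_multinomial")
  if (!is.finite(theta) || theta <= 1e-8) theta <- 1e-6

  a0 <- (1 - theta) / theta
  alpha <- pi_hat * a0
  if (any(alpha <= 0)) {
    flags <- c(flags, "zero_taxon_floored")
    alpha[alpha <= 0] <- 1e-3
  }
  dm_params(alpha, flags = flags)
}

#' Simulate a count table from Dirichlet-multinomial models
#'
#' Per sample, a composition is drawn from the Dirichlet distribution of
#' that sample's group and the counts multinomially at the sample's library
#' size. With a single parameter set the group labels carry no information
#' (a null table); with two sets the groups differ in composition.
#'
#' @param params_by_group A single [dm_params()] (shared null model) or a
#'   list of two, indexed by the values of `group`.
#' @param group Vector of group labels (coerced to factor with at most two
#'   levels; ignored for a single shared parameter set).
#' @param library_sizes Positive integer vector of per-sample read depths.
#' @param seed Optional seed.
#' @return A [taxon_table()].
#' @export
generate_dm_table <- function(params_by_group, group, library_sizes,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params_by_group, "dm_params")) {
    params_by_group <- list(params_by_group)
  }
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  n <- length(library_sizes)
  g <- as.integer(factor(group))
  if (length(params_by_group) == 1L) g <- rep(1L, n)
  if (length(g) != n) stop("group and library_sizes lengths differ")
  if (max(g) > length(params_by_group)) stop("more groups than parameter sets")
  J <- length(params_by_group[[1]]$alpha)
  counts <- matrix(0L, n, J)
  for (i in seq_len(n)) {
    a <- params_by_group[[g[i]]]$alpha
    comp <- stats::rgamma(J, shape = a)
    comp <- comp / sum(comp)
    counts[i, ] <- stats::rmultinom(1, library_sizes[i], comp)
  }
  taxon_table(counts, sample_ids = paste0("sample", seq_len(n)),
              taxon_ids = paste0("taxon", seq_len(J)))
}

#' A pair of empirical distributions defining two groups
#'
#' @param values_a,values_b Non-negative numeric vectors of normalized
#'   abundances observed in the two groups.
#' @return An object of class `edf_pair`.
#' @export
edf_pair <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both edfs must be non-empty")
  if (any(values_a < 0) || any(values_b < 0)) stop("abundances must be non-negative")
  structure(list(values_a = as.numeric(values_a),
                 values_b = as.numeric(values_b)),
            class = "edf_pair")
}

#' Sample two groups from a mixture of empirical distributions
#'
#' Group 1 draws each observation from `values_a` with probability `mix` and
#' from `values_b` otherwise (iid, with replacement); group 2 symmetrically
#' (from `values_b` with probability `mix`). `mix = 1` reproduces the
#' full-effect setting, smaller values dilute the signal, and `mix = 0.5`
#' makes both groups identically distributed (a null). For null data with
#' the group-B distribution in both arms, pass an `edf_pair` whose two
#' components are both `values_b`.
#'
#' @param pair An [edf_pair()].
#' @param n_per_group Samples per group.
#' @param mix Mixture proportion in `[0.5, 1]`.
#' @param seed Optional seed.
#' @return List with `y` (length `2 n_per_group`) and `group` (1 for the
#'   first group, 0 for the second).
#' @export
edf_mixture_sampler <- function(pair, n_per_group, mix = 1, seed = NULL) {
  stopifnot(inherits(pair, "edf_pair"))
  if (mix < 0.5 || mix > 1) stop("mix must lie in [0.5, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- n_per_group
  draw <- function(primary, secondary) {
    from_primary <- stats::runif(n) < mix
    out <- numeric(n)
    out[from_primary] <- sample(primary, sum(from_primary), replace = TRUE)
    out[!from_primary] <- sample(secondary, sum(!from_primary), replace = TRUE)
    out
  }
  y1 <- draw(pair$values_a, pair$values_b)
  y0 <- draw(pair$values_b, pair$values_a)
  list(y = c(y1, y0), group = c(rep(1, n), rep(0, n)))
}

#' Reproducible catalogue of two-part benchmark parameters
#'
#' Builds `J` parameter sets spanning prevalences from about 10% to 95%,
#' log-normal-like and heavy-tailed positive parts, and a cycle of effect
#' shapes: a pure location shift (`beta_c` constant), a crossing effect
#' (`beta_c` changes sign across `tau`), a spindle-shaped effect
#' (concentrated in the upper quantiles), and a null taxon. The catalogue is
#' a stand-in for restricted cohort-fitted parameters (fully synthetic) and
#' is deterministic under the seed. Designs are intercept-only; the
#' covariate structure is supplied separately at generation time.
#'
#' @param J Number of taxa.
#' @param seed Integer seed.
#' @param fine_grid Quantile levels for the coefficient functions.
#' @return List of `J` [two_part_params()].
#' @export
synthetic_benchmark_params <- function(J, seed = 1,
                                       fine_grid = seq(0.01, 0.99, by = 0.01)) {
  if (J < 1) stop("J must be at least 1")
  set.seed(seed)
  types <- c("shift", "crossing", "spindle", "null")
  out <- vector("list", J)
  for (j in seq_len(J)) {
    prev <- 0.10 + 0.85 * ((j - 1) %% 7) / 6 + stats::runif(1, -0.02, 0.02)
    prev <- min(max(prev, 0.08), 0.95)
    heavy <- j %% 3 == 0
    if (heavy) {
      a <- stats::runif(1, 1.5, 3)
      scale <- stats::runif(1, 20, 60)
      q0 <- scale * ((1 - fine_grid)^(-1 / a) - 1) + 1
    } else {
      mu <- stats::runif(1, 2.5, 4)
      sdl <- stats::runif(1, 0.6, 1.1)
      q0 <- stats::qlnorm(fine_grid, meanlog = mu, sdlog = sdl)
    }
    spread <- stats::median(q0)
    type <- types[((j - 1) %% 4) + 1]
    delta <- 0.4 * spread
    beta_c <- switch(
      type,
      shift = rep(delta, length(fine_grid)),
      crossing = delta * 2 * (fine_grid - 0.5),
      spindle = delta * pmax(0, (fine_grid - 0.55) / 0.45)^2,
      null = rep(0, length(fine_grid))
    )
    gamma_c <- switch(type, shift = 0.4, crossing = 0, spindle = 0, null = 0)
    out[[j]] <- two_part_params(
      gamma_z = stats::qlogis(prev), gamma_c = gamma_c,
      beta_z = matrix(q0, ncol = 1), beta_c = beta_c,
      fine_grid = fine_grid, effect_type = type
    )
  }
  out
}
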