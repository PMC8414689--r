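# Shared fixture builders: everything is generated in code, nothing stored.

# A small deterministic count table.
make_table <- function(n = 6, J = 3, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n * J, lambda = 20) * rbinom(n * J, 1, 0.8), n, J)
  taxon_table(counts,
              sample_ids = paste0("s", seq_len(n)),
              taxon_ids = paste0("t", seq_len(J)))
}

# Zero-inflated null data: presence and positive part independent of the
# binary variable.
null_taxon <- function(n = 300, prevalence = 0.7, seed = 1) {
  set.seed(seed)
  C <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, prevalence) * rlnorm(n)
  list(y = y, design = zinq_design(C))
}

# Write a small counts + metadata TSV pair; returns the two paths.
write_fixture_files <- function(dir, seed = 5) {
  set.seed(seed)
  n <- 40
  counts <- matrix(rpois(n * 2, 30) * rbinom(n * 2, 1, 0.7), n, 2)
  counts[, 1] <- counts[, 1] + 1L  # keep library sizes positive
  ids <- paste0("s", seq_len(n))
  cpath <- file.path(dir, "counts.tsv")
  mpath <- file.path(dir, "meta.tsv")
  write.table(data.frame(sample_id = ids, taxonA = counts[, 1],
                         taxonB = counts[, 2]),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = ids, group = rbinom(n, 1, 0.5),
                         age = round(runif(n, 20, 60))),
              mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(counts = cpath, metadata = mpath)
}

# Brute-force quantile-regression oracle: enumerate all p-subsets of
# observations, fit exactly through them, return the minimum achieved loss.
brute_force_qr_loss <- function(X, y, tau) {
  m <- nrow(X)
  p <- ncol(X)
  best <- Inf
  for (idx in combn(m, p, simplify = FALSE)) {
    Xh <- X[idx, , drop = FALSE]
    if (abs(det(Xh)) < 1e-10) next
    b <- solve(Xh, y[idx])
    loss <- sum(qr_check_loss(y - as.vector(X %*% b), tau))
    best <- min(best, loss)
  }
  best
}

# Brute-force BH step-up.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
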