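#' Construct a normalized abundance table
#'
#' Wraps a normalized abundance matrix together with the name of the
#' normalization that produced it and a discreteness flag. The flag drives
#' downstream analysis: discrete tables (raw counts, rarefied counts) get the
#' tie-breaking uniform perturbation and the 3-point quantile grid by default.
#'
#' @param values Non-negative (or, for CLR, real) numeric matrix,
#'   samples x taxa.
#' @param method One of `"none"`, `"rarefaction"`, `"tss"`, `"css"`, `"clr"`.
#' @param discrete Logical: are the values integer counts?
#' @param sample_ids,taxon_ids Identifiers carried over from the source table.
#' @return An object of class `normalized_table`.
#' @export
normalized_table <- function(values, method = c("none", "rarefaction", "tss",
                                                "css", "clr"),
                             discrete, sample_ids = rownames(values),
                             taxon_ids = colnames(values)) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(values)))
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(
    list(values = values, method = method, discrete = isTRUE(discrete),
         sample_ids = as.character(sample_ids),
         taxon_ids = as.character(taxon_ids)),
    class = "normalized_table"
  )
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("normalized_table (%s%s): %d samples x %d taxa\n",
              x$method, if (x$discrete) ", discrete" else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Treat a raw count table as a (non-)normalized table
#'
#' @param table A [taxon_table()].
#' @return A `normalized_table` with `method = "none"`, `discrete = TRUE`.
#' @export
as_normalized <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  normalized_table(table$counts, method = "none", discrete = TRUE,
                   sample_ids = table$sample_ids, taxon_ids = table$taxon_ids)
}

# Multivariate hypergeometric draw: subsample `depth` reads without
# replacement from a vector of per-taxon counts, by sequential conditional
# hypergeometric draws.
rhyper_vec <- function(counts, depth) {
  J <- length(counts)
  out <- integer(J)
  remaining <- sum(counts)
  todraw <- depth
  for (j in seq_len(J)) {
    if (todraw == 0L) break
    if (j == J) {
      out[j] <- todraw
      break
    }
    x <- stats::rhyper(1, counts[j], remaining - counts[j], todraw)
    out[j] <- x
    todraw <- todraw - x
    remaining <- remaining - counts[j]
  }
  out
}

#' Rarefy a count table to a common depth
#'
#' Each sample is subsampled without replacement (a multivariate
#' hypergeometric draw over its reads) so that every row sums to exactly
#' `depth`. A taxon absent from a sample stays absent.
#'
#' @param table A [taxon_table()].
#' @param depth Target read depth; must not exceed any library size.
#' @param seed Integer seed governing the whole table.
#' @return A `normalized_table` with `method = "rarefaction"`,
#'   `discrete = TRUE`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "taxon_table"))
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive")
  too_small <- table$library_sizes < depth
  if (any(too_small)) {
    stop("depth ", depth, " exceeds library size of samples: ",
         paste(utils::head(table$sample_ids[too_small], 10), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  out <- t(apply(table$counts, 1, rhyper_vec, depth = depth))
  normalized_table(out, method = "rarefaction", discrete = TRUE,
                   sample_ids = table$sample_ids, taxon_ids = table$taxon_ids)
}

#' Average several independent rarefactions
#'
#' Rarefies the table `times` times independently and returns the elementwise
#' mean. Used to build a stable "starting" dataset for model fitting: the
#' averaging removes most of the single-draw subsampling noise while keeping
#' all rows at a common depth. Not a normalization for analysis proper.
#'
#' @inheritParams rarefy
#' @param times Number of independent rarefactions to average.
#' @return A `normalized_table` (`method = "rarefaction"`,
#'   `discrete = FALSE` unless `times == 1`).
#' @export
rarefy_average <- function(table, depth, times = 10, seed = NULL) {
  stopifnot(inherits(table, "taxon_table"))
  times <- as.integer(times)
  if (times < 1) stop("times must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0, nrow(table$counts), ncol(table$counts))
  for (b in seq_len(times)) {
    acc <- acc + rarefy(table, depth, seed = NULL)$values
  }
  normalized_table(acc / times, method = "rarefaction",
                   discrete = (times == 1L),
                   sample_ids = table$sample_ids, taxon_ids = table$taxon_ids)
}

#' Total sum scaling
#'
#' Divides each sample's counts by its library size, yielding relative
#' abundances that sum to one per sample.
#'
#' @param table A [taxon_table()].
#' @return A `normalized_table` with `method = "tss"`, `discrete = FALSE`.
#' @export
tss <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  if (any(table$library_sizes == 0)) {
    stop("zero library size for samples: ",
         paste(table$sample_ids[table$library_sizes == 0], collapse = ", "))
  }
  vals <- table$counts / table$library_sizes
  normalized_table(vals, method = "tss", discrete = FALSE,
                   sample_ids = table$sample_ids, taxon_ids = table$taxon_ids)
}

#' Cumulative sum scaling
#'
#' Per sample, the scaling factor is the sum of all counts at or below the
#' `quantile`-level empirical quantile of that sample's positive counts; the
#' counts are divided by this factor and multiplied by `scale`. The empirical
#' quantile is the order-statistic convention: the lowest positive value at
#' or above the nominal level (the `ceiling(level * n_positive)`-th order
#' statistic of the positive counts).
#'
#' @param table A [taxon_table()].
#' @param quantile Quantile level in (0,1) used for the cumulative cutoff.
#' @param scale Multiplier applied after division (a "per-`scale`-reads"
#'   unit).
#' @return A `normalized_table` with `method = "css"`, `discrete = FALSE`.
#' @export
css <- function(table, quantile = 0.5, scale = 1000) {
  stopifnot(inherits(table, "taxon_table"))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0,1)")
  if (scale <= 0) stop("scale must be positive")
  vals <- table$counts
  for (i in seq_len(nrow(vals))) {
    pos <- sort(vals[i, vals[i, ] > 0])
    if (!length(pos)) {
      stop("sample '", table$sample_ids[i], "' has no positive counts")
    }
    k <- max(1L, ceiling(quantile * length(pos)))
    q_i <- pos[k]
    s_i <- sum(vals[i, vals[i, ] <= q_i])
    if (s_i == 0) {
      stop("zero CSS scaling factor for sample '", table$sample_ids[i], "'")
    }
    vals[i, ] <- vals[i, ] / s_i * scale
  }
  normalized_table(vals, method = "css", discrete = FALSE,
                   sample_ids = table$sample_ids, taxon_ids = table$taxon_ids)
}

#' Centered log-ratio transformation
#'
#' Per sample, `log(y_j) - mean_k log(y_k)`. Zeros are either an error
#' (`zero_policy = "error"`) or handled by adding a pseudocount to every
#' entry before taking logs (`zero_policy = "pseudocount"`). With
#' `fill_back = TRUE`, entries that were zero in the raw counts are reset to
#' zero after the transformation, restoring the zero inflation so that the
#' presence/absence part of downstream testing still operates; the resulting
#' rows then no longer sum to zero.
#'
#' @param table A [taxon_table()].
#' @param zero_policy `"error"` or `"pseudocount"`.
#' @param pseudocount Positive value added to all counts under the
#'   pseudocount policy.
#' @param fill_back Logical; reset original zeros to 0 after transforming.
#' @return A `normalized_table` with `method = "clr"`, `discrete = FALSE`.
#' @export
clr <- function(table, zero_policy = c("error", "pseudocount"),
                pseudocount = 0.5, fill_back = FALSE) {
  stopifnot(inherits(table, "taxon_table"))
  zero_policy <- match.arg(zero_policy)
  y <- table$counts
  if (any(y == 0)) {
    if (zero_policy == "error") {
      stop("zero counts present; use zero_policy = 'pseudocount'")
    }
    if (pseudocount <= 0) stop("pseudocount must be positive")
    y <- y + pseudocount
  }
  logs <- log(y)
  vals <- logs - rowMeans(logs)
  if (fill_back) vals[table$counts == 0] <- 0
  normalized_table(vals, method = "clr", discrete = FALSE,
                   sample_ids = table$sample_ids, taxon_ids = table$taxon_ids)
}
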