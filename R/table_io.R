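#' Construct a taxon count table
#'
#' A taxon table holds the raw sequencing counts of `J` taxa in `n` samples,
#' oriented samples-in-rows. Library sizes (per-sample total read counts) are
#' computed on construction and kept consistent with the count matrix.
#'
#' @param counts Non-negative integer matrix, `n` samples by `J` taxa.
#' @param sample_ids Character vector of `n` unique sample identifiers.
#'   Defaults to the row names of `counts`.
#' @param taxon_ids Character vector of `J` unique taxon identifiers.
#'   Defaults to the column names of `counts`.
#' @return An object of class `taxon_table`: a list with elements `counts`
#'   (integer matrix with dimnames), `sample_ids`, `taxon_ids` and
#'   `library_sizes` (row sums).
#' @export
taxon_table <- function(counts, sample_ids = rownames(counts),
                        taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be a numeric matrix")
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("missing count at row %d, column %d", bad[1], bad[2]))
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d, column %d", bad[1], bad[2]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at row %d, column %d", bad[1], bad[2]))
  }
  counts <- round(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(counts)) {
    stop("length of sample_ids does not match the number of rows")
  }
  if (length(taxon_ids) != ncol(counts)) {
    stop("length of taxon_ids does not match the number of columns")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(taxon_ids)) {
    stop("duplicate taxon IDs: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  }
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(
    list(counts = counts, sample_ids = sample_ids, taxon_ids = taxon_ids,
         library_sizes = rowSums(counts)),
    class = "taxon_table"
  )
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d samples x %d taxa\n",
              length(x$sample_ids), length(x$taxon_ids)))
  cat(sprintf("library sizes: %s .. %s (median %s)\n",
              min(x$library_sizes), max(x$library_sizes),
              stats::median(x$library_sizes)))
  invisible(x)
}

#' Construct a regression design
#'
#' Packages the clinical variable of interest `C` together with the covariate
#' matrix `Z` (always including an intercept as its first column). Both parts
#' must be complete: the test has no missing-data theory, so missing values
#' are rejected rather than imputed.
#'
#' @param variable Length-`n` numeric vector: the variable of interest
#'   (binary 0/1 or quantitative).
#' @param covariates Optional `n` by `p-1` numeric matrix (or data frame) of
#'   additional covariates, excluding the intercept. `NULL` for an
#'   intercept-only design.
#' @param variable_name Name used for the variable in outputs.
#' @param sample_ids Optional sample identifiers (needed for alignment with a
#'   count table).
#' @return An object of class `zinq_design`: list with `variable`,
#'   `covariates` (`n` by `p` matrix whose first column is the intercept),
#'   `variable_name`, `sample_ids`.
#' @export
zinq_design <- function(variable, covariates = NULL, variable_name = "C",
                        sample_ids = NULL) {
  variable <- as.numeric(variable)
  n <- length(variable)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) stop("covariates and variable have different lengths")
    if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
    if (!all(Z[, 1] == 1)) {
      Z <- cbind("(Intercept)" = 1, Z)
    }
  }
  if (anyNA(variable) || anyNA(Z)) {
    bad <- union(which(is.na(variable)), which(rowSums(is.na(Z)) > 0))
    stop("missing values in design for samples: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (qr(Z)$rank < ncol(Z)) {
    stop("covariate matrix Z is rank deficient")
  }
  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != n) stop("sample_ids has wrong length")
    if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in design")
  }
  structure(
    list(variable = variable, covariates = Z, variable_name = variable_name,
         sample_ids = sample_ids),
    class = "zinq_design"
  )
}

#' @export
print.zinq_design <- function(x, ...) {
  cat(sprintf("zinq_design: n = %d, variable '%s', %d covariate column(s) incl. intercept\n",
              length(x$variable), x$variable_name, ncol(x$covariates)))
  invisible(x)
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a delimited taxon count table
#'
#' Reads a TSV/CSV count matrix with a header row and a first column of IDs.
#' The delimiter is auto-detected (tab, then comma) unless given explicitly.
#' Counts must be non-negative integers; missing-value tokens (`""`, `"NA"`)
#' are hard errors.
#'
#' @param path Path to the delimited file.
#' @param orientation `"samples_in_rows"` (default) if rows are samples, or
#'   `"taxa_in_rows"` if the file stores taxa in rows; the returned table is
#'   always samples-in-rows.
#' @param delim Optional explicit field delimiter.
#' @return A [taxon_table()].
#' @export
read_count_table <- function(path,
                             orientation = c("samples_in_rows", "taxa_in_rows"),
                             delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (anyNA(col)) {
      i <- which(is.na(col))[1]
      stop(sprintf("missing or empty cell at row '%s', column '%s'",
                   ids[i], colnames(body)[j]))
    }
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      i <- which(is.na(num))[1]
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   col[i], ids[i], colnames(body)[j]))
    }
    if (any(col < 0)) {
      i <- which(col < 0)[1]
      stop(sprintf("negative cell '%s' at row '%s', column '%s'",
                   col[i], ids[i], colnames(body)[j]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "taxa_in_rows") m <- t(m)
  taxon_table(m)
}

#' Read a sample metadata table into a design
#'
#' Reads TSV/CSV metadata (one row per sample, first column sample IDs),
#' extracts the variable of interest and the named covariates, and builds the
#' design matrix. Character/factor covariates are reference-coded against the
#' lexicographically first level so design matrices are deterministic.
#'
#' @param path Path to the delimited metadata file.
#' @param variable_name Name of the column holding the variable of interest.
#' @param covariate_names Character vector of covariate column names (may be
#'   empty for an unadjusted analysis).
#' @param delim Optional explicit field delimiter.
#' @return A [zinq_design()] with intercept prepended to the covariates.
#' @export
read_metadata <- function(path, variable_name, covariate_names = character(),
                          delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  ids <- as.character(df[[1]])
  need <- c(variable_name, covariate_names)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) {
    stop("metadata columns not found: ", paste(missing_cols, collapse = ", "))
  }
  sub <- df[, need, drop = FALSE]
  na_rows <- which(rowSums(is.na(sub)) > 0)
  if (length(na_rows)) {
    stop("missing metadata values for samples: ",
         paste(utils::head(ids[na_rows], 10), collapse = ", "))
  }
  variable <- sub[[variable_name]]
  if (!is.numeric(variable)) {
    stop(sprintf("variable column '%s' must be numeric (code binary variables 0/1)",
                 variable_name))
  }
  Z <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in covariate_names) {
    col <- sub[[nm]]
    if (is.numeric(col)) {
      Z <- cbind(Z, stats::setNames(data.frame(col), nm))
    } else {
      lev <- sort(unique(as.character(col)))  # reference = first level
      if (length(lev) < 2) {
        stop(sprintf("categorical covariate '%s' has a single level", nm))
      }
      for (l in lev[-1]) {
        ind <- as.numeric(col == l)
        Z <- cbind(Z, stats::setNames(data.frame(ind), paste0(nm, l)))
      }
    }
  }
  zinq_design(variable, as.matrix(Z), variable_name = variable_name,
              sample_ids = ids)
}

#' Align a count table and a design on shared samples
#'
#' Restricts both objects to the intersection of their sample IDs, in the
#' order the IDs appear in the count table, and reports how many samples were
#' dropped from each side.
#'
#' @param table A [taxon_table()].
#' @param design A [zinq_design()] carrying sample IDs.
#' @return List with `table`, `design`, and `dropped` (named counts of
#'   samples dropped from each input).
#' @export
align_samples <- function(table, design) {
  stopifnot(inherits(table, "taxon_table"), inherits(design, "zinq_design"))
  if (is.null(design$sample_ids)) {
    stop("design carries no sample IDs; cannot align")
  }
  common <- intersect(table$sample_ids, design$sample_ids)
  if (!length(common)) stop("no overlapping sample IDs between table and design")
  ti <- match(common, table$sample_ids)
  di <- match(common, design$sample_ids)
  out_table <- taxon_table(table$counts[ti, , drop = FALSE],
                           sample_ids = common, taxon_ids = table$taxon_ids)
  out_design <- zinq_design(design$variable[di],
                            design$covariates[di, , drop = FALSE],
                            variable_name = design$variable_name,
                            sample_ids = common)
  list(table = out_table, design = out_design,
       dropped = c(table = length(table$sample_ids) - length(common),
                   design = length(design$sample_ids) - length(common)))
}

#' Convert a list of per-taxon results to a data frame
#'
#' One row per taxon with the zero proportion, the logistic and per-quantile
#' p-values (union of all grids used, NA where a level was not tested), the
#' combined MinP/Cauchy p-values, BH-adjusted Cauchy p-values, and flags.
#'
#' @param results List of `zinq_result` objects (see [zinq_test()]).
#' @return A data frame with a deterministic column order.
#' @export
results_to_data_frame <- function(results) {
  if (!length(results)) stop("empty results list")
  all_taus <- sort(unique(unlist(lapply(results, function(r) r$taus))))
  tau_cols <- if (length(all_taus)) paste0("p_tau_", format(all_taus)) else character()
  rows <- lapply(results, function(r) {
    ptau <- rep(NA_real_, length(all_taus))
    if (length(r$taus)) {
      ptau[match(r$taus, all_taus)] <- r$p_quantile
    }
    row <- data.frame(taxon_id = r$taxon_id, n = r$n, n_nonzero = r$m,
                      r_hat = r$r_hat, p_logistic = r$p_logistic,
                      stringsAsFactors = FALSE)
    for (k in seq_along(all_taus)) row[[tau_cols[k]]] <- ptau[k]
    row$p_minp <- r$p_minp
    row$p_cauchy <- r$p_cauchy
    row$flags <- if (length(r$flags)) paste(r$flags, collapse = ";") else ""
    row
  })
  df <- do.call(rbind, rows)
  df$p_bh <- adjust_bh(df$p_cauchy)
  rownames(df) <- NULL
  df
}

#' Write per-taxon test results to a TSV file
#'
#' @param results List of `zinq_result` objects or a data frame from
#'   [results_to_data_frame()].
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_results <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_to_data_frame(results)
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write results to '", path, "': ",
                             conditionMessage(e)),
    warning = function(w) stop("cannot write results to '", path, "': ",
                               conditionMessage(w))
  )
  invisible(df)
}
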