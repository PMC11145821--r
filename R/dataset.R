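# Container for one analysis-ready dataset: binary exposure X, continuous
# outcome Y, n x p mediator matrix M, n x q confounder matrix C.

#' Assemble a mediation dataset
#'
#' Bundles the exposure, outcome, mediator matrix and confounder matrix
#' with aligned sample and mediator identifiers, after validating that the
#' pieces are mutually consistent and free of missing values.
#'
#' @param X length-n binary (0/1) exposure.
#' @param Y length-n continuous outcome.
#' @param M `n x p` numeric mediator matrix (samples in rows).
#' @param C `n x q` numeric confounder matrix.
#' @param sample_ids,mediator_ids optional identifier vectors; defaults use
#'   row/column names or `S1..Sn` / `M1..Mp`.
#' @param truth optional truth tibble (see [sim_truth()]) for simulated data.
#' @param validate_exposure require both exposure groups to be non-empty
#'   (`TRUE` for analysis entry points).
#' @return an object of class `mediation_dataset`.
#' @export
mediation_dataset <- function(X, Y, M, C, sample_ids = NULL,
                              mediator_ids = NULL, truth = NULL,
                              validate_exposure = TRUE) {
  M <- as.matrix(M); C <- as.matrix(C)
  n <- length(X)
  if (length(Y) != n || nrow(M) != n || nrow(C) != n) {
    abort(sprintf(
      "inconsistent dimensions: length(X) = %d, length(Y) = %d, nrow(M) = %d, nrow(C) = %d",
      n, length(Y), nrow(M), nrow(C)))
  }
  if (anyNA(X) || anyNA(Y) || anyNA(M) || anyNA(C)) {
    abort("mediation_dataset does not accept missing values; drop or impute first")
  }
  assert_binary(X, "X", require_both = validate_exposure)
  sample_ids <- sample_ids %||% rownames(M) %||% paste0("S", seq_len(n))
  mediator_ids <- mediator_ids %||% colnames(M) %||% paste0("M", seq_len(ncol(M)))
  colnames(M) <- mediator_ids
  if (is.null(colnames(C))) colnames(C) <- paste0("C", seq_len(ncol(C)))
  structure(list(
    X = as.numeric(X), Y = as.numeric(Y), M = M, C = C,
    sample_ids = as.character(sample_ids),
    mediator_ids = as.character(mediator_ids),
    truth = truth
  ), class = "mediation_dataset")
}

#' @export
print.mediation_dataset <- function(x, ...) {
  cat(sprintf(
    "<mediation_dataset> %d samples, %d mediators, %d confounders\n",
    length(x$X), ncol(x$M), ncol(x$C)))
  cat(sprintf("  exposed: %d / %d\n", sum(x$X == 1), length(x$X)))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: %d true mediators\n", sum(x$truth$true_mediator)))
  }
  invisible(x)
}

#' @export
dim.mediation_dataset <- function(x) c(length(x$X), ncol(x$M))

#' Flatten a mediation dataset to a tibble
#'
#' One row per sample with columns `sample_id`, `X`, `Y`, the confounders
#' and the mediators — the shape written by the `simulate` command line.
#'
#' @param x a [mediation_dataset()].
#' @param ... unused.
#' @return a tibble with `n` rows.
#' @export
as_tibble.mediation_dataset <- function(x, ...) {
  bind_cols_unique <- cbind(
    data.frame(sample_id = x$sample_ids, X = x$X, Y = x$Y),
    as.data.frame(x$C), as.data.frame(x$M))
  as_tibble(bind_cols_unique)
}

#' Read a mediation dataset from delimited files
#'
#' Reads a phenotype table (one row per sample: id, exposure, outcome,
#' confounders) and a sample-by-mediator matrix, inner-joins them on the
#' id column, drops rows with missing values in the used columns (with a
#' message), and validates the exposure coding.
#'
#' @param pheno_path delimited file with header; must contain `id_col`,
#'   `exposure`, `outcome` and the `confounders` columns.
#' @param mediator_path delimited file with header; first column (or
#'   `id_col` if present) holds the sample id, remaining columns are
#'   mediators.
#' @param exposure,outcome column names in the phenotype file.
#' @param confounders character vector of confounder column names.
#' @param id_col sample-identifier column name (default `"id"`).
#' @param sep field separator (default tab).
#' @param max_id_mismatch error if more than this fraction of phenotype
#'   samples is missing from the mediator file (default 0.5).
#' @return a [mediation_dataset()].
#' @export
read_mediation_data <- function(pheno_path, mediator_path,
                                exposure, outcome, confounders,
                                id_col = "id", sep = "\t",
                                max_id_mismatch = 0.5) {
  ph <- utils::read.delim(pheno_path, sep = sep, check.names = FALSE)
  md <- utils::read.delim(mediator_path, sep = sep, check.names = FALSE)
  need <- c(id_col, exposure, outcome, confounders)
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols)) {
    abort(paste0("phenotype file lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  m_id <- if (id_col %in% names(md)) id_col else names(md)[1]
  ids <- intersect(as.character(ph[[id_col]]), as.character(md[[m_id]]))
  if (length(ids) < (1 - max_id_mismatch) * nrow(ph)) {
    abort(sprintf("only %d of %d phenotype samples found in the mediator file",
                  length(ids), nrow(ph)))
  }
  dropped_join <- nrow(ph) - length(ids)
  ph <- ph[match(ids, as.character(ph[[id_col]])), , drop = FALSE]
  md <- md[match(ids, as.character(md[[m_id]])), , drop = FALSE]
  M <- as.matrix(md[, setdiff(names(md), m_id), drop = FALSE])
  used <- cbind(ph[, c(exposure, outcome, confounders), drop = FALSE])
  keep <- complete.cases(used) & complete.cases(M)
  dropped_na <- sum(!keep)
  if (dropped_join + dropped_na > 0) {
    message(sprintf("dropped %d unmatched and %d incomplete samples; %d remain",
                    dropped_join, dropped_na, sum(keep)))
  }
  ph <- ph[keep, , drop = FALSE]; M <- M[keep, , drop = FALSE]
  X <- ph[[exposure]]
  if (!all(X %in% c(0, 1))) {
    lev <- sort(unique(X))
    if (length(lev) == 2) {
      X <- as.integer(X == lev[2])
      message(sprintf("exposure recoded: %s -> 0, %s -> 1", lev[1], lev[2]))
    } else {
      abort(paste0("exposure is not binary; observed levels: ",
                   paste(lev, collapse = ", ")))
    }
  }
  mediation_dataset(
    X = X, Y = ph[[outcome]],
    M = M, C = as.matrix(ph[, confounders, drop = FALSE]),
    sample_ids = as.character(ph[[id_col]]))
}
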