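#' Construct a cell-cell interaction matrix (CCIM) object
#'
#' Rows are ordered (sender, receiver) pairs of single cells, columns are
#' ligand-receptor features, entries are interaction scores.
#'
#' @param scores numeric matrix, cell pairs x features.
#' @param pairs data.frame with columns `sender_id`, `receiver_id`,
#'   `sender_type`, `receiver_type`, one row per cell pair.
#' @param features data.frame with columns `ligand`, `receptor`, one row per
#'   feature; ordered (ligand, receptor) tuples must be unique.
#' @param standardized logical; whether columns are z-scored.
#' @return an object of class `ccim`.
#' @export
ccim <- function(scores, pairs, features, standardized = FALSE) {
  scores <- as.matrix(scores)
  ccb_assert(is.numeric(scores), "ccb_validation_error", "scores must be numeric")
  ccb_assert(is.data.frame(pairs) &&
               all(c("sender_id", "receiver_id", "sender_type", "receiver_type") %in% names(pairs)),
             "ccb_validation_error",
             "pairs must have sender_id, receiver_id, sender_type, receiver_type")
  ccb_assert(is.data.frame(features) &&
               all(c("ligand", "receptor") %in% names(features)),
             "ccb_validation_error", "features must have ligand and receptor columns")
  ccb_assert(nrow(pairs) == nrow(scores), "ccb_format_error",
             "pair metadata rows (%d) != score rows (%d)", nrow(pairs), nrow(scores))
  ccb_assert(nrow(features) == ncol(scores), "ccb_format_error",
             "feature metadata rows (%d) != score columns (%d)", nrow(features), ncol(scores))
  ccb_assert(!anyDuplicated(paste(features$ligand, features$receptor, sep = "\r")),
             "ccb_validation_error", "duplicated ligand-receptor features")
  colnames(scores) <- feature_names(features)
  rownames(scores) <- NULL
  rownames(pairs) <- NULL
  rownames(features) <- NULL
  structure(list(scores = scores, pairs = pairs, features = features,
                 standardized = isTRUE(standardized)),
            class = "ccim")
}

feature_names <- function(features) paste(features$ligand, features$receptor, sep = "_")

#' @export
print.ccim <- function(x, ...) {
  cat(sprintf("ccim: %d cell pairs x %d ligand-receptor features (%s)\n",
              nrow(x$scores), ncol(x$scores),
              if (x$standardized) "standardized" else "raw scores"))
  invisible(x)
}

#' @export
dim.ccim <- function(x) dim(x$scores)

#' Build a CCIM from expression data and a ligand-receptor database
#'
#' For every ordered (sender, receiver) pair of cells and every retained
#' ligand-receptor feature k, the interaction score is
#' `expr[sender, ligand_k] * expr[receiver, receptor_k]` (the single-cell
#' convention popularized by NICHES-style connectomics).  Pairs are directed:
#' (A,B) and (B,A) are distinct rows.  Database entries whose ligand or
#' receptor gene is absent from the expression matrix are dropped with a
#' warning.
#'
#' @param expr an [expression_matrix()].
#' @param db an `lr_database`.
#' @param include_self_pairs keep (cell, cell) self pairs? Default `TRUE`.
#' @param senders,receivers optional character vectors of cell ids restricting
#'   the sender / receiver sets (defaults: all cells).
#' @return a raw (unstandardized) [ccim()].
#' @export
build_ccim <- function(expr, db, include_self_pairs = TRUE,
                       senders = NULL, receivers = NULL) {
  ccb_assert(inherits(expr, "expression_matrix"), "ccb_validation_error",
             "expr must be an expression_matrix")
  ccb_assert(nrow(db) > 0, "ccb_empty_feature_space_error",
             "ligand-receptor database is empty")
  genes <- colnames(expr$values)
  keep <- db$ligand %in% genes & db$receptor %in% genes
  if (!all(keep)) {
    warning(sprintf("dropping %d ligand-receptor pair(s) with genes absent from the expression matrix",
                    sum(!keep)))
  }
  ccb_assert(any(keep), "ccb_empty_feature_space_error",
             "no ligand-receptor pair has both genes in the expression matrix")
  db <- db[keep, , drop = FALSE]

  cells <- rownames(expr$values)
  if (is.null(senders)) senders <- cells
  if (is.null(receivers)) receivers <- cells
  ccb_assert(all(senders %in% cells) && all(receivers %in% cells),
             "ccb_validation_error", "unknown cell id in senders/receivers")

  # sender-major enumeration of ordered pairs
  grid <- expand.grid(receiver = receivers, sender = senders,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("sender", "receiver")]
  if (!include_self_pairs) grid <- grid[grid$sender != grid$receiver, , drop = FALSE]
  ccb_assert(nrow(grid) > 0, "ccb_empty_pair_set_error", "no (sender, receiver) pairs retained")

  si <- match(grid$sender, cells)
  ri <- match(grid$receiver, cells)
  L <- expr$values[si, db$ligand, drop = FALSE]
  R <- expr$values[ri, db$receptor, drop = FALSE]
  scores <- L * R

  types <- expr$cell_types
  pairs <- data.frame(sender_id = grid$sender, receiver_id = grid$receiver,
                      sender_type = types[si], receiver_type = types[ri],
                      stringsAsFactors = FALSE)
  ccim(scores, pairs,
       data.frame(ligand = db$ligand, receptor = db$receptor,
                  stringsAsFactors = FALSE))
}

#' Filter a CCIM to its active features
#'
#' A feature is considered active when its fraction of nonzero scores is at
#' least `min_nonzero_fraction` and its variance is strictly positive.
#' Inactive columns are removed together with their metadata.
#'
#' @param x a raw (unstandardized) [ccim()].
#' @param min_nonzero_fraction required fraction of nonzero entries, in
#'   `[0, 1]`; default 0.05.
#' @return the filtered [ccim()].
#' @export
filter_active_features <- function(x, min_nonzero_fraction = 0.05) {
  ccb_assert(inherits(x, "ccim"), "ccb_validation_error", "x must be a ccim")
  ccb_assert(!x$standardized, "ccb_validation_error",
             "filter_active_features expects an unstandardized CCIM")
  ccb_assert(is.numeric(min_nonzero_fraction) &&
               min_nonzero_fraction >= 0 && min_nonzero_fraction <= 1,
             "ccb_validation_error", "min_nonzero_fraction must be in [0, 1]")
  nz_frac <- colMeans(x$scores != 0)
  v <- apply(x$scores, 2L, stats::var)
  keep <- nz_frac >= min_nonzero_fraction & v > 0
  ccb_assert(any(keep), "ccb_empty_feature_space_error",
             "all features removed by activity filter")
  ccim(x$scores[, keep, drop = FALSE], x$pairs,
       x$features[keep, , drop = FALSE], standardized = FALSE)
}

#' Standardize CCIM features
#'
#' Independently z-scores every column: subtract the column mean and divide by
#' its standard deviation.  The default uses the population SD (divisor `n`);
#' set `ddof = 1` for the sample SD.  Standardization is idempotent up to
#' floating-point error.
#'
#' @param x a [ccim()].
#' @param ddof delta degrees of freedom for the SD divisor `n - ddof`;
#'   default 0 (population SD).
#' @return the standardized [ccim()] with `standardized = TRUE`.
#' @export
standardize_features <- function(x, ddof = 0) {
  ccb_assert(inherits(x, "ccim"), "ccb_validation_error", "x must be a ccim")
  n <- nrow(x$scores)
  ccb_assert(n - ddof > 0, "ccb_validation_error", "too few rows for ddof = %g", ddof)
  mu <- colMeans(x$scores)
  centered <- sweep(x$scores, 2L, mu)
  sd_ <- sqrt(colSums(centered^2) / (n - ddof))
  if (any(sd_ == 0)) {
    bad <- feature_names(x$features)[which(sd_ == 0)[1L]]
    ccb_stop("ccb_constant_feature_error",
             "constant feature '%s'; run filter_active_features() first", bad)
  }
  ccim(sweep(centered, 2L, sd_, "/"), x$pairs, x$features, standardized = TRUE)
}

#' Write a CCIM to a directory
#'
#' Scores are written as `scores.csv` (dense) or `scores.mtx` (MatrixMarket
#' triplet), with sidecars `pairs.tsv` (sender_id, receiver_id, sender_type,
#' receiver_type), `features.tsv` (ligand, receptor) and a small `ccim.json`
#' manifest recording the format and the standardized flag.
#'
#' @param x a [ccim()] with at least one row.
#' @param dir output directory (created if missing).
#' @param format `"csv"` or `"mtx"`.
#' @return invisibly, `dir`.
#' @export
write_ccim <- function(x, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  ccb_assert(inherits(x, "ccim"), "ccb_validation_error", "x must be a ccim")
  ccb_assert(nrow(x$scores) > 0, "ccb_empty_pair_set_error",
             "refusing to write a CCIM with zero cell pairs")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "csv") {
    utils::write.table(x$scores, file.path(dir, "scores.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
  } else {
    write_mtx(x$scores, file.path(dir, "scores.mtx"))
  }
  utils::write.table(x$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$features, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(format = format, standardized = x$standardized,
                            n_pairs = nrow(x$scores), n_features = ncol(x$scores)),
                       file.path(dir, "ccim.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a CCIM written by [write_ccim()]
#'
#' @param dir directory containing `scores.csv`/`scores.mtx`, `pairs.tsv`,
#'   `features.tsv` and `ccim.json`.
#' @return a [ccim()].
#' @export
read_ccim <- function(dir) {
  meta_path <- file.path(dir, "ccim.json")
  ccb_assert(file.exists(meta_path), "ccb_io_error", "no ccim.json in %s", dir)
  meta <- jsonlite::read_json(meta_path)
  pairs <- utils::read.table(file.path(dir, "pairs.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character")
  features <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE,
                                colClasses = "character")
  scores <- if (identical(meta$format, "mtx")) {
    read_mtx_dense(file.path(dir, "scores.mtx"))
  } else {
    as.matrix(utils::read.table(file.path(dir, "scores.csv"), sep = ",",
                                header = TRUE, check.names = FALSE))
  }
  ccb_assert(nrow(scores) == meta$n_pairs && ncol(scores) == meta$n_features,
             "ccb_format_error", "score matrix does not match manifest dimensions")
  ccb_assert(nrow(pairs) == nrow(scores), "ccb_format_error",
             "pairs.tsv rows (%d) != score rows (%d)", nrow(pairs), nrow(scores))
  ccb_assert(nrow(features) == ncol(scores), "ccb_format_error",
             "features.tsv rows (%d) != score columns (%d)", nrow(features), ncol(scores))
  ccim(scores, pairs, features, standardized = isTRUE(meta$standardized))
}
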