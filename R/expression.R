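#' Construct an expression matrix object
#'
#' A light container for a cells x genes matrix of nonnegative expression
#' values with per-cell type labels and optional 2D spatial coordinates.
#' Row names are cell ids, column names are gene ids.
#'
#' @param values numeric matrix, cells in rows, genes in columns; must carry
#'   unique row and column names and contain no negative entries.
#' @param cell_types character vector of cell-type labels, one per cell.
#' @param spatial_coords optional numeric matrix of 2D coordinates per cell;
#'   carried through as metadata only.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_types = NULL, spatial_coords = NULL) {
  ccb_assert(is.matrix(values) && is.numeric(values),
             "ccb_validation_error", "values must be a numeric matrix")
  ccb_assert(!is.null(rownames(values)) && !is.null(colnames(values)),
             "ccb_validation_error", "values must have cell ids as rownames and gene ids as colnames")
  ccb_assert(!anyDuplicated(rownames(values)),
             "ccb_validation_error", "duplicate cell ids")
  ccb_assert(!anyDuplicated(colnames(values)),
             "ccb_validation_error", "duplicate gene ids")
  ccb_assert(all(is.finite(values)), "ccb_validation_error", "non-finite expression values")
  ccb_assert(all(values >= 0), "ccb_validation_error", "negative expression values")
  if (is.null(cell_types)) cell_types <- rep("unspecified", nrow(values))
  ccb_assert(length(cell_types) == nrow(values),
             "ccb_validation_error", "cell_types length (%d) != number of cells (%d)",
             length(cell_types), nrow(values))
  if (!is.null(spatial_coords)) {
    spatial_coords <- as.matrix(spatial_coords)
    ccb_assert(nrow(spatial_coords) == nrow(values) && ncol(spatial_coords) == 2L,
               "ccb_validation_error", "spatial_coords must be n_cells x 2")
  }
  structure(list(values = values,
                 cell_types = as.character(cell_types),
                 spatial_coords = spatial_coords),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes, %d cell types%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$cell_types)),
              if (is.null(x$spatial_coords)) "" else ", with spatial coordinates"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

read_delim_matrix <- function(path, sep) {
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

read_cell_types <- function(path, cell_ids) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ccb_assert(ncol(tab) >= 2L, "ccb_format_error",
             "cell-type table must have two columns (cell_id, cell_type)")
  idx <- match(cell_ids, tab[[1L]])
  ccb_assert(!anyNA(idx), "ccb_format_error",
             "cell-type table is missing %d cell id(s)", sum(is.na(idx)))
  as.character(tab[[2L]][idx])
}

#' Load an expression matrix from disk
#'
#' Reads cells x genes expression values from a dense delimited file (cells in
#' rows with an index column of cell ids, genes in a header row) or from a
#' MatrixMarket triplet file with `.rows` / `.cols` sidecar name files.
#'
#' @param path path to the matrix file.
#' @param format one of `"csv"`, `"tsv"`, `"mtx_triplet"`.
#' @param cell_types_path optional path to a two-column TSV (cell_id,
#'   cell_type); required for the MTX format, optional otherwise (cells are
#'   labelled "unspecified" when absent).
#' @return an [expression_matrix()] object; name order is preserved from file.
#' @export
load_expression <- function(path, format = c("csv", "tsv", "mtx_triplet"),
                            cell_types_path = NULL) {
  format <- match.arg(format)
  ccb_assert(file.exists(path), "ccb_io_error", "file not found: %s", path)
  if (format %in% c("csv", "tsv")) {
    values <- read_delim_matrix(path, if (format == "csv") "," else "\t")
  } else {
    rows_path <- paste0(path, ".rows")
    cols_path <- paste0(path, ".cols")
    ccb_assert(file.exists(rows_path) && file.exists(cols_path), "ccb_io_error",
               "mtx_triplet format requires %s and %s", rows_path, cols_path)
    ccb_assert(!is.null(cell_types_path), "ccb_validation_error",
               "mtx_triplet format requires a cell-type table")
    values <- read_mtx_dense(path)
    rownames(values) <- readLines(rows_path)
    colnames(values) <- readLines(cols_path)
  }
  cell_types <- if (!is.null(cell_types_path)) {
    ccb_assert(file.exists(cell_types_path), "ccb_io_error",
               "file not found: %s", cell_types_path)
    read_cell_types(cell_types_path, rownames(values))
  }
  expression_matrix(values, cell_types = cell_types)
}

#' Write an expression matrix to disk
#'
#' Inverse of [load_expression()]: writes the dense matrix with cell ids as
#' the index column and gene ids as the header, plus a cell-type sidecar TSV.
#'
#' @param expr an [expression_matrix()].
#' @param path output path for the matrix (CSV or TSV by `format`).
#' @param format `"csv"` or `"tsv"`.
#' @return invisibly, the paths written (matrix and cell-type table).
#' @export
write_expression <- function(expr, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(cell_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  ct_path <- paste0(path, ".cell_types.tsv")
  utils::write.table(
    data.frame(cell_id = rownames(expr$values), cell_type = expr$cell_types),
    ct_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = path, cell_types = ct_path))
}

# minimal MatrixMarket coordinate reader returning a dense base matrix;
# only the "matrix coordinate real general" flavour is supported.
read_mtx_dense <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  ccb_assert(length(lines) >= 1L, "ccb_format_error", "empty MTX file: %s", path)
  hdr <- scan(text = lines[1L], quiet = TRUE)
  ccb_assert(length(hdr) == 3L, "ccb_format_error", "malformed MTX size line in %s", path)
  n <- hdr[1L]; p <- hdr[2L]; nnz <- hdr[3L]
  out <- matrix(0, n, p)
  if (nnz > 0) {
    trip <- matrix(scan(text = lines[-1L], quiet = TRUE), ncol = 3L, byrow = TRUE)
    ccb_assert(nrow(trip) == nnz, "ccb_format_error",
               "MTX entry count mismatch in %s", path)
    out[cbind(trip[, 1L], trip[, 2L])] <- trip[, 3L]
  }
  out
}

write_mtx <- function(m, path) {
  nz <- which(m != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz)), con)
  if (nrow(nz) > 0) {
    writeLines(sprintf("%d %d %.17g", nz[, 1L], nz[, 2L], m[nz]), con)
  }
  invisible(path)
}

#' Load a ligand-receptor database
#'
#' Reads a TSV with (at least) columns `ligand` and `receptor` into an ordered,
#' de-duplicated list of ligand-receptor pairs.  Duplicated ordered pairs are
#' dropped with a warning.
#'
#' @param path path to the TSV file.
#' @return an object of class `lr_database`: a data.frame with character
#'   columns `ligand` and `receptor`.
#' @export
load_lr_database <- function(path) {
  ccb_assert(file.exists(path), "ccb_io_error", "file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ccb_assert(all(c("ligand", "receptor") %in% names(tab)), "ccb_format_error",
             "ligand-receptor TSV must have columns 'ligand' and 'receptor'")
  lr_database(tab$ligand, tab$receptor)
}

#' Construct a ligand-receptor database in memory
#'
#' @param ligand,receptor character vectors of equal length; empty gene names
#'   are rejected, duplicated ordered pairs dropped with a warning.
#' @return an `lr_database` data.frame with columns `ligand`, `receptor`.
#' @export
lr_database <- function(ligand, receptor) {
  ligand <- as.character(ligand); receptor <- as.character(receptor)
  ccb_assert(length(ligand) == length(receptor), "ccb_validation_error",
             "ligand and receptor vectors differ in length")
  ccb_assert(!any(!nzchar(ligand) | !nzchar(receptor) |
                    is.na(ligand) | is.na(receptor)),
             "ccb_validation_error", "empty or missing gene names in pair list")
  key <- paste(ligand, receptor, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicated ligand-receptor pair(s)", sum(dup)))
    ligand <- ligand[!dup]; receptor <- receptor[!dup]
  }
  structure(data.frame(ligand = ligand, receptor = receptor,
                       stringsAsFactors = FALSE),
            class = c("lr_database", "data.frame"))
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("lr_database: %d ligand-receptor pair(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10L))
  invisible(x)
}
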