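#' Expression dataset container
#'
#' A light container for a cells x genes expression matrix with up to two
#' layers: raw counts and a library-size-normalized layer. Matrices are held
#' as sparse \code{dgCMatrix} (cells in rows, genes in columns) with unique
#' cell and gene identifiers as dimnames.
#'
#' @param counts raw count matrix (cells x genes), or NULL when only a
#'   pre-normalized layer is available.
#' @param normalized normalized matrix of identical shape, or NULL.
#' @param gene_ids,cell_ids character vectors of unique identifiers; taken
#'   from dimnames when missing.
#' @return an object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(counts = NULL, normalized = NULL,
                               gene_ids = NULL, cell_ids = NULL) {
  if (is.null(counts) && is.null(normalized))
    stop("at least one of 'counts' or 'normalized' must be supplied")
  as_sparse <- function(m) {
    if (is.null(m)) return(NULL)
    m <- methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                             "dMatrix"), "generalMatrix"),
                     "CsparseMatrix")
    m
  }
  counts <- as_sparse(counts)
  normalized <- as_sparse(normalized)
  ref <- if (!is.null(counts)) counts else normalized
  if (is.null(gene_ids)) gene_ids <- colnames(ref)
  if (is.null(cell_ids)) cell_ids <- rownames(ref)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required (as dimnames or arguments)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  check_unique_ids(gene_ids, "gene")
  check_unique_ids(cell_ids, "cell")
  for (nm in c("counts", "normalized")) {
    m <- get(nm)
    if (is.null(m)) next
    if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids))
      stop(sprintf("%s matrix is %d x %d but %d cells and %d genes were named",
                   nm, nrow(m), ncol(m), length(cell_ids), length(gene_ids)))
    if (any(m@x < 0) || any(!is.finite(m@x)))
      stop(sprintf("%s matrix contains negative or non-finite entries", nm))
    dimnames(m) <- list(cell_ids, gene_ids)
    assign(nm, m)
  }
  structure(list(counts = counts, normalized = normalized,
                 gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_totals = NULL),
            class = "expression_dataset")
}

check_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate %s identifiers: %s", what,
                 paste(utils::head(dup, 10), collapse = ", ")))
  }
  invisible(ids)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d cells x %d genes (layer: %s)\n",
              length(x$cell_ids), length(x$gene_ids), layer_tag(x)))
  invisible(x)
}

#' Active layer tag of a dataset
#'
#' @param ds an \code{expression_dataset}.
#' @return \code{"normalized"} when a normalized layer is present, else
#'   \code{"raw_counts"}.
#' @export
layer_tag <- function(ds) {
  if (!is.null(ds$normalized)) "normalized" else "raw_counts"
}

#' Number of genes / cells
#' @param ds an \code{expression_dataset}.
#' @export
n_genes <- function(ds) length(ds$gene_ids)

#' @rdname n_genes
#' @export
n_cells <- function(ds) length(ds$cell_ids)

#' Extract a layer matrix
#'
#' @param ds an \code{expression_dataset}.
#' @param layer \code{"normalized"}, \code{"raw_counts"}, or \code{"auto"}
#'   (normalized when present, raw otherwise).
#' @return a \code{dgCMatrix}, cells x genes.
#' @export
get_layer <- function(ds, layer = c("auto", "normalized", "raw_counts")) {
  layer <- match.arg(layer)
  if (layer == "auto")
    return(if (!is.null(ds$normalized)) ds$normalized else ds$counts)
  m <- if (layer == "normalized") ds$normalized else ds$counts
  if (is.null(m)) stop(sprintf("dataset has no %s layer", layer))
  m
}

#' Read an expression matrix from disk
#'
#' Supports Matrix Market triplet files with one-column sidecar gene and cell
#' name files, and dense delimited text with a header row of gene names and a
#' first column of cell names (or the transpose, declared with
#' \code{transpose = TRUE}). Orientation is normalized to cells x genes.
#'
#' @param matrix_file path to the matrix (.mtx or delimited text).
#' @param genes_file,cells_file one-column name files (Matrix Market only).
#' @param format \code{"auto"} (by extension), \code{"mtx"} or \code{"dense"}.
#' @param transpose for dense input: rows are genes rather than cells. For
#'   Matrix Market input, orientation is resolved against the name-file
#'   lengths; set \code{transpose = TRUE} if a square matrix is stored
#'   genes x cells.
#' @param layer layer tag of the stored values, \code{"raw_counts"} by default.
#' @param sep field separator for dense input (autodetected by
#'   \code{data.table::fread} when NULL).
#' @return an \code{expression_dataset}.
#' @export
read_expression_matrix <- function(matrix_file, genes_file = NULL,
                                   cells_file = NULL,
                                   format = c("auto", "mtx", "dense"),
                                   transpose = FALSE,
                                   layer = c("raw_counts", "normalized"),
                                   sep = NULL) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (!file.exists(matrix_file)) stop("matrix file not found: ", matrix_file)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", matrix_file, ignore.case = TRUE)) "mtx" else "dense"
  if (format == "mtx") {
    if (is.null(genes_file) || is.null(cells_file))
      stop("Matrix Market input requires gene and cell name files")
    m <- methods::as(Matrix::readMM(matrix_file), "CsparseMatrix")
    genes <- trimws(readLines(genes_file))
    cells <- trimws(readLines(cells_file))
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    fits_cg <- nrow(m) == length(cells) && ncol(m) == length(genes)
    fits_gc <- nrow(m) == length(genes) && ncol(m) == length(cells)
    if (fits_cg && fits_gc) {            # square: honour the flag
      if (transpose) m <- Matrix::t(m)
    } else if (fits_cg) {
      # stored cells x genes already
    } else if (fits_gc) {
      m <- Matrix::t(m)
    } else {
      stop(sprintf(
        "matrix is %d x %d; name files list %d cells and %d genes (no orientation fits)",
        nrow(m), ncol(m), length(cells), length(genes)))
    }
    mat <- m
  } else {
    dt <- data.table::fread(matrix_file, header = TRUE,
                            sep = if (is.null(sep)) "auto" else sep,
                            data.table = FALSE)
    row_labels <- trimws(as.character(dt[[1]]))
    mat <- as.matrix(dt[, -1, drop = FALSE])
    rownames(mat) <- row_labels
    colnames(mat) <- trimws(colnames(dt)[-1])
    if (transpose) mat <- t(mat)
    cells <- rownames(mat)
    genes <- colnames(mat)
  }
  ds <- if (layer == "raw_counts")
    expression_dataset(counts = mat, gene_ids = genes, cell_ids = cells)
  else
    expression_dataset(normalized = mat, gene_ids = genes, cell_ids = cells)
  ds
}

#' Write an expression dataset to disk
#'
#' @param ds an \code{expression_dataset}.
#' @param dir output directory (created if absent).
#' @param format \code{"mtx"} (matrix.mtx + genes.txt + cells.txt) or
#'   \code{"dense"} (matrix.csv with cell rows and gene columns).
#' @param layer which layer to write.
#' @return the paths written, invisibly.
#' @export
write_expression_dataset <- function(ds, dir, format = c("mtx", "dense"),
                                     layer = c("auto", "raw_counts", "normalized")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- get_layer(ds, layer)
  if (format == "mtx") {
    paths <- file.path(dir, c("matrix.mtx", "genes.txt", "cells.txt"))
    Matrix::writeMM(m, paths[1])
    writeLines(ds$gene_ids, paths[2])
    writeLines(ds$cell_ids, paths[3])
  } else {
    paths <- file.path(dir, "matrix.csv")
    out <- data.frame(cell_id = ds$cell_ids, as.matrix(m),
                      check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(out, paths)
  }
  invisible(paths)
}

#' Library-size normalization (counts per `scale`)
#'
#' Rescales each cell so its entries sum to \code{scale} (counts-per-10k by
#' default). Cells with zero total count are dropped with a warning. The raw
#' layer and per-cell totals are retained, so the transform is exactly
#' invertible.
#'
#' @param ds an \code{expression_dataset} carrying raw counts only.
#' @param scale target per-cell total, default \code{1e4}.
#' @return the dataset with a normalized layer added.
#' @export
normalize_library_size <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.null(ds$normalized))
    stop("dataset already carries a normalized layer (double normalization)")
  if (scale <= 0) stop("'scale' must be positive")
  totals <- Matrix::rowSums(ds$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("dropping %d cell(s) with zero total count", sum(zero)))
    ds <- subset_dataset(ds, cells = ds$cell_ids[!zero])
    totals <- totals[!zero]
  }
  norm <- Matrix::Diagonal(x = scale / totals) %*% ds$counts
  norm <- methods::as(norm, "CsparseMatrix")
  dimnames(norm) <- list(ds$cell_ids, ds$gene_ids)
  ds$normalized <- norm
  ds$cell_totals <- stats::setNames(totals, ds$cell_ids)
  ds
}

#' Subset a dataset by cells and/or genes
#'
#' @param ds an \code{expression_dataset}.
#' @param cells,genes identifiers to keep (NULL keeps all); order preserved as
#'   in the dataset, not as in the argument.
#' @export
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  keep_c <- if (is.null(cells)) ds$cell_ids else ds$cell_ids[ds$cell_ids %in% cells]
  keep_g <- if (is.null(genes)) ds$gene_ids else ds$gene_ids[ds$gene_ids %in% genes]
  if (!length(keep_c)) stop("cell subset is empty")
  if (!length(keep_g)) stop("gene subset is empty")
  out <- ds
  for (nm in c("counts", "normalized"))
    if (!is.null(ds[[nm]])) out[[nm]] <- ds[[nm]][keep_c, keep_g, drop = FALSE]
  out$cell_ids <- keep_c
  out$gene_ids <- keep_g
  if (!is.null(ds$cell_totals)) out$cell_totals <- ds$cell_totals[keep_c]
  out
}

#' Cell identity map
#'
#' Assigns each cell to an identity group (tissue, cell class, brain region or
#' neuronal subtype). The analysis level controls the upregulation criterion
#' downstream: levels 1 and 2 require Log2FC >= 1, level 3 only Log2FC > 0.
#'
#' @param assignments named character vector, cell_id -> group label.
#' @param level one of \code{"level1_multiorgan"}, \code{"level2_wholebrain"},
#'   \code{"level3_region"} (or 1, 2, 3).
#' @export
cell_identity_map <- function(assignments, level = "level1_multiorgan") {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("'assignments' must be named by cell identifier")
  check_unique_ids(names(assignments), "cell")
  structure(list(assignments = stats::setNames(trimws(as.character(assignments)),
                                               trimws(names(assignments))),
                 level = as_level(level)),
            class = "cell_identity_map")
}

#' @export
print.cell_identity_map <- function(x, ...) {
  cat(sprintf("cell_identity_map: %d cells, %d groups, %s\n",
              length(x$assignments), length(unique(x$assignments)), x$level))
  invisible(x)
}

#' Normalize an analysis-level designation
#' @param level 1, 2, 3 or the long level tags.
#' @return the canonical level tag.
#' @export
as_level <- function(level) {
  tags <- c("level1_multiorgan", "level2_wholebrain", "level3_region")
  if (is.numeric(level)) {
    stopifnot(level %in% 1:3)
    return(tags[level])
  }
  match.arg(as.character(level), tags)
}

#' Attach a cell-identity table to a dataset
#'
#' Reads a two-column delimited file (cell_id, label), trims whitespace, and
#' restricts the map to cells present in the dataset. Cells missing from the
#' file are excluded from all downstream analysis; their count is reported.
#'
#' @param ds an \code{expression_dataset}.
#' @param table path to a two-column delimited file, or a data.frame.
#' @param level analysis level tag (see \code{\link{cell_identity_map}}).
#' @return a \code{cell_identity_map} covering the intersection.
#' @export
attach_identities <- function(ds, table, level = "level1_multiorgan") {
  df <- if (is.character(table))
    data.table::fread(table, header = TRUE, data.table = FALSE)
  else as.data.frame(table)
  if (ncol(df) < 2) stop("identity table must have two columns: cell_id, label")
  ids <- trimws(as.character(df[[1]]))
  labels <- trimws(as.character(df[[2]]))
  keep <- ids %in% ds$cell_ids
  if (!any(keep)) stop("no cell identifier in the identity table matches the dataset")
  excluded <- sum(!(ds$cell_ids %in% ids))
  if (excluded > 0)
    message(sprintf("%d dataset cell(s) absent from the identity table; excluded downstream",
                    excluded))
  cell_identity_map(stats::setNames(labels[keep], ids[keep]), level = level)
}
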