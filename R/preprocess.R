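#' Gene-presence filter
#'
#' Removes genes expressed (raw count > 0) in fewer than \code{min_cells}
#' cells. This is the consistent filter applied to every dataset before any
#' enrichment analysis; the retained gene count is the ORA universe size.
#'
#' @param ds an \code{expression_dataset}.
#' @param min_cells minimum number of cells with nonzero expression, default 20.
#' @return the filtered dataset, with attribute \code{"n_retained"}.
#' @export
filter_genes_min_cells <- function(ds, min_cells = 20) {
  stopifnot(inherits(ds, "expression_dataset"), min_cells >= 1)
  if (n_genes(ds) < 1) stop("dataset has no genes")
  m <- if (!is.null(ds$counts)) ds$counts else ds$normalized
  n_expr <- Matrix::colSums(m > 0)
  keep <- ds$gene_ids[n_expr >= min_cells]
  if (!length(keep))
    stop(sprintf("no gene is expressed in >= %d cells", min_cells))
  out <- subset_dataset(ds, genes = keep)
  attr(out, "n_retained") <- length(keep)
  out
}

#' Subset cells by identity label and re-apply the gene filter
#'
#' Used to pass from a global-cell analysis to a restricted one (e.g. neurons
#' only): cells are restricted to \code{keep_labels}, then the gene-presence
#' filter is re-applied on the subset, so the gene universe is recomputed at
#' each analysis level. Surviving identity groups with fewer than 2 cells are
#' dropped with a warning (a group-vs-rest test is undefined for them).
#'
#' @param ds an \code{expression_dataset}.
#' @param ids a \code{cell_identity_map}.
#' @param keep_labels labels to retain.
#' @param min_cells gene filter threshold, default 20.
#' @param level analysis level tag for the returned map (defaults to the level
#'   of \code{ids}).
#' @return list with elements \code{dataset} and \code{identities}.
#' @export
subset_cells_and_refilter <- function(ds, ids, keep_labels, min_cells = 20,
                                      level = NULL) {
  stopifnot(inherits(ids, "cell_identity_map"))
  keep_labels <- as.character(keep_labels)
  if (!length(keep_labels)) stop("'keep_labels' must be nonempty")
  missing_lab <- setdiff(keep_labels, unique(ids$assignments))
  if (length(missing_lab))
    stop("label(s) not present in the identity map: ",
         paste(missing_lab, collapse = ", "))
  asg <- ids$assignments[ids$assignments %in% keep_labels]
  asg <- asg[names(asg) %in% ds$cell_ids]
  sizes <- table(asg)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 cells after subsetting: ",
            paste(small, collapse = ", "))
    asg <- asg[!(asg %in% small)]
  }
  if (!length(asg)) stop("no cells remain after subsetting")
  sub <- subset_dataset(ds, cells = names(asg))
  sub <- filter_genes_min_cells(sub, min_cells = min_cells)
  list(dataset = sub,
       identities = cell_identity_map(asg,
                                      level = if (is.null(level)) ids$level else level))
}
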