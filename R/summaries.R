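#' Per-group counts of tagged genes with their expression maximum there
#'
#' For each tagged gene passing the filter, computes the mean normalized
#' expression per identity group and assigns the gene to its argmax group;
#' ties go to the lexicographically first group label (reported via the
#' \code{"ties"} attribute). Counts are conserved: they sum to the number of
#' tagged genes present.
#'
#' @param ds_norm dataset with a normalized layer.
#' @param ids a \code{cell_identity_map} with >= 2 groups.
#' @param genes a \code{tagged_gene_list}.
#' @return named integer vector of per-group counts (all groups, zeros kept).
#' @export
top_expression_counts <- function(ds_norm, ids, genes) {
  gm <- group_means(ds_norm, ids)
  if (nrow(gm) < 2) stop("need >= 2 identity groups")
  tagged <- intersect(genes$gene_id, colnames(gm))
  if (!length(tagged)) stop("no tagged gene present in the dataset")
  sub <- gm[, tagged, drop = FALSE]
  top <- apply(sub, 2, function(v) rownames(gm)[which.max(v)])  # first max = lexicographic tie rule
  n_tied <- sum(apply(sub, 2, function(v) sum(v == max(v)) > 1))
  counts <- table(factor(top, levels = rownames(gm)))
  out <- stats::setNames(as.integer(counts), rownames(gm))
  attr(out, "ties") <- n_tied
  out
}

# mean normalized expression per group (groups x genes), group rows sorted
group_means <- function(ds_norm, ids) {
  X <- get_layer(ds_norm, "normalized")
  cells <- intersect(ds_norm$cell_ids, names(ids$assignments))
  X <- X[cells, , drop = FALSE]
  f <- factor(ids$assignments[cells])
  memb <- Matrix::sparseMatrix(i = seq_along(cells), j = as.integer(f), x = 1,
                               dims = c(length(cells), nlevels(f)))
  m <- as.matrix(Matrix::crossprod(memb, X)) / as.numeric(table(f))
  rownames(m) <- levels(f)
  colnames(m) <- ds_norm$gene_ids
  m[order(rownames(m)), , drop = FALSE]
}

#' Mean normalized expression of tagged vs all other genes, per group
#'
#' Pools all cell x gene entries of a group: the tagged mean averages over
#' (cells in group) x (tagged genes), the rest mean over (cells in group) x
#' (all other genes). With no non-tagged gene present the rest mean is NA.
#'
#' @inheritParams top_expression_counts
#' @return data.frame: group, mean_expr_tagged, mean_expr_rest.
#' @export
mean_expression_table <- function(ds_norm, ids, genes) {
  gm <- group_means(ds_norm, ids)
  tagged <- intersect(genes$gene_id, colnames(gm))
  if (!length(tagged)) stop("no tagged gene present in the dataset")
  rest <- setdiff(colnames(gm), tagged)
  data.frame(group = rownames(gm),
             mean_expr_tagged = rowMeans(gm[, tagged, drop = FALSE]),
             mean_expr_rest = if (length(rest))
               rowMeans(gm[, rest, drop = FALSE]) else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap partition of two gene sets with distinct universes
#'
#' Classifies the union of two upregulated sets the way a cross-dataset Venn
#' diagram does, accounting for genes that could not appear in the other
#' analysis because they did not pass its filters: \code{both}; \code{a_only}
#' (in set A only, but present in B's universe); \code{b_only};
#' \code{a_only_unavailable_in_b} (in set A and absent from B's universe);
#' \code{b_only_unavailable_in_a}. Classes are disjoint and cover the union.
#'
#' @param set_a,set_b gene sets (subsets of their universes).
#' @param universe_a,universe_b post-filter gene universes of the analyses.
#' @return list with the five membership classes, \code{counts}, and
#'   \code{shared_universe} (size of the universe intersection).
#' @export
overlap_partition <- function(set_a, universe_a, set_b, universe_b) {
  if (length(setdiff(set_a, universe_a)))
    stop("set_a contains genes outside universe_a")
  if (length(setdiff(set_b, universe_b)))
    stop("set_b contains genes outside universe_b")
  both <- intersect(set_a, set_b)
  a_rest <- setdiff(set_a, set_b)
  b_rest <- setdiff(set_b, set_a)
  out <- list(
    both = sort(both),
    a_only = sort(intersect(a_rest, universe_b)),
    b_only = sort(intersect(b_rest, universe_a)),
    a_only_unavailable_in_b = sort(setdiff(a_rest, universe_b)),
    b_only_unavailable_in_a = sort(setdiff(b_rest, universe_a)))
  out$counts <- vapply(out, length, integer(1))
  out$shared_universe <- length(intersect(universe_a, universe_b))
  out
}

#' Parental-origin split analyses (MEG vs PEG)
#'
#' Partitions the tagged list by the active parental origin (origin_brain
#' when the list was loaded with \code{context = "brain"}, origin_default
#' otherwise) and re-runs ORA and GSEA for each partition against the same DE
#' table; eligibility is recomputed against each partition's own post-filter
#' total. A partition with no gene passing the filter is skipped with a
#' warning.
#'
#' @param de a \code{de_table}.
#' @param genes a \code{tagged_gene_list} with both origins represented.
#' @param level analysis level; defaults to the level recorded in \code{de}.
#' @param seed integer seed for GSEA permutation draws (required when
#'   \code{gsea = TRUE}).
#' @param gsea also run GSEA per partition (default TRUE).
#' @param ... further arguments passed to \code{\link{run_ora}} and
#'   \code{\link{run_gsea}} (q_cut, threshold_frac, min_tagged, n_perm, ...).
#' @return named list (MEG, PEG) of lists with elements \code{ora} and
#'   (optionally) \code{gsea}.
#' @export
parental_split_run <- function(de, genes, level = NULL, seed = NULL,
                               gsea = TRUE, ...) {
  stopifnot(inherits(genes, "tagged_gene_list"))
  if (length(unique(genes$origin)) < 2)
    stop("the gene list must contain both MEGs and PEGs")
  if (gsea && is.null(seed)) stop("an integer seed is required for GSEA")
  parts <- split_by_origin(genes)
  universe <- unique(de$gene)
  dots <- list(...)
  ora_args <- dots[names(dots) %in% c("q_cut", "threshold_frac")]
  gsea_args <- dots[names(dots) %in% c("q_cut", "min_tagged", "n_perm", "weighted")]
  out <- list()
  for (o in names(parts)) {
    part <- parts[[o]]
    if (!length(intersect(part$gene_id, universe))) {
      warning("origin partition with no post-filter gene skipped: ", o)
      next
    }
    ora <- do.call(run_ora, c(list(de = de, genes = part, level = level), ora_args))
    res <- list(ora = ora)
    if (gsea)
      res$gsea <- do.call(run_gsea, c(list(de = de, genes = part, ora = ora,
                                           level = level,
                                           seed = stage_seed(seed, match(o, names(parts)))),
                                      gsea_args))
    out[[o]] <- res
  }
  out
}
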