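#' Tagged gene list with parental-origin annotations
#'
#' The tagged set is a curated list of imprinted genes, each annotated with
#' the parent of origin of its expressed allele: MEG (maternally expressed) or
#' PEG (paternally expressed). A handful of genes (notably Igf2 and Grb10)
#' switch parental origin between tissues, so the list carries two origin
#' columns: \code{origin_default} and \code{origin_brain}. The active origin
#' used by origin-split analyses is chosen by the \code{context} argument.
#' \code{chromosome_order} is a positive integer rank used to order genes in
#' dot plots.
#'
#' @param path delimited file with columns \code{gene_id},
#'   \code{origin_default}, \code{origin_brain}, \code{chromosome_order}.
#' @param context \code{"generic"} or \code{"brain"}; selects which origin
#'   column drives MEG/PEG splits.
#' @return a data.frame of class \code{tagged_gene_list} with an active
#'   \code{origin} column.
#' @export
load_gene_list <- function(path, context = c("generic", "brain")) {
  context <- match.arg(context)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  required <- c("gene_id", "origin_default", "origin_brain", "chromosome_order")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("gene list is missing column(s): ", paste(missing_cols, collapse = ", "))
  tagged_gene_list(df, context = context)
}

#' Construct a tagged gene list from a data.frame
#'
#' @param df data.frame with the four gene-list columns.
#' @inheritParams load_gene_list
#' @export
tagged_gene_list <- function(df, context = c("generic", "brain")) {
  context <- match.arg(context)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene_id <- trimws(as.character(df$gene_id))
  check_unique_ids(df$gene_id, "gene")
  for (col in c("origin_default", "origin_brain")) {
    v <- trimws(as.character(df[[col]]))
    if (any(is.na(v) | !nzchar(v)))
      stop("missing parental-origin value in column ", col)
    bad <- setdiff(unique(v), c("MEG", "PEG"))
    if (length(bad))
      stop("unknown parental-origin token(s) in ", col, ": ",
           paste(bad, collapse = ", "))
    df[[col]] <- v
  }
  df$chromosome_order <- as.integer(df$chromosome_order)
  if (any(is.na(df$chromosome_order) | df$chromosome_order < 1))
    stop("chromosome_order must be positive integers")
  df$origin <- if (context == "brain") df$origin_brain else df$origin_default
  attr(df, "context") <- context
  class(df) <- c("tagged_gene_list", "data.frame")
  df
}

#' The shipped imprinted-gene list
#'
#' Loads the bundled list of 119 murine imprinted genes. This list is a
#' synthetic reconstruction assembled from well-established murine imprinted
#' genes (canonical protein-coding and long non-coding RNA loci, X-linked and
#' small non-coding RNA genes excluded); the MEG/PEG annotations are
#' good-faith consensus calls, with Igf2 and Grb10 carrying tissue-dependent
#' origins (both switch parental origin in the brain). It is intended for
#' demonstration, simulation and testing; substitute a curated list via
#' \code{\link{load_gene_list}} for real analyses.
#'
#' @inheritParams load_gene_list
#' @return a \code{tagged_gene_list} of 119 entries.
#' @export
default_imprinted_genes <- function(context = c("generic", "brain")) {
  path <- system.file("extdata", "imprinted_genes_mm_synthetic.csv",
                      package = "igenrich", mustWork = TRUE)
  load_gene_list(path, context = match.arg(context))
}

#' Split a tagged gene list by parental origin
#'
#' @param genes a \code{tagged_gene_list}.
#' @return a named list with \code{MEG} and \code{PEG} sublists (active-origin
#'   partition; entries absent from an origin give a zero-row sublist).
#' @export
split_by_origin <- function(genes) {
  stopifnot(inherits(genes, "tagged_gene_list"))
  ctx <- attr(genes, "context")
  out <- lapply(c(MEG = "MEG", PEG = "PEG"), function(o) {
    sub <- genes[genes$origin == o, , drop = FALSE]
    attr(sub, "context") <- ctx
    class(sub) <- c("tagged_gene_list", "data.frame")
    sub
  })
  out
}
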