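#' Run the full enrichment pipeline
#'
#' Executes load (or simulate) -> gene filter -> (optional cell subset with
#' re-filter) -> normalization -> group-vs-rest DE -> ORA -> GSEA ->
#' summaries, and writes every result table as CSV plus a machine-readable
#' JSON manifest (parameters, seed, dropped counts). Reruns with the same
#' config and seed produce byte-identical CSV output.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{input}{either a \code{synthetic_spec}, or a list with the
#'       already-loaded objects (\code{dataset}, \code{identities},
#'       \code{gene_list}), or a list of file paths (\code{matrix_file},
#'       \code{genes_file}, \code{cells_file}, \code{identities_file},
#'       \code{gene_list_file}, optional \code{format}, \code{transpose}).}
#'     \item{level}{analysis level (1, 2, 3 or long tag); defaults to the
#'       identity map's level.}
#'     \item{min_cells}{gene-presence filter, default 20.}
#'     \item{keep_labels}{optional labels for cell subsetting + re-filter.}
#'     \item{q_cut, ora_frac, gsea_min, n_perm}{thresholds; defaults 0.05,
#'       0.05, 15, 10000.}
#'     \item{context}{gene-list origin context, "generic" or "brain".}
#'     \item{split_parental}{also run MEG/PEG split analyses, default FALSE.}
#'     \item{normalize_scale}{counts-per-`scale` normalization, default 1e4.}
#'     \item{seed}{integer seed (required).}
#'   }
#' @param outdir output directory (created; existing files overwritten).
#' @return invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(is.list(config), !is.null(config$seed))
  cfg <- utils::modifyList(list(min_cells = 20, q_cut = 0.05, ora_frac = 0.05,
                                gsea_min = 15, n_perm = 10000,
                                context = "generic", split_parental = FALSE,
                                normalize_scale = 1e4, keep_labels = NULL,
                                level = NULL),
                           config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  loaded <- stage("load", {
    inp <- cfg$input
    if (inherits(inp, "synthetic_spec")) {
      generate_synthetic(inp)
    } else if (!is.null(inp$dataset)) {
      inp
    } else {
      ds <- read_expression_matrix(inp$matrix_file, inp$genes_file,
                                   inp$cells_file,
                                   format = if (is.null(inp$format)) "auto" else inp$format,
                                   transpose = isTRUE(inp$transpose))
      ids <- attach_identities(ds, inp$identities_file,
                               level = if (is.null(cfg$level)) "level1_multiorgan" else cfg$level)
      gl <- if (is.null(inp$gene_list_file)) default_imprinted_genes(cfg$context)
            else load_gene_list(inp$gene_list_file, context = cfg$context)
      list(dataset = ds, identities = ids, gene_list = gl)
    }
  })
  ds <- loaded$dataset
  ids <- loaded$identities
  genes <- loaded$gene_list
  if (!is.null(cfg$level)) ids$level <- as_level(cfg$level)
  n_cells_in <- n_cells(ds); n_genes_in <- n_genes(ds)

  prep <- stage("preprocess", {
    if (!is.null(cfg$keep_labels)) {
      sub <- subset_cells_and_refilter(ds, ids, cfg$keep_labels,
                                       min_cells = cfg$min_cells)
      sub
    } else {
      list(dataset = filter_genes_min_cells(ds, min_cells = cfg$min_cells),
           identities = ids)
    }
  })
  ds <- prep$dataset; ids <- prep$identities
  ds <- stage("normalize",
              if (layer_tag(ds) == "raw_counts")
                normalize_library_size(ds, scale = cfg$normalize_scale)
              else ds)

  de <- stage("diffexpr", run_de(ds, ids))
  ora <- stage("ora", run_ora(de, genes, q_cut = cfg$q_cut,
                              threshold_frac = cfg$ora_frac))
  gsea <- stage("gsea", run_gsea(de, genes, ora = ora, q_cut = cfg$q_cut,
                                 min_tagged = cfg$gsea_min,
                                 n_perm = cfg$n_perm,
                                 seed = stage_seed(cfg$seed, 101L)))
  summaries <- stage("summaries", list(
    top_counts = top_expression_counts(ds, ids, genes),
    mean_expr = mean_expression_table(ds, ids, genes)))
  split <- NULL
  if (isTRUE(cfg$split_parental) && length(unique(genes$origin)) > 1)
    split <- stage("parental_split",
                   parental_split_run(de, genes, seed = stage_seed(cfg$seed, 102L),
                                      q_cut = cfg$q_cut,
                                      threshold_frac = cfg$ora_frac,
                                      min_tagged = cfg$gsea_min,
                                      n_perm = cfg$n_perm))

  stage("write", {
    wcsv <- function(x, name) data.table::fwrite(as.data.frame(x),
                                                 file.path(outdir, name))
    wcsv(de, "de_table.csv")
    wcsv(ora, "ora_results.csv")
    wcsv(format_ora_table(ora), "ora_table_display.csv")
    wcsv(gsea, "gsea_results.csv")
    wcsv(data.frame(group = names(summaries$top_counts),
                    n_tagged_top = as.integer(summaries$top_counts)),
         "top_expression_counts.csv")
    wcsv(summaries$mean_expr, "mean_expression.csv")
    if (!is.null(split))
      for (o in names(split)) {
        wcsv(split[[o]]$ora, sprintf("ora_results_%s.csv", o))
        if (!is.null(split[[o]]$gsea))
          wcsv(split[[o]]$gsea, sprintf("gsea_results_%s.csv", o))
      }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("igenrich")),
    seed = cfg$seed,
    level = ids$level,
    thresholds = cfg[c("min_cells", "q_cut", "ora_frac", "gsea_min", "n_perm",
                       "normalize_scale")],
    context = cfg$context,
    input_cells = n_cells_in, input_genes = n_genes_in,
    analysed_cells = n_cells(ds), universe_genes = n_genes(ds),
    universe_tagged = length(intersect(genes$gene_id, ds$gene_ids)),
    dropped_cells = n_cells_in - n_cells(ds),
    filtered_genes = n_genes_in - n_genes(ds),
    groups = sort(unique(ids$assignments)),
    synthetic = inherits(cfg$input, "synthetic_spec"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dataset = ds, identities = ids, gene_list = genes, de = de,
                 ora = ora, gsea = gsea, summaries = summaries,
                 parental_split = split, manifest = manifest))
}
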