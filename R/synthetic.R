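#' Specification for a synthetic single-cell count dataset
#'
#' Describes a negative-binomial cells x genes count matrix with identity
#' groups, group-specific marker genes, and a tagged gene set that can carry
#' planted enrichment in one group. Per-gene base means are lognormal,
#' per-cell library-size factors are lognormal, and counts are NB with a
#' gene-shared dispersion (a Poisson mode exists for exactness checks).
#' Marker genes are disjoint across groups and disjoint from the tagged set
#' unless \code{allow_marker_tagged_overlap} permits overlap (used for null
#' calibration, where the tagged set must behave like a random draw from the
#' whole gene universe).
#'
#' @param n_genes number of genes (default 5000).
#' @param n_cells_per_group cells per identity group (default 300).
#' @param group_labels identity-group labels (default G1..G6).
#' @param tagged_set_size size of the tagged set (default 100).
#' @param tagged_fraction_meg fraction of tagged genes annotated MEG
#'   (default 0.5).
#' @param baseline_mean_log_mu,baseline_mean_log_sigma lognormal parameters
#'   of per-gene base means (defaults 0.5, 1.0).
#' @param nb_dispersion NB dispersion phi; variance is mu + phi mu^2
#'   (default 0.5).
#' @param marker_genes_per_group,marker_fold planted marker genes per group
#'   and their fold factor (defaults 50, 4).
#' @param enriched_group label receiving planted tagged enrichment, or NULL
#'   for a null dataset.
#' @param enriched_tagged_fraction fraction of tagged genes planted
#'   (default 0.3).
#' @param enriched_fold fold factor of planted tagged genes (default 3).
#' @param enriched_origin restrict planting to one origin ("MEG"/"PEG"), or
#'   NULL for origin-blind planting.
#' @param library_size_variation lognormal sigma of per-cell size factors
#'   (default 0.3).
#' @param allow_marker_tagged_overlap allow marker genes inside the tagged
#'   set (default FALSE).
#' @param distribution \code{"nb"} (default) or \code{"poisson"}.
#' @param level analysis level tag attached to the generated identity map.
#' @param seed integer seed (required); identical spec + seed gives
#'   bit-identical output.
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_genes = 5000, n_cells_per_group = 300,
                           group_labels = paste0("G", 1:6),
                           tagged_set_size = 100, tagged_fraction_meg = 0.5,
                           baseline_mean_log_mu = 0.5,
                           baseline_mean_log_sigma = 1.0,
                           nb_dispersion = 0.5,
                           marker_genes_per_group = 50, marker_fold = 4,
                           enriched_group = NULL,
                           enriched_tagged_fraction = 0.3, enriched_fold = 3,
                           enriched_origin = NULL,
                           library_size_variation = 0.3,
                           allow_marker_tagged_overlap = FALSE,
                           distribution = c("nb", "poisson"),
                           level = "level1_multiorgan",
                           seed) {
  if (missing(seed)) stop("an integer seed is required")
  distribution <- match.arg(distribution)
  spec <- list(n_genes = as.integer(n_genes),
               n_cells_per_group = as.integer(n_cells_per_group),
               group_labels = as.character(group_labels),
               tagged_set_size = as.integer(tagged_set_size),
               tagged_fraction_meg = tagged_fraction_meg,
               baseline_mean_log_mu = baseline_mean_log_mu,
               baseline_mean_log_sigma = baseline_mean_log_sigma,
               nb_dispersion = nb_dispersion,
               marker_genes_per_group = as.integer(marker_genes_per_group),
               marker_fold = marker_fold,
               enriched_group = enriched_group,
               enriched_tagged_fraction = enriched_tagged_fraction,
               enriched_fold = enriched_fold,
               enriched_origin = enriched_origin,
               library_size_variation = library_size_variation,
               allow_marker_tagged_overlap = allow_marker_tagged_overlap,
               distribution = distribution,
               level = as_level(level),
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_genes < 2 || n_cells_per_group < 2) stop("sizes too small")
    if (anyDuplicated(group_labels) || length(group_labels) < 2)
      stop("need >= 2 distinct group labels")
    if (tagged_set_size > n_genes) stop("tagged_set_size exceeds n_genes")
    if (tagged_set_size < 1) stop("tagged_set_size must be positive")
    if (tagged_fraction_meg < 0 || tagged_fraction_meg > 1)
      stop("tagged_fraction_meg must lie in [0, 1]")
    if (nb_dispersion <= 0 && distribution == "nb")
      stop("nb_dispersion must be positive")
    if (baseline_mean_log_sigma < 0 || library_size_variation < 0)
      stop("lognormal sigmas must be non-negative")
    if (marker_fold < 1 || enriched_fold < 1) stop("fold factors must be >= 1")
    if (marker_genes_per_group < 0) stop("marker_genes_per_group must be >= 0")
    pool <- if (allow_marker_tagged_overlap) n_genes else n_genes - tagged_set_size
    if (length(group_labels) * marker_genes_per_group > pool)
      stop("not enough genes for disjoint marker sets")
    if (!is.null(enriched_group)) {
      if (!enriched_group %in% group_labels)
        stop("enriched_group is not one of group_labels")
      if (enriched_tagged_fraction * tagged_set_size < 1)
        stop("enriched fraction of the tagged set must cover >= 1 gene")
      if (!is.null(enriched_origin) && !enriched_origin %in% c("MEG", "PEG"))
        stop("enriched_origin must be MEG or PEG")
    }
  })
  invisible(spec)
}

# Stage 1 randomness: gene roles (tagged membership, origins, markers,
# planted enrichment). Shared verbatim by generate_synthetic and truth_table.
assign_effects <- function(spec) {
  gene_ids <- sprintf("g%05d", seq_len(spec$n_genes))
  with_local_seed(stage_seed(spec$seed, 1L), {
    tagged_idx <- sort(sample.int(spec$n_genes, spec$tagged_set_size))
    n_meg <- round(spec$tagged_fraction_meg * spec$tagged_set_size)
    origin <- rep("PEG", spec$tagged_set_size)
    origin[sample.int(spec$tagged_set_size, n_meg)] <- "MEG"
    pool <- if (spec$allow_marker_tagged_overlap) seq_len(spec$n_genes)
            else setdiff(seq_len(spec$n_genes), tagged_idx)
    n_mark <- length(spec$group_labels) * spec$marker_genes_per_group
    marker_idx <- if (n_mark > 0) sample(pool, n_mark) else integer(0)
    markers <- split(marker_idx,
                     rep(spec$group_labels, each = spec$marker_genes_per_group))
    enriched_idx <- integer(0)
    if (!is.null(spec$enriched_group)) {
      cand <- if (is.null(spec$enriched_origin)) tagged_idx
              else tagged_idx[origin == spec$enriched_origin]
      n_enr <- max(1L, round(spec$enriched_tagged_fraction * spec$tagged_set_size))
      n_enr <- min(n_enr, length(cand))
      enriched_idx <- sort(sample(cand, n_enr))
    }
    fold <- matrix(1, spec$n_genes, length(spec$group_labels),
                   dimnames = list(gene_ids, spec$group_labels))
    for (g in names(markers)) fold[markers[[g]], g] <- spec$marker_fold
    if (length(enriched_idx))
      fold[enriched_idx, spec$enriched_group] <-
        fold[enriched_idx, spec$enriched_group] * spec$enriched_fold
    list(gene_ids = gene_ids, tagged_idx = tagged_idx, origin = origin,
         markers = markers, enriched_idx = enriched_idx, fold = fold)
  })
}

#' Generate a synthetic dataset from a specification
#'
#' Draws per-gene base means (lognormal), per-cell size factors (lognormal),
#' and counts \code{NB(mean = s_c * mu_g * f(c,g), dispersion)} where
#' \code{f} is the planted fold factor (marker or enrichment, 1 otherwise).
#' All randomness flows from the spec seed through per-stage derived seeds.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with \code{dataset} (raw-count \code{expression_dataset}),
#'   \code{identities} (\code{cell_identity_map}), \code{gene_list}
#'   (\code{tagged_gene_list} for the tagged set), \code{truth} (the
#'   per-gene x group fold matrix as a data.frame), and \code{spec}.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  eff <- assign_effects(spec)
  G <- length(spec$group_labels)
  n_cells <- G * spec$n_cells_per_group
  cell_ids <- sprintf("c%05d", seq_len(n_cells))
  group_of <- rep(spec$group_labels, each = spec$n_cells_per_group)
  mu <- with_local_seed(stage_seed(spec$seed, 2L),
    stats::rlnorm(spec$n_genes, spec$baseline_mean_log_mu,
                  spec$baseline_mean_log_sigma))
  s <- with_local_seed(stage_seed(spec$seed, 3L),
    stats::rlnorm(n_cells, 0, spec$library_size_variation))
  counts <- with_local_seed(stage_seed(spec$seed, 4L), {
    m <- matrix(0L, n_cells, spec$n_genes)
    for (gi in seq_len(G)) {
      rows <- which(group_of == spec$group_labels[gi])
      mean_block <- outer(s[rows], mu * eff$fold[, gi])
      m[rows, ] <- if (spec$distribution == "nb")
        stats::rnbinom(length(mean_block), mu = mean_block,
                       size = 1 / spec$nb_dispersion)
      else
        stats::rpois(length(mean_block), mean_block)
    }
    m
  })
  dimnames(counts) <- list(cell_ids, eff$gene_ids)
  ds <- expression_dataset(counts = counts)
  ids <- cell_identity_map(stats::setNames(group_of, cell_ids),
                           level = spec$level)
  gl <- tagged_gene_list(data.frame(
    gene_id = eff$gene_ids[eff$tagged_idx],
    origin_default = eff$origin, origin_brain = eff$origin,
    chromosome_order = seq_along(eff$tagged_idx),
    stringsAsFactors = FALSE))
  list(dataset = ds, identities = ids, gene_list = gl,
       truth = truth_from_effects(eff), spec = spec)
}

truth_from_effects <- function(eff) {
  data.frame(gene = eff$gene_ids,
             tagged = seq_along(eff$gene_ids) %in% eff$tagged_idx,
             as.data.frame(eff$fold, optional = TRUE),
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Ground-truth fold factors of a synthetic specification
#'
#' Recomputes the per-gene, per-group true fold factors (marker and planted
#' enrichment effects) from the spec alone, without generating counts;
#' identical to the \code{truth} element of \code{\link{generate_synthetic}}
#' for the same spec.
#'
#' @param spec a \code{synthetic_spec}.
#' @return data.frame: gene, tagged, one fold column per group.
#' @export
truth_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  truth_from_effects(assign_effects(spec))
}
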