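#' Rank a group's upregulated genes by Log2FC
#'
#' Sorts the group's level-dependent upregulated set by decreasing log2 fold
#' change (all positive by construction of the set); ties are broken by
#' lexicographic gene identifier so the ranking is deterministic.
#'
#' @inheritParams upregulated_set
#' @return data.frame with columns \code{gene} and \code{weight} (the
#'   log2fc), in rank order.
#' @export
rank_genes <- function(de, group, level, q_cut = 0.05) {
  up <- upregulated_set(de, group, level, q_cut = q_cut)
  if (!length(up))
    stop("group has no upregulated genes; GSEA is inapplicable: ", group)
  sub <- de[de$group == group & de$gene %in% up, , drop = FALSE]
  sub <- sub[order(-sub$log2fc, sub$gene), , drop = FALSE]
  data.frame(gene = sub$gene, weight = sub$log2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Running-sum enrichment score
#'
#' Walks the ranked list accumulating a weight: a tagged gene at position i
#' adds \code{weight_i / sum(weights of tagged genes)}, a non-tagged gene
#' subtracts \code{1 / (n_ranked - n_tagged)}. The enrichment score is the
#' maximum of the running sum over all positions (floored at 0 when the curve
#' never rises above 0); the curve always returns to 0 at the end. With equal
#' weights this reduces to the classical Kolmogorov-Smirnov-style statistic.
#'
#' @param ranked data.frame from \code{\link{rank_genes}} (columns gene,
#'   weight), or a character vector of genes (equal weights).
#' @param tagged character vector of tagged gene identifiers; must intersect
#'   the ranked list and must not cover it entirely.
#' @param weighted use the log2fc weights for hit increments (default); FALSE
#'   gives the equal-weight variant.
#' @return list with \code{es}, \code{running_curve} (one value per
#'   position), \code{hit_positions}, and \code{leading_edge} (ranked genes
#'   up to the position of the maximum).
#' @export
enrichment_score <- function(ranked, tagged, weighted = TRUE) {
  if (is.character(ranked))
    ranked <- data.frame(gene = ranked, weight = 1, stringsAsFactors = FALSE)
  n <- nrow(ranked)
  hit <- ranked$gene %in% tagged
  k <- sum(hit)
  if (k == 0) stop("no tagged gene is present in the ranked list")
  if (k == n) stop("tagged set covers the whole ranked list (miss decrement undefined)")
  w <- if (weighted) ranked$weight else rep(1, n)
  if (any(w[hit] < 0)) stop("hit weights must be non-negative")
  step <- rep(-1 / (n - k), n)
  step[hit] <- w[hit] / sum(w[hit])
  curve <- cumsum(step)
  es <- max(0, max(curve))
  peak <- if (es > 0) which.max(curve) else 0L
  list(es = es, running_curve = curve, hit_positions = which(hit),
       leading_edge = if (peak > 0) ranked$gene[seq_len(peak)] else character(0))
}

# es for a random placement of k hits at 'pos' given fixed weights
es_at_positions <- function(w, pos, n, miss_step) {
  step <- rep(miss_step, n)
  step[pos] <- w[pos] / sum(w[pos])
  max(0, max(cumsum(step)))
}

#' Gene-set permutation p-value for the enrichment score
#'
#' Keeps the observed ranking (and weights) fixed and draws
#' \code{n_perm} uniform random subsets of \code{tagged_size} positions,
#' recomputing the enrichment score for each; this is the null of tagged
#' genes falling anywhere along the ranked axis with equal probability.
#' \code{p = (1 + #\{es_perm >= es_obs\}) / (1 + n_perm)}, so the smallest
#' attainable p is \code{1/(n_perm+1)}.
#'
#' @param ranked data.frame (gene, weight) or character vector as in
#'   \code{\link{enrichment_score}}.
#' @param tagged_size number of tagged positions to draw.
#' @param es_obs observed enrichment score.
#' @param n_perm number of permutations, default 10000.
#' @param seed integer seed (required; the draw is reproducible and does not
#'   disturb the global RNG stream).
#' @param weighted as in \code{\link{enrichment_score}}.
#' @return the permutation p-value.
#' @export
permutation_p <- function(ranked, tagged_size, es_obs, n_perm = 10000, seed,
                          weighted = TRUE) {
  if (missing(seed)) stop("an integer seed is required")
  if (is.character(ranked))
    ranked <- data.frame(gene = ranked, weight = 1, stringsAsFactors = FALSE)
  n <- nrow(ranked)
  if (tagged_size <= 0 || tagged_size >= n)
    stop("need 0 < tagged_size < number of ranked genes")
  w <- if (weighted) ranked$weight else rep(1, n)
  miss_step <- -1 / (n - tagged_size)
  es_perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      es_at_positions(w, sample.int(n, tagged_size), n, miss_step),
      numeric(1))
  })
  (1 + sum(es_perm >= es_obs - 1e-12)) / (1 + n_perm)
}

#' GSEA eligibility gate
#'
#' A group qualifies for GSEA when it has at least \code{min_tagged}
#' upregulated tagged genes and the mean linear fold change of those genes
#' exceeds the mean fold change of the other upregulated genes (preventing
#' significance driven by a handful of genes or by tagged genes clustering in
#' the weak tail).
#'
#' @param n_tagged_up upregulated tagged genes in the group.
#' @param mean_fc_tagged,mean_fc_rest mean linear fold changes over the
#'   upregulated tagged / other upregulated genes.
#' @param min_tagged minimum tagged count, default 15.
#' @return logical.
#' @export
gsea_eligibility <- function(n_tagged_up, mean_fc_tagged, mean_fc_rest,
                             min_tagged = 15) {
  !is.na(n_tagged_up) & n_tagged_up >= min_tagged &
    !is.na(mean_fc_tagged) & !is.na(mean_fc_rest) &
    mean_fc_tagged > mean_fc_rest
}

#' Running-sum GSEA across identity groups
#'
#' For each GSEA-eligible group (see \code{\link{gsea_eligibility}}; the
#' counts and mean fold changes come from the ORA result), ranks the
#' upregulated genes by log2fc, computes the weighted running-sum enrichment
#' score for the tagged set, and a gene-set permutation p-value; Bonferroni
#' correction is applied across the eligible groups.
#'
#' @param de a \code{de_table}.
#' @param genes a \code{tagged_gene_list}.
#' @param ora matching \code{ora_result} (recomputed when NULL).
#' @param level analysis level; defaults to the level recorded in \code{de}.
#' @param q_cut upregulation cutoff, default 0.05.
#' @param min_tagged GSEA eligibility minimum, default 15.
#' @param n_perm permutations, default 10000.
#' @param seed integer seed for the permutation draws (required).
#' @param weighted weighted hit increments (default) or equal-weight variant.
#' @return a \code{gsea_result} data.frame: group, eligible, es, p_gsea,
#'   q_gsea, n_ranked, n_tagged; curves are in attribute \code{"curves"}
#'   (a named list), leading edges in attribute \code{"leading_edges"}.
#' @export
run_gsea <- function(de, genes, ora = NULL, level = NULL, q_cut = 0.05,
                     min_tagged = 15, n_perm = 10000, seed, weighted = TRUE) {
  if (missing(seed)) stop("an integer seed is required")
  if (is.null(level)) level <- attr(de, "level")
  level <- as_level(level)
  if (is.null(ora)) ora <- run_ora(de, genes, level = level, q_cut = q_cut)
  tagged <- intersect(genes$gene_id, unique(de$gene))
  res <- data.frame(group = ora$group,
                    eligible = gsea_eligibility(ora$n_up_tagged,
                                                ora$mean_fc_tagged,
                                                ora$mean_fc_rest,
                                                min_tagged = min_tagged),
                    es = NA_real_, p_gsea = NA_real_, q_gsea = NA_real_,
                    n_ranked = NA_integer_, n_tagged = NA_integer_,
                    stringsAsFactors = FALSE)
  curves <- list(); edges <- list()
  for (i in which(res$eligible)) {
    g <- res$group[i]
    ranked <- rank_genes(de, g, level, q_cut = q_cut)
    sc <- enrichment_score(ranked, tagged, weighted = weighted)
    res$es[i] <- sc$es
    res$n_ranked[i] <- nrow(ranked)
    res$n_tagged[i] <- length(sc$hit_positions)
    res$p_gsea[i] <- permutation_p(ranked, length(sc$hit_positions), sc$es,
                                   n_perm = n_perm,
                                   seed = stage_seed(seed, match(g, res$group)),
                                   weighted = weighted)
    curves[[g]] <- sc$running_curve
    edges[[g]] <- sc$leading_edge
  }
  el <- which(res$eligible)
  if (length(el)) res$q_gsea[el] <- bonferroni(res$p_gsea[el])
  attr(res, "curves") <- curves
  attr(res, "leading_edges") <- edges
  attr(res, "level") <- level
  class(res) <- c("gsea_result", "data.frame")
  res
}
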