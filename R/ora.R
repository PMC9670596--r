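#' One-sided Fisher's exact test for gene-set over-representation
#'
#' Exact upper-tail hypergeometric probability P(X >= a) where X is the
#' number of tagged genes among \code{n} upregulated genes drawn from a
#' universe of \code{N} genes containing \code{K} tagged genes. Equivalent to
#' a one-sided Fisher's exact test on the 2x2 table
#' \code{[a, K-a; n-a, N-K-n+a]} against enrichment. The tail is summed in
#' log space (log-gamma binomials with log-sum-exp), so p-values of order
#' 1e-13 and below keep full relative precision.
#'
#' @param a observed tagged genes among the upregulated (0 <= a <= min(K, n)).
#' @param K tagged genes in the universe.
#' @param n upregulated genes.
#' @param N universe size (genes passing the presence filter).
#' @return the exact upper-tail probability.
#' @export
fisher_one_sided <- function(a, K, n, N) {
  stopifnot(length(a) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  a <- as.numeric(a); K <- as.numeric(K); n <- as.numeric(n); N <- as.numeric(N)
  if (K > N || n > N || a > K || a > n || a < 0)
    stop("inconsistent margins: need 0 <= a <= min(K, n) and K, n <= N")
  if (N - K - n + a < 0)
    stop("inconsistent margins: derived cell N - K - n + a is negative")
  if (a == 0) return(1)
  x <- seq(a, min(K, n))
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  mx <- max(logp)
  exp(mx + log(sum(exp(logp - mx))))
}

#' ORA eligibility gate
#'
#' A group is eligible for over-representation testing when its count of
#' upregulated tagged genes reaches \code{threshold_frac} of the tagged genes
#' present in the universe. The comparison is real-valued (no rounding):
#' with 95 tagged genes, 5 upregulated is eligible (5 >= 4.75); with 106,
#' 5 is not (5 < 5.3).
#'
#' @param n_up_tagged upregulated tagged genes in the group.
#' @param universe_tagged tagged genes passing the presence filter.
#' @param threshold_frac eligibility fraction, default 0.05.
#' @return logical.
#' @export
ora_eligibility <- function(n_up_tagged, universe_tagged, threshold_frac = 0.05) {
  stopifnot(all(universe_tagged > 0))
  n_up_tagged >= threshold_frac * universe_tagged
}

#' Bonferroni correction over eligible groups
#'
#' @param p_values p-values of the eligible groups only; the multiplier is
#'   their count.
#' @return \code{pmin(1, m * p)} with \code{m = length(p_values)}.
#' @export
bonferroni <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  pmin(1, length(p_values) * p_values)
}

#' Over-representation analysis of the tagged set across identity groups
#'
#' Per group: extracts the level-dependent upregulated set, counts tagged
#' membership, applies the 5%-of-tagged eligibility gate, computes the
#' one-sided Fisher p for eligible groups, and Bonferroni-corrects across the
#' eligible groups only. Mean linear fold changes over the upregulated tagged
#' genes and over the other upregulated genes are reported for every group
#' (they also feed the GSEA eligibility gate).
#'
#' @param de a \code{de_table} from \code{\link{run_de}}.
#' @param genes a \code{tagged_gene_list}; only entries present in the DE
#'   universe count toward \code{universe_tagged}.
#' @param level analysis level (1, 2, 3 or long tags); defaults to the level
#'   recorded in \code{de}.
#' @param q_cut upregulation significance cutoff, default 0.05.
#' @param threshold_frac ORA eligibility fraction, default 0.05.
#' @return an \code{ora_result} data.frame, one row per group: group, n_up,
#'   n_up_tagged, universe_genes, universe_tagged, eligible, p_ora, q_ora
#'   (NA when ineligible), mean_fc_tagged, mean_fc_rest.
#' @export
run_ora <- function(de, genes, level = NULL, q_cut = 0.05, threshold_frac = 0.05) {
  stopifnot(inherits(genes, "tagged_gene_list"))
  if (is.null(level)) level <- attr(de, "level")
  level <- as_level(level)
  universe <- unique(de$gene)
  N <- length(universe)
  tagged <- intersect(genes$gene_id, universe)
  K <- length(tagged)
  if (K == 0) stop("no tagged gene passes the filter (empty tagged universe)")
  groups <- sort(unique(de$group))
  rows <- lapply(groups, function(g) {
    up <- upregulated_set(de, g, level, q_cut = q_cut)
    up_tag <- intersect(up, tagged)
    sub <- de[de$group == g, , drop = FALSE]
    fc_by_gene <- stats::setNames(sub$fc, sub$gene)
    data.frame(group = g, n_up = length(up), n_up_tagged = length(up_tag),
               universe_genes = N, universe_tagged = K,
               eligible = ora_eligibility(length(up_tag), K, threshold_frac),
               p_ora = NA_real_, q_ora = NA_real_,
               mean_fc_tagged = if (length(up_tag)) mean(fc_by_gene[up_tag]) else NA_real_,
               mean_fc_rest = if (length(setdiff(up, up_tag)))
                 mean(fc_by_gene[setdiff(up, up_tag)]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  el <- which(res$eligible)
  if (length(el)) {
    res$p_ora[el] <- vapply(el, function(i)
      fisher_one_sided(res$n_up_tagged[i], res$universe_tagged[i],
                       res$n_up[i], res$universe_genes[i]), numeric(1))
    res$q_ora[el] <- bonferroni(res$p_ora[el])
  }
  attr(res, "level") <- level
  attr(res, "n_eligible") <- length(el)
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Format an ORA result the way the published tables print it
#'
#' Ineligible groups show "--" for p and q; eligible values are rendered to
#' three significant figures.
#'
#' @param ora an \code{ora_result}.
#' @param digits significant figures for p/q display, default 3.
#' @return a data.frame of display strings alongside the counts.
#' @export
format_ora_table <- function(ora, digits = 3) {
  fmt <- function(v) ifelse(is.na(v), "--", format(signif(v, digits)))
  data.frame(group = ora$group,
             up_reg = ora$n_up, ig = ora$n_up_tagged,
             ora_p = fmt(ora$p_ora), ora_q = fmt(ora$q_ora),
             mean_fc_ig = round(ora$mean_fc_tagged, 2),
             mean_fc_rest = round(ora$mean_fc_rest, 2),
             eligible = ora$eligible,
             stringsAsFactors = FALSE)
}
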