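#' One-sided Wilcoxon rank-sum test (alternative: first sample greater)
#'
#' Returns P(rank-sum >= observed) under the null that both samples share a
#' distribution, against the alternative that \code{values_in} is
#' stochastically greater. For small samples (total <= 50) the exact
#' distribution is used: the closed-form Mann-Whitney distribution when there
#' are no ties, full enumeration of group assignments when there are ties and
#' enumeration is feasible. Larger samples use the normal approximation with
#' midrank tie correction and continuity correction.
#'
#' @param values_in,values_rest numeric vectors, both nonempty.
#' @param exact force the exact (TRUE) or approximate (FALSE) branch; NULL
#'   selects exact when \code{length(values_in) + length(values_rest) <= 50}.
#' @param max_enumeration cap on the number of assignments enumerated in the
#'   tied exact branch before falling back to the approximation.
#' @return the one-sided p-value; attribute \code{"degenerate"} is TRUE when
#'   all values are identical (p = 1, no evidence either way).
#' @export
wilcoxon_one_sided <- function(values_in, values_rest, exact = NULL,
                               max_enumeration = 2e5) {
  x <- as.numeric(values_in); y <- as.numeric(values_rest)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  comb <- c(x, y)
  if (length(unique(comb)) == 1L) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  r <- rank(comb)
  rs_obs <- sum(r[seq_len(n1)])
  u_obs <- rs_obs - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(comb) > 0L
  if (is.null(exact)) exact <- n <= 50
  if (exact && !has_ties) {
    # P(U >= u_obs) for integer-valued U
    return(stats::pwilcox(u_obs - 1, n1, n2, lower.tail = FALSE))
  }
  if (exact && has_ties && choose(n, n1) <= max_enumeration) {
    idx <- utils::combn(n, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    return(mean(sums >= rs_obs - 1e-9))
  }
  # normal approximation, midrank tie correction, continuity correction
  tie_tab <- table(comb)
  tie_term <- sum(tie_tab^3 - tie_tab)
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  z <- (u_obs - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment across genes ("horizontal")
#'
#' Step-up BH applied across the genes of one group-vs-rest comparison.
#' Output order matches input order; values are monotone and capped at 1.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return BH-adjusted q-values.
#' @export
bh_adjust_horizontal <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# ---- vectorized group-vs-rest engine ------------------------------------

# Midranks of the nonzero entries of a dgCMatrix, computed column-wise in one
# vectorized pass, plus per-column tie terms. Entries are assumed > 0 so all
# zeros of a column share the midrank (n0+1)/2.
sparse_column_rank_stats <- function(X) {
  n <- nrow(X); m <- length(X@x)
  nnz <- diff(X@p)
  n0 <- n - nnz
  jvec <- rep.int(seq_along(nnz), nnz)
  if (m == 0L)
    return(list(rank_nz = numeric(0), jvec = jvec, n0 = n0,
                tie_term = n0^3 - n0))
  # jvec is already nondecreasing (column-major storage), so a stable radix
  # sort on (jvec, x) leaves jvec unchanged and only values move
  ordv <- order(jvec, X@x, method = "radix")
  xs <- X@x[ordv]
  colstart <- X@p[-length(X@p)] + 1L              # first element of each column
  newcol <- logical(m)
  newcol[colstart[nnz > 0]] <- TRUE
  pos_in_col <- seq_len(m) - rep.int(X@p[-length(X@p)], nnz)
  newrun <- newcol | c(TRUE, xs[-1] != xs[-m])
  runid <- cumsum(newrun)
  runlen <- tabulate(runid)
  midrank <- pos_in_col[newrun] + (runlen - 1) / 2  # rank among the column's nonzeros
  rank_nz <- numeric(m)
  rank_nz[ordv] <- midrank[runid]
  # tie term: runs of equal nonzero values, per column
  tie_nz <- numeric(length(nnz))
  tie_by_col <- rowsum(runlen^3 - runlen, group = jvec[newrun])
  tie_nz[as.integer(rownames(tie_by_col))] <- tie_by_col[, 1]
  list(rank_nz = rank_nz, jvec = jvec, n0 = n0,
       tie_term = tie_nz + (n0^3 - n0))
}

#' Group-vs-rest differential expression for all identity groups
#'
#' For every identity group and every gene, computes the one-sided Wilcoxon
#' rank-sum p-value (group greater than rest) on the normalized layer, the
#' horizontal BH q-value (across genes, within the group's comparison), the
#' linear fold change of mean normalized expression, its log2, and the
#' nonzero-expression fractions in the group and in the rest.
#'
#' All groups share one ranking pass: ranks over all cells per gene are
#' computed once, tie-corrected rank sums are then accumulated per group by a
#' sparse cross-product, and the normal approximation (with continuity
#' correction) is applied. When the dataset has 50 cells or fewer, the exact
#' per-gene test is used instead.
#'
#' @param ds an \code{expression_dataset} with a normalized layer.
#' @param ids a \code{cell_identity_map} covering (a subset of) the cells.
#' @param epsilon pseudo-term guarding fold-change division by zero.
#' @param bh_axis \code{"genes"} (default, horizontal: BH across genes within
#'   each group's comparison) or \code{"groups"} (across groups per gene).
#' @return a \code{de_table} data.frame with one row per (gene, group):
#'   columns gene, group, p, q, fc, log2fc, pct_in, pct_rest, mean_in,
#'   mean_rest.
#' @export
run_de <- function(ds, ids, epsilon = 1e-9, bh_axis = c("genes", "groups")) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(ids, "cell_identity_map"))
  bh_axis <- match.arg(bh_axis)
  X <- get_layer(ds, "normalized")
  cells <- intersect(ds$cell_ids, names(ids$assignments))
  if (length(cells) < nrow(X)) X <- X[cells, , drop = FALSE]
  asg <- ids$assignments[cells]
  f <- factor(asg)
  sizes <- table(f)
  if (any(sizes < 2))
    stop("identity group(s) with < 2 cells: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (nlevels(f) < 2) stop("need at least two identity groups")
  n <- nrow(X); G <- nlevels(f); ngene <- ncol(X)
  memb <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                               dims = c(n, G))
  n_g <- as.numeric(sizes)

  # expression summaries (pattern matrix reuses X's structure: no comparison pass)
  P <- X; P@x[] <- 1
  nnz_gk <- as.matrix(Matrix::crossprod(memb, P))            # G x genes
  sum_gk <- as.matrix(Matrix::crossprod(memb, X))
  tot_nnz <- diff(P@p)
  tot_sum <- Matrix::colSums(X)
  mean_in <- sum_gk / n_g
  mean_rest <- sweep(-sum_gk, 2, tot_sum, `+`) / (n - n_g)
  pct_in <- nnz_gk / n_g
  pct_rest <- sweep(-nnz_gk, 2, tot_nnz, `+`) / (n - n_g)
  fc <- (mean_in + epsilon) / (mean_rest + epsilon)
  log2fc <- log2(fc)

  if (n > 50) {
    rs <- sparse_column_rank_stats(X)
    # centred sparse rank matrix: s = full rank - (n0+1)/2 at nonzero entries
    S <- X
    S@x <- rs$rank_nz + rs$n0[rs$jvec] - (rs$n0[rs$jvec] + 1) / 2
    rank_sum <- as.matrix(Matrix::crossprod(memb, S)) +
      outer(n_g, (rs$n0 + 1) / 2)
    u <- sweep(rank_sum, 1, n_g * (n_g + 1) / 2)             # Mann-Whitney U
    n2 <- n - n_g
    mu <- n_g * n2 / 2
    sigma2 <- outer(n_g * n2 / 12,
                    (n + 1) - rs$tie_term / (n * (n - 1)))
    z <- (u - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    p[!is.finite(z)] <- 1                                    # constant genes
  } else {
    Xd <- as.matrix(X)
    p <- matrix(1, G, ngene)
    for (g in seq_len(G)) {
      ing <- as.integer(f) == g
      for (j in seq_len(ngene))
        p[g, j] <- as.numeric(wilcoxon_one_sided(Xd[ing, j], Xd[!ing, j]))
    }
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  q <- p
  if (bh_axis == "genes") {
    for (g in seq_len(G)) q[g, ] <- bh_adjust_horizontal(p[g, ])
  } else {
    for (j in seq_len(ngene)) q[, j] <- bh_adjust_horizontal(p[, j])
  }

  out <- data.frame(
    gene = rep(ds$gene_ids, each = G),
    group = rep(levels(f), times = ngene),
    p = as.vector(p), q = as.vector(q),
    fc = as.vector(fc), log2fc = as.vector(log2fc),
    pct_in = as.vector(pct_in), pct_rest = as.vector(pct_rest),
    mean_in = as.vector(mean_in), mean_rest = as.vector(mean_rest),
    stringsAsFactors = FALSE)
  out <- out[order(out$group, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "level") <- ids$level
  attr(out, "universe_genes") <- ngene
  class(out) <- c("de_table", "data.frame")
  out
}

#' Fold changes and expression fractions for one group
#'
#' Direct computation for a single group-vs-rest split:
#' \code{fc = (mean_in + epsilon) / (mean_rest + epsilon)} on linear
#' normalized values; \code{pct_in}/\code{pct_rest} are nonzero-cell
#' fractions.
#'
#' @param ds_norm dataset with a normalized layer.
#' @param ids a \code{cell_identity_map}.
#' @param group identity-group label.
#' @param epsilon pseudo-term, default 1e-9.
#' @return data.frame with one row per gene: fc, log2fc, pct_in, pct_rest.
#' @export
fold_changes <- function(ds_norm, ids, group, epsilon = 1e-9) {
  X <- get_layer(ds_norm, "normalized")
  cells <- intersect(ds_norm$cell_ids, names(ids$assignments))
  X <- X[cells, , drop = FALSE]
  ing <- ids$assignments[cells] == group
  if (sum(ing) < 2 || sum(!ing) < 2)
    stop("group and rest must both have >= 2 cells")
  mean_in <- Matrix::colMeans(X[ing, , drop = FALSE])
  mean_rest <- Matrix::colMeans(X[!ing, , drop = FALSE])
  fc <- (mean_in + epsilon) / (mean_rest + epsilon)
  data.frame(gene = ds_norm$gene_ids, fc = fc, log2fc = log2(fc),
             pct_in = Matrix::colMeans(X[ing, , drop = FALSE] > 0),
             pct_rest = Matrix::colMeans(X[!ing, , drop = FALSE] > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Upregulated gene set for a group, at a given analysis level
#'
#' Levels 1 and 2 require \code{q <= 0.05} and \code{log2fc >= 1}; level 3
#' relaxes the fold-change criterion to \code{log2fc > 0}. Boundaries are
#' inclusive exactly as stated.
#'
#' @param de a \code{de_table}.
#' @param group identity-group label present in \code{de}.
#' @param level analysis level (1, 2, 3 or the long tags).
#' @param q_cut significance cutoff on the BH q-value, default 0.05.
#' @return character vector of gene identifiers.
#' @export
upregulated_set <- function(de, group, level, q_cut = 0.05) {
  level <- as_level(level)
  rows <- de[de$group == group, , drop = FALSE]
  if (!nrow(rows)) stop("group not present in the DE table: ", group)
  keep <- if (level == "level3_region")
    rows$q <= q_cut & rows$log2fc > 0
  else
    rows$q <= q_cut & rows$log2fc >= 1
  rows$gene[keep]
}
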