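# Small fixtures, built in code at test time.

# dataset from a dense matrix given as cells x genes
toy_dataset <- function(m, normalized = FALSE, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(m)))
  dimnames(m) <- list(cells, genes)
  if (normalized) expression_dataset(normalized = m)
  else expression_dataset(counts = m)
}

# hand-built DE table with controllable q/log2fc per (gene, group)
fake_de <- function(df, level = "level2_wholebrain", universe = NULL) {
  need <- c("gene", "group", "q", "log2fc")
  stopifnot(all(need %in% names(df)))
  for (col in c("p", "fc", "pct_in", "pct_rest", "mean_in", "mean_rest"))
    if (is.null(df[[col]])) df[[col]] <- switch(col, p = df$q, fc = 2^df$log2fc, 0.5)
  attr(df, "level") <- as_level(level)
  attr(df, "universe_genes") <- if (is.null(universe)) length(unique(df$gene)) else universe
  class(df) <- c("de_table", "data.frame")
  df
}

# small seeded simulation used by several suites
small_sim <- function(seed = 11, enriched = "G2", ...) {
  sp <- synthetic_spec(n_genes = 400, n_cells_per_group = 40,
                       group_labels = paste0("G", 1:4),
                       tagged_set_size = 30, marker_genes_per_group = 20,
                       enriched_group = enriched, seed = seed, ...)
  generate_synthetic(sp)
}

# independent step-up BH implementation (oracle; never calls p.adjust)
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# brute-force running-sum score, written independently of enrichment_score
es_bruteforce <- function(weights, hit_idx) {
  n <- length(weights)
  k <- length(hit_idx)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_idx) run <- run + weights[i] / sum(weights[hit_idx])
    else run <- run - 1 / (n - k)
    if (run > best) best <- run
  }
  best
}

# tolerance implied by a printed value string: half a unit in the last digit
printed_tol <- function(s) {
  if (grepl("E", s, ignore.case = TRUE)) {
    mant <- sub("[eE].*", "", s)
    ex <- as.numeric(sub(".*[eE]", "", s))
    sig <- nchar(gsub("[^0-9]", "", mant))
    0.5 * 10^(ex - (sig - 1))
  } else if (grepl("\\.", s)) {
    0.5 * 10^(-nchar(sub(".*\\.", "", s)))
  } else 0.5
}
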