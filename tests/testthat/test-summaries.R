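test_that("top-expression counts follow the per-gene argmax, conserving totals", {
  m <- rbind(c(10, 1, 5), c(10, 1, 5),   # group A cells
             c(3, 8, 5), c(3, 8, 5))     # group B cells
  ds <- toy_dataset(m, normalized = TRUE)
  ids <- cell_identity_map(setNames(c("A", "A", "B", "B"), ds$cell_ids))
  gl <- tagged_gene_list(data.frame(gene_id = c("g1", "g2", "g3"),
                                    origin_default = c("MEG", "PEG", "MEG"),
                                    origin_brain = c("MEG", "PEG", "MEG"),
                                    chromosome_order = 1:3))
  tc <- top_expression_counts(ds, ids, gl)
  expect_equal(as.integer(tc), c(2L, 1L))          # g1->A, g2->B, g3 tie -> A
  expect_equal(attr(tc, "ties"), 1L)
  expect_equal(sum(tc), 3L)                        # conservation
  # brute-force oracle on random data
  set.seed(15)
  mr <- matrix(rexp(40 * 25), 40, 25)
  dsr <- toy_dataset(mr, normalized = TRUE)
  lab <- setNames(sample(c("A", "B", "C"), 40, replace = TRUE), dsr$cell_ids)
  idsr <- cell_identity_map(lab)
  glr <- tagged_gene_list(data.frame(gene_id = sprintf("g%d", 1:10),
                                     origin_default = "MEG",
                                     origin_brain = "MEG",
                                     chromosome_order = 1:10))
  tcr <- top_expression_counts(dsr, idsr, glr)
  brute <- table(factor(vapply(1:10, function(j) {
    means <- tapply(mr[, j], lab, mean)
    sort(names(means))[which.max(means[sort(names(means))])]
  }, character(1)), levels = sort(unique(lab))))
  expect_equal(as.integer(tcr), as.integer(brute))
})

test_that("mean expression pools cell x gene entries per group", {
  ds <- toy_dataset(cbind(c(1, 2, 3)), normalized = TRUE)
  ids <- cell_identity_map(setNames(rep("A", 3), ds$cell_ids))
  gl <- tagged_gene_list(data.frame(gene_id = "g1", origin_default = "MEG",
                                    origin_brain = "MEG", chromosome_order = 1))
  mt <- mean_expression_table(ds, ids, gl)
  expect_equal(mt$mean_expr_tagged, 2)
  expect_true(is.na(mt$mean_expr_rest))            # tagged set covers all genes
  # two-loop reference on random data
  set.seed(44)
  m <- matrix(rexp(30 * 20), 30, 20)
  dsr <- toy_dataset(m, normalized = TRUE)
  lab <- setNames(rep(c("A", "B"), 15), dsr$cell_ids)
  idsr <- cell_identity_map(lab)
  glr <- tagged_gene_list(data.frame(gene_id = c("g3", "g7", "g11"),
                                     origin_default = "PEG", origin_brain = "PEG",
                                     chromosome_order = 1:3))
  mtr <- mean_expression_table(dsr, idsr, glr)
  for (g in c("A", "B")) {
    tg <- mean(m[lab == g, c(3, 7, 11)])
    rs <- mean(m[lab == g, -c(3, 7, 11)])
    expect_equal(mtr$mean_expr_tagged[mtr$group == g], tg)
    expect_equal(mtr$mean_expr_rest[mtr$group == g], rs)
  }
})

test_that("overlap partition is disjoint, exhaustive, and availability-aware", {
  u <- sprintf("u%d", 1:10)
  out <- overlap_partition(c("u1", "u2"), u, c("u2", "u3"), u)
  expect_equal(out$both, "u2")
  expect_equal(out$a_only, "u1")
  expect_equal(out$b_only, "u3")
  expect_equal(out$counts[["a_only_unavailable_in_b"]], 0L)
  # a gene absent from the other universe is classed unavailable, not a-only
  out2 <- overlap_partition(c("u1", "zz"), c(u, "zz"), "u2", u)
  expect_equal(out2$a_only_unavailable_in_b, "zz")
  expect_equal(out2$a_only, "u1")
  # completeness and disjointness on random sets
  set.seed(60)
  for (rep in 1:15) {
    ua <- sample(u, 7); ub <- sample(u, 7)
    sa <- sample(ua, 4); sb <- sample(ub, 4)
    o <- overlap_partition(sa, ua, sb, ub)
    classes <- o[c("both", "a_only", "b_only",
                   "a_only_unavailable_in_b", "b_only_unavailable_in_a")]
    expect_equal(sum(lengths(classes)), length(union(sa, sb)))
    expect_equal(sort(unlist(classes, use.names = FALSE)), sort(union(sa, sb)))
  }
  expect_error(overlap_partition("x", u, "u1", u), "outside universe_a")
})

test_that("parental split partitions the list and recomputes eligibility", {
  sim <- small_sim(seed = 31, enriched = "G2")
  ds <- normalize_library_size(filter_genes_min_cells(sim$dataset, 20))
  de <- run_de(ds, sim$identities)
  split <- parental_split_run(de, sim$gene_list, seed = 5, gsea = FALSE)
  expect_setequal(names(split), c("MEG", "PEG"))
  n_meg <- split$MEG$ora$universe_tagged[1]
  n_peg <- split$PEG$ora$universe_tagged[1]
  full <- run_ora(de, sim$gene_list)
  expect_equal(n_meg + n_peg, full$universe_tagged[1])   # partition covers once
  # tagged-up counts add across the partition
  expect_equal(split$MEG$ora$n_up_tagged + split$PEG$ora$n_up_tagged,
               full$n_up_tagged)
})

test_that("Igf2 and Grb10 switch origin partition between contexts", {
  generic <- split_by_origin(default_imprinted_genes("generic"))
  brain <- split_by_origin(default_imprinted_genes("brain"))
  expect_true("Igf2" %in% generic$PEG$gene_id)
  expect_true("Igf2" %in% brain$MEG$gene_id)
  expect_true("Grb10" %in% generic$MEG$gene_id)
  expect_true("Grb10" %in% brain$PEG$gene_id)
})
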