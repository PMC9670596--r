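test_that("ranking sorts by log2fc with deterministic lexicographic ties", {
  de <- fake_de(data.frame(gene = c("gb", "ga", "gc", "gd"), group = "G",
                           q = 0.01, log2fc = c(1, 3, 2, 1)))
  r <- rank_genes(de, "G", 2)
  expect_equal(r$gene, c("ga", "gc", "gb", "gd"))   # tie at 1: gb before gd
  expect_equal(r$weight, c(3, 2, 1, 1))
  expect_setequal(r$gene, upregulated_set(de, "G", 2))
  de0 <- fake_de(data.frame(gene = "ga", group = "G", q = 0.9, log2fc = 2))
  expect_error(rank_genes(de0, "G", 2), "inapplicable")
})

test_that("running-sum score matches hand-enumerated curves", {
  genes <- letters[1:5]
  top <- enrichment_score(data.frame(gene = genes, weight = 1), c("a", "b"))
  expect_equal(top$running_curve, c(0.5, 1, 2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(top$es, 1)
  expect_equal(top$leading_edge, c("a", "b"))
  mid <- enrichment_score(data.frame(gene = genes, weight = 1), c("b", "d"))
  expect_equal(mid$running_curve, c(-1/3, 1/6, -1/6, 1/3, 0), tolerance = 1e-12)
  expect_equal(mid$es, 1/3)
  expect_error(enrichment_score(data.frame(gene = genes, weight = 1), genes),
               "whole ranked list")
})

test_that("score conserves to zero, is scale-invariant, and floors at zero", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    w <- rexp(n) + 0.05
    ranked <- data.frame(gene = sprintf("g%02d", 1:n), weight = w)
    tg <- sample(ranked$gene, sample(seq_len(n - 1), 1))
    sc <- enrichment_score(ranked, tg)
    expect_equal(sc$running_curve[n], 0, tolerance = 1e-10)
    sc2 <- enrichment_score(transform(ranked, weight = weight * 13.7), tg)
    expect_equal(sc2$es, sc$es, tolerance = 1e-10)
    expect_gte(sc$es, 0)
  }
  # bottom-loaded set never rises above zero
  ranked <- data.frame(gene = letters[1:6], weight = 1)
  sc <- enrichment_score(ranked, c("e", "f"))
  expect_equal(sc$es, 0)
  expect_length(sc$leading_edge, 0)
})

test_that("weighted score equals a brute-force reimplementation on all placements", {
  set.seed(10)
  for (n in 4:8) {
    w <- rexp(n) + 0.1
    ranked <- data.frame(gene = sprintf("g%d", 1:n), weight = w)
    for (k in 1:(n - 1)) {
      placements <- combn(n, k)
      for (col in seq_len(ncol(placements))) {
        idx <- placements[, col]
        expect_equal(enrichment_score(ranked, ranked$gene[idx])$es,
                     es_bruteforce(w, idx), tolerance = 1e-12)
      }
    }
  }
})

test_that("permutation p attains its lower bound and matches exhaustive placement", {
  ranked <- data.frame(gene = letters[1:6], weight = c(6, 5, 4, 3, 2, 1))
  # an observed score strictly above every permuted score hits the floor
  es_top <- enrichment_score(ranked, c("a", "b"))$es   # the maximum, 1
  p <- permutation_p(ranked, 2, es_top + 1e-6, n_perm = 500, seed = 1)
  expect_equal(p, 1 / 501)
  # exhaustive distribution over the C(6,2) = 15 placements
  all_es <- combn(6, 2, function(idx) es_bruteforce(ranked$weight, idx))
  obs <- enrichment_score(ranked, c("b", "e"))$es
  exact_p <- mean(all_es >= obs - 1e-12)
  approx_p <- permutation_p(ranked, 2, obs, n_perm = 1e5, seed = 2)
  expect_lt(abs(approx_p - exact_p), 0.01)
  # identical seed reproduces, and the global RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  p1 <- permutation_p(ranked, 2, obs, n_perm = 200, seed = 5)
  p2 <- permutation_p(ranked, 2, obs, n_perm = 200, seed = 5)
  expect_identical(p1, p2)
  set.seed(99)
  expect_identical(rnorm(1), before)
})

test_that("GSEA eligibility gates on tagged count and mean fold change", {
  expect_true(gsea_eligibility(47, 11.88, 5.42))    # neuroendocrine-style row
  expect_false(gsea_eligibility(14, 20.0, 1.0))     # below the 15-gene floor
  expect_false(gsea_eligibility(44, 11.73, 24.97))  # tagged FC below the rest
})

test_that("run_gsea recovers planted top-loading and corrects across groups", {
  sim <- small_sim(seed = 23, enriched = "G2", enriched_fold = 6)
  ds <- normalize_library_size(filter_genes_min_cells(sim$dataset, 20))
  de <- run_de(ds, sim$identities)
  ora <- run_ora(de, sim$gene_list)
  gs <- run_gsea(de, sim$gene_list, ora = ora, min_tagged = 5,
                 n_perm = 2000, seed = 17)
  el <- gs[gs$eligible, ]
  expect_gte(nrow(el), 1)
  expect_true(all(el$p_gsea >= 1 / 2001 & el$p_gsea <= 1))
  expect_equal(el$q_gsea, pmin(1, nrow(el) * el$p_gsea))
  curves <- attr(gs, "curves")
  for (g in el$group) {
    expect_equal(length(curves[[g]]), el$n_ranked[el$group == g])
    expect_equal(max(0, max(curves[[g]])), el$es[el$group == g])
  }
})
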