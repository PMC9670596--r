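test_that("exact one-sided Wilcoxon matches full rank-assignment enumeration", {
  # fully separated samples: the most extreme of the C(6,3) = 20 assignments
  expect_equal(as.numeric(wilcoxon_one_sided(c(5, 6, 7), c(1, 2, 3))), 0.05)
  # independent oracle: enumerate every assignment of ranks to the first group
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(4); y <- rnorm(5)
    r <- rank(c(x, y))
    obs <- sum(r[1:4])
    sums <- combn(9, 4, function(idx) sum(r[idx]))
    expect_equal(as.numeric(wilcoxon_one_sided(x, y)),
                 mean(sums >= obs), tolerance = 1e-12)
  }
  # tied data: enumeration with midranks
  x <- c(0, 1, 1); y <- c(0, 0, 1)
  r <- rank(c(x, y))
  sums <- combn(6, 3, function(idx) sum(r[idx]))
  expect_equal(as.numeric(wilcoxon_one_sided(x, y)),
               mean(sums >= sum(r[1:3]) - 1e-9), tolerance = 1e-12)
})

test_that("Wilcoxon p respects symmetry, rank invariance and degeneracy", {
  set.seed(2)
  x <- rnorm(10); y <- rnorm(12)
  expect_gte(as.numeric(wilcoxon_one_sided(c(x, y), c(y, x))), 0.5)
  # monotone transform leaves ranks (hence p) unchanged
  a <- rexp(15); b <- rexp(15)
  expect_equal(as.numeric(wilcoxon_one_sided(a, b)),
               as.numeric(wilcoxon_one_sided(a^2, b^2)))
  pd <- wilcoxon_one_sided(rep(3, 5), rep(3, 7))
  expect_equal(as.numeric(pd), 1)
  expect_true(attr(pd, "degenerate"))
})

test_that("approximate branch matches the tie-corrected normal reference", {
  set.seed(8)
  for (rep in 1:10) {
    x <- rpois(40, 2); y <- rpois(60, 2)      # heavy ties
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater",
                         exact = FALSE, correct = TRUE)$p.value)
    expect_equal(as.numeric(wilcoxon_one_sided(x, y)), ref, tolerance = 1e-10)
  }
})

test_that("exact and approximate branches agree closely at n = 25 + 25", {
  set.seed(42)
  for (rep in 1:25) {
    x <- rnorm(25); y <- rnorm(25)
    d <- abs(wilcoxon_one_sided(x, y, exact = TRUE) -
               wilcoxon_one_sided(x, y, exact = FALSE))
    expect_lte(d, 0.01)
  }
})

test_that("BH adjustment equals an independent step-up implementation", {
  expect_equal(bh_adjust_horizontal(0.03), 0.03)
  expect_equal(bh_adjust_horizontal(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_identical(bh_adjust_horizontal(numeric(0)), numeric(0))
  set.seed(14)
  for (rep in 1:25) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust_horizontal(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_equal(order(q, p), order(p))   # q preserves the p ordering
  }
  expect_error(bh_adjust_horizontal(c(0.1, 0)), "0, 1")
})

test_that("fold changes match a direct two-pass mean computation", {
  set.seed(3)
  m <- matrix(rpois(30 * 12, 4), 30, 12) + 0.0
  ds <- toy_dataset(m, normalized = TRUE)
  lab <- setNames(rep(c("A", "B"), 15), ds$cell_ids)
  ids <- cell_identity_map(lab)
  fcs <- fold_changes(ds, ids, "A")
  for (j in c(1, 5, 12)) {
    mi <- mean(m[lab == "A", j]); mr <- mean(m[lab != "A", j])
    expect_equal(fcs$fc[j], (mi + 1e-9) / (mr + 1e-9))
    expect_equal(fcs$log2fc[j], log2(fcs$fc[j]))
  }
  # doubling the group mean gives log2fc = 1
  m2 <- cbind(c(rep(4, 15), rep(2, 15)))
  ds2 <- toy_dataset(m2, normalized = TRUE)
  fc2 <- fold_changes(ds2, cell_identity_map(setNames(rep(c("A", "B"), each = 15),
                                                      ds2$cell_ids)), "A")
  expect_equal(fc2$log2fc, 1, tolerance = 1e-8)
})

test_that("upregulation criteria hit their boundaries and nest across levels", {
  de <- fake_de(data.frame(
    gene = c("a", "b", "c", "d"), group = "G",
    q = c(0.05, 0.04, 0.051, 0.04),
    log2fc = c(1.0, 0.3, 2.0, -0.2)))
  expect_setequal(upregulated_set(de, "G", 2), "a")       # q = 0.05, lfc = 1 inclusive
  expect_setequal(upregulated_set(de, "G", 3), c("a", "b"))
  expect_setequal(upregulated_set(de, "G", 1), upregulated_set(de, "G", 2))
  set.seed(77)
  rnd <- fake_de(data.frame(gene = sprintf("g%d", 1:300), group = "G",
                            q = runif(300), log2fc = rnorm(300)))
  expect_true(all(upregulated_set(rnd, "G", 2) %in% upregulated_set(rnd, "G", 3)))
})

test_that("DE table is invariant to a global positive rescaling", {
  sim <- small_sim(seed = 19)
  ds <- normalize_library_size(filter_genes_min_cells(sim$dataset, 10))
  de1 <- run_de(ds, sim$identities)
  # a power-of-two factor rescales every float exactly, so ties are preserved
  # bit for bit and the ranks (hence p and q) are identical
  ds2 <- ds
  ds2$normalized <- ds$normalized * 8
  de2 <- run_de(ds2, sim$identities)
  expect_identical(de2$p, de1$p)
  expect_identical(de2$q, de1$q)
  # a non-dyadic factor can flip float ties in the last ulp; results agree up
  # to that tie-handling noise
  ds3 <- ds
  ds3$normalized <- ds$normalized * 7.3
  de3 <- run_de(ds3, sim$identities)
  expect_equal(de3$p, de1$p, tolerance = 5e-3)
  expect_equal(de3$log2fc, de1$log2fc, tolerance = 1e-6)
})

test_that("group-vs-rest p-values are approximately uniform with no effect", {
  sp <- synthetic_spec(n_genes = 2500, n_cells_per_group = 150,
                       group_labels = c("A", "B"), tagged_set_size = 10,
                       marker_genes_per_group = 0, enriched_group = NULL,
                       seed = 314)
  sim <- generate_synthetic(sp)
  ds <- normalize_library_size(filter_genes_min_cells(sim$dataset, 20))
  de <- run_de(ds, sim$identities)
  pa <- de$p[de$group == "A"]
  frac <- mean(pa <= 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / length(pa))
  expect_gte(frac, 0.05 - band)
  expect_lte(frac, 0.05 + band)
})
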