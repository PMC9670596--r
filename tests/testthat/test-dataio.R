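test_that("dense delimited read-back preserves entries and orientation", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell,g1,g2", "c1,1,0", "c2,0,2", "c3,5,5"), tmp)
  ds <- read_expression_matrix(tmp, format = "dense")
  expect_equal(c(n_cells(ds), n_genes(ds)), c(3L, 2L))
  expect_equal(as.numeric(ds$counts["c3", "g2"]), 5)
  # transpose flag: genes as rows
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2,c3", "g1,1,0,5", "g2,0,2,5"), tmp2)
  ds2 <- read_expression_matrix(tmp2, format = "dense", transpose = TRUE)
  expect_equal(as.matrix(ds2$counts), as.matrix(ds$counts))
})

test_that("Matrix Market triplet input fills implicit zeros", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 4"), mtx)
  writeLines(c("g1", "g2"), file.path(dir, "genes.txt"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.txt"))
  ds <- read_expression_matrix(mtx, file.path(dir, "genes.txt"),
                               file.path(dir, "cells.txt"))
  expect_equal(unname(as.matrix(ds$counts)), matrix(c(4, 0, 0, 0), 2, 2))
})

test_that("write/read round trip is lossless for both formats", {
  set.seed(101)
  m <- matrix(rpois(50 * 100, 0.6), 50, 100)
  ds <- toy_dataset(m)
  for (fmt in c("mtx", "dense")) {
    dir <- withr::local_tempdir()
    write_expression_dataset(ds, dir, format = fmt)
    back <- if (fmt == "mtx")
      read_expression_matrix(file.path(dir, "matrix.mtx"),
                             file.path(dir, "genes.txt"),
                             file.path(dir, "cells.txt"))
    else read_expression_matrix(file.path(dir, "matrix.csv"), format = "dense")
    expect_identical(as.matrix(back$counts), as.matrix(ds$counts))
    expect_identical(back$gene_ids, ds$gene_ids)
    expect_identical(back$cell_ids, ds$cell_ids)
  }
})

test_that("duplicate identifiers and dimension mismatches are hard errors", {
  m <- matrix(1, 2, 2)
  expect_error(expression_dataset(counts = m, gene_ids = c("g1", "g1"),
                                  cell_ids = c("c1", "c2")),
               "duplicate gene identifiers.*g1")
  expect_error(expression_dataset(counts = m, gene_ids = c("g1", "g2"),
                                  cell_ids = c("c1", "c1")),
               "duplicate cell identifiers.*c1")
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "3 2 1", "1 1 4"), mtx)
  writeLines(c("g1", "g2"), file.path(dir, "genes.txt"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.txt"))
  expect_error(read_expression_matrix(mtx, file.path(dir, "genes.txt"),
                                      file.path(dir, "cells.txt")),
               "no orientation fits")
})

test_that("gene list loading validates origins and honours context", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,origin_default,origin_brain,chromosome_order",
               "Igf2,PEG,MEG,1", "H19,MEG,MEG,2", "Peg3,PEG,PEG,3"), tmp)
  gl <- load_gene_list(tmp, context = "generic")
  expect_equal(nrow(gl), 3L)
  expect_equal(gl$gene_id, c("Igf2", "H19", "Peg3"))  # order preserved
  expect_equal(gl$origin[gl$gene_id == "Igf2"], "PEG")
  glb <- load_gene_list(tmp, context = "brain")
  expect_equal(glb$origin[glb$gene_id == "Igf2"], "MEG")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,origin_default,origin_brain,chromosome_order",
               "Igf2,PATERNAL,PEG,1"), bad)
  expect_error(load_gene_list(bad), "unknown parental-origin")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,origin_default,origin_brain,chromosome_order",
               "Igf2,,PEG,1"), bad2)
  expect_error(load_gene_list(bad2), "missing parental-origin")
})

test_that("shipped default list has 119 entries and tissue-variable genes", {
  gl <- default_imprinted_genes()
  expect_equal(nrow(gl), 119L)
  expect_false(anyDuplicated(gl$gene_id) > 0)
  expect_true(all(gl$origin %in% c("MEG", "PEG")))
  variable <- gl$gene_id[gl$origin_default != gl$origin_brain]
  expect_setequal(variable, c("Igf2", "Grb10"))
  # the origin-split partition covers the list exactly once
  parts <- split_by_origin(gl)
  expect_equal(sort(c(parts$MEG$gene_id, parts$PEG$gene_id)),
               sort(gl$gene_id))
})

test_that("library-size normalization scales, conserves, inverts, refuses twice", {
  ds <- toy_dataset(matrix(c(1, 1, 2,
                             10, 0, 30), 2, 3, byrow = TRUE))
  nds <- normalize_library_size(ds)
  expect_equal(as.numeric(nds$normalized["c1", ]), c(2500, 2500, 5000))
  expect_equal(unname(Matrix::rowSums(nds$normalized)), c(1e4, 1e4))
  expect_error(normalize_library_size(nds), "double normalization")
  # exact inversion from the stored totals
  set.seed(7)
  big <- toy_dataset(matrix(rpois(20 * 30, 2), 20, 30))
  nb <- normalize_library_size(big)
  rec <- Matrix::Diagonal(x = nb$cell_totals / 1e4) %*% nb$normalized
  expect_equal(as.matrix(rec), as.matrix(big$counts), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero-total cells dropped with a warning
  z <- toy_dataset(rbind(c(1, 2), c(0, 0)))
  expect_warning(nz <- normalize_library_size(z), "zero total")
  expect_equal(n_cells(nz), 1L)
})

test_that("identity attachment trims, intersects, and ignores row order", {
  ds <- toy_dataset(matrix(1, 3, 2))
  tab <- data.frame(cell = c(" c1", "c3 "), label = c("A ", " B"))
  expect_message(ids <- attach_identities(ds, tab), "1 dataset cell")
  expect_equal(ids$assignments, c(c1 = "A", c3 = "B"))
  ids2 <- suppressMessages(attach_identities(ds, tab[2:1, ]))
  expect_equal(sort(names(ids2$assignments)), sort(names(ids$assignments)))
  expect_equal(ids2$assignments[names(ids$assignments)], ids$assignments)
  expect_error(attach_identities(ds, data.frame(cell = "zz", label = "A")),
               "no cell identifier")
})
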