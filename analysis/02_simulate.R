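#!/usr/bin/env Rscript
# Simulate a single-cell dataset with planted imprinted-gene enrichment.
#
# Negative-binomial counts for 6 identity groups; each group gets its own
# marker genes (fold 4), and group G2 additionally upregulates 30% of the
# tagged set at fold 3 — the situation the enrichment workflow is meant to
# detect. Matrices are written in the same Matrix Market + sidecar format the
# loader reads, so the downstream scripts exercise the full I/O path.
# (2,000 genes and 150 cells per group keep the demo quick; the generator
# defaults are larger.)

suppressPackageStartupMessages(library(igenrich))
outdir <- "scratch/synthetic_demo"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(
  n_genes = 2000, n_cells_per_group = 150,
  group_labels = paste0("G", 1:6),
  tagged_set_size = 100, tagged_fraction_meg = 0.5,
  marker_genes_per_group = 50, marker_fold = 4,
  enriched_group = "G2", enriched_tagged_fraction = 0.3, enriched_fold = 3,
  seed = 20260920)

sim <- generate_synthetic(spec)

write_expression_dataset(sim$dataset, outdir, format = "mtx")
data.table::fwrite(data.frame(cell_id = names(sim$identities$assignments),
                              label = sim$identities$assignments),
                   file.path(outdir, "identities.csv"))
data.table::fwrite(as.data.frame(sim$gene_list)[
  , c("gene_id", "origin_default", "origin_brain", "chromosome_order")],
  file.path(outdir, "gene_list.csv"))
data.table::fwrite(sim$truth, file.path(outdir, "truth.csv"))

cat(sprintf("Simulated %d cells x %d genes; tagged set %d (%d MEG / %d PEG)\n",
            n_cells(sim$dataset), n_genes(sim$dataset),
            nrow(sim$gene_list),
            sum(sim$gene_list$origin == "MEG"),
            sum(sim$gene_list$origin == "PEG")))
planted <- sum(sim$truth$G2 == spec$enriched_fold)
cat(sprintf("Planted: %d markers/group at fold %g; %d tagged genes at fold %g in G2\n",
            spec$marker_genes_per_group, spec$marker_fold,
            planted, spec$enriched_fold))
cat("Wrote matrix + metadata under", outdir, "\n")
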