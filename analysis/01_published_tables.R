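#!/usr/bin/env Rscript
# Desk recomputation of the published over-representation tables.
#
# The five tables of per-identity-group counts shipped with the package
# (upregulated genes, upregulated imprinted genes, dataset totals) are enough
# to rebuild every printed ORA statistic: the 5% eligibility gate decides
# which groups get a p-value, the one-sided Fisher's exact test gives p, and
# Bonferroni over each table's eligible groups gives q. No expression data
# are touched.

suppressPackageStartupMessages(library(igenrich))
dir.create("results", showWarnings = FALSE)

rec <- recompute_published_ora(load_published_counts())
rec$p_3sf <- ifelse(is.na(rec$p), "--", format(signif(rec$p, 3)))
rec$q_3sf <- ifelse(is.na(rec$q), "--", format(signif(rec$q, 3)))

data.table::fwrite(rec, "results/published_ora_recomputed.csv")

cat("Eligible groups per table (Bonferroni multipliers):\n")
print(tapply(rec$eligible, rec$table_id, sum))

cat("\nEligibility pattern matches the printed '--' cells:",
    all(rec$eligible == (rec$printed_p != "--")), "\n")

sig <- rec[!is.na(rec$q) & rec$q < 0.05, ]
cat("\nGroups significant after Bonferroni (q < 0.05):\n")
print(sig[, c("table_id", "group", "up_reg", "ig_up", "p_3sf", "q_3sf")],
      row.names = FALSE)

cat("\nWrote results/published_ora_recomputed.csv\n")
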