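#!/usr/bin/env Rscript
# Stage 5: concordance of molecular vs morphological node-age estimates.
#
# Reads the dating summaries produced by stage 4 and reports, per
# calibration strategy, the through-origin regression of morphological on
# molecular posterior mean ages, the fraction of morphological estimates
# inside the molecular 95% HPDs, and the per-data-type precision.

suppressPackageStartupMessages(library(morphoclock))

read_summary <- function(s, subset)
  read.delim(sprintf("results/pipeline/dating_%s_%s.tsv", s, subset))

root_node <- 21L  # 20 tips
for (s in c("Cr", "C1", "C2")) {
  rep_s <- concordance_report(read_summary(s, "mol"), read_summary(s, "morph"),
                              exclude_root = identical(s, "Cr"),
                              root_node = root_node)
  cat(sprintf("strategy %-3s slope = %.3f  R2 = %.3f  r = %.3f  morph-in-mol coverage = %.0f%%\n",
              s, rep_s$regression$slope, rep_s$regression$r_squared,
              rep_s$regression$r, rep_s$coverage_y_in_x_pct))
  cat(sprintf("              mean %%HPD width: mol %.0f%%, morph %.0f%%\n",
              rep_s$mean_rel_width_x, rep_s$mean_rel_width_y))
  write.table(rep_s$scatter, sprintf("results/concordance_scatter_%s.tsv", s),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

cat("\nCombined vs molecular (C1):\n")
rep_c <- concordance_report(read_summary("C1", "mol"),
                            read_summary("C1", "combined"),
                            exclude_root = FALSE, root_node = root_node)
cat(sprintf("  slope = %.3f  R2 = %.3f  coverage = %.0f%%\n",
            rep_c$regression$slope, rep_c$regression$r_squared,
            rep_c$coverage_y_in_x_pct))
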