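#!/usr/bin/env Rscript
# Full-cohort screen: Spearman correlations between every spine feature
# (overall and per class) and cognition/pathology scores, with Storey
# q-value FDR control at 10% and a stringent 5% level, per region.  Writes
# the long-format grid and heatmap-shaped matrices.

suppressPackageStartupMessages(library(spinecog))

features <- data.table::fread("results/features.csv")
feature_cols <- c("mean_density", "mean_length", "mean_head_diameter",
                  "mean_volume",
                  paste0(rep(spine_classes(), each = 4), "_",
                         c("density", "length", "head_diameter", "volume")))
score_cols <- c("episodic_memory", "np_score", "nft_burden", "age")

for (region in c("BA37", "BA6")) {
  at <- data.table::fread(sprintf("results/analysis_%s.csv", region))
  scores <- at[, c("case_id", score_cols), with = FALSE]
  keep <- which(features[["region"]] == region)
  grid <- correlation_matrix(features[keep], scores,
                             feature_cols, score_cols,
                             fdr_levels = c(0.1, 0.05))
  data.table::fwrite(grid, sprintf("results/correlations_%s.csv", region))
  rho <- correlation_heatmap_matrix(grid, "rho")
  ann <- correlation_heatmap_matrix(grid, "annotation")
  write.csv(rho, sprintf("results/heatmap_rho_%s.csv", region))
  write.csv(ann, sprintf("results/heatmap_annotation_%s.csv", region))
  n_len <- sum(grid$sig_lenient, na.rm = TRUE)
  n_str <- sum(grid$sig_stringent, na.rm = TRUE)
  cat(sprintf("%s: %d/%d cells significant at q<0.1 (%d at q<0.05), pi0 = %.2f\n",
              region, n_len, sum(!is.na(grid$q_value)), n_str,
              attr(grid, "pi0")))
  hd <- grid[grid$feature == "mean_head_diameter" &
               grid$score == "episodic_memory"]
  cat(sprintf("  head diameter x episodic memory: rho = %.3f, q = %.3g %s\n",
              hd$rho, hd$q_value, hd$annotation))
}
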