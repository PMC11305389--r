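#!/usr/bin/env Rscript
# Validation stage: compare nested linear models for episodic memory on each
# region's validation half by leave-one-out cross-validation, with bootstrap
# percentile intervals on each model's LOOCV MSE.  The smallest-MSE model
# best predicts episodic memory.

suppressPackageStartupMessages(library(spinecog))

B <- 1000

for (region in c("BA37", "BA6")) {
  val <- data.table::fread(sprintf("results/validation_%s.csv", region))
  cmp <- compare_models(val)
  tab <- cmp$comparison
  ci_lo <- ci_hi <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ci <- bootstrap_mse_ci(val, cmp$reports[[i]]$spec, B = B,
                           level = 0.90, seed = 111 + i)
    ci_lo[i] <- ci$lower; ci_hi[i] <- ci$upper
  }
  tab[, "mse_ci90_lower" := ci_lo]
  tab[, "mse_ci90_upper" := ci_hi]
  data.table::fwrite(tab, sprintf("results/model_comparison_%s.csv",
                                  region))
  preds <- data.table::rbindlist(lapply(cmp$reports, function(r)
    cbind(model = r$spec$name, r$predictions)))
  data.table::fwrite(preds,
                     sprintf("results/observed_predicted_%s.csv", region))
  cat(sprintf("%s nested-model LOOCV comparison (n = %d):\n",
              region, tab$n_used[1]))
  print(as.data.frame(tab), digits = 4)
  cat(sprintf("  best model: %s (MSE-CV %.4f, R2 %.3f)\n\n",
              tab$model[1], tab$loocv_mse[1], tab$r_squared[1]))
}
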