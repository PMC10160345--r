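#!/usr/bin/env Rscript

# Step 4 — compare the trained models against the retention-factor baselines.
#
# Reads the tables written by analysis/03_train_models.R and reports, per
# process class: how often the model beats the RF-table and RF100 baselines,
# the relative improvement in RMSE, and the per-category breakdown of pooled
# out-of-fold predictions for the best arm (SCS for wet heat,
# PINS-cholesterol for dry heat).

library(nutricook)
library(dplyr)

exp_dir <- "results/experiment"
if (!file.exists(file.path(exp_dir, "win_loss.csv"))) {
  stop("run analysis/03_train_models.R first")
}
rd <- function(f) readr::read_csv(file.path(exp_dir, f), show_col_types = FALSE)

wl <- rd("win_loss.csv")
cat("-- model vs baseline win counts --\n")
print(as.data.frame(wl))

for (pc in c("WH", "DH")) {
  t2 <- rd(paste0("table2_", pc, ".csv"))
  cat(sprintf("\n-- %s best arm (%s): model vs baselines --\n", pc, t2$variant[1]))
  print(as.data.frame(t2[, c("nutrient", "model_rmse", "rftable_rmse", "rf100_rmse",
                             "rel_vs_rftable", "rel_vs_rf100")]), digits = 3)
  cat(sprintf("mean RMSE improvement vs RF table: %.1f%%; vs RF100: %.1f%%\n",
              mean(t2$rel_vs_rftable), mean(t2$rel_vs_rf100)))
}

cat("\n-- per-category mean R2 of pooled out-of-fold predictions --\n")
for (pc in c("WH", "DH")) {
  bc <- rd(paste0("table3_by_category_", pc, ".csv"))
  cat(pc, "(all nutrients):\n")
  print(as.data.frame(bc), digits = 3)
  bcr <- rd(paste0("table3_by_category_reliable_", pc, ".csv"))
  cat(pc, "(reliable-nutrient subset):\n")
  print(as.data.frame(bcr), digits = 3)
}
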