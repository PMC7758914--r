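#!/usr/bin/env Rscript
# Stage 3: compact reporting. Compares the DIC selection and trend
# classification against the generating truth, writes small summary tables
# under results/analysis/, and annotates the block map with trend
# categories for choropleth use.

suppressMessages(library(bymtrends))

run_dir <- "scratch/analysis/run"
out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

summary <- utils::read.csv(file.path(run_dir, "combined_summary.csv"))
truth <- utils::read.csv("scratch/analysis/data/truth.csv")

cat("== DIC selection vs generating truth ==\n")
truth_inter <- tapply(truth$true_or, truth$indicator_id,
                      function(or) diff(range(or)) > 1e-9)
summary$truth_interaction <- truth_inter[summary$indicator_id]
print(summary[, c("indicator_id", "interaction_selected",
                  "truth_interaction", "dic_no_int", "dic_int",
                  "n_increase", "n_decrease", "n_indeterminate")],
      row.names = FALSE)

cat("\n== trend classification vs true per-block OR ==\n")
rows <- list()
for (id in summary$indicator_id) {
  tr <- utils::read.csv(file.path(run_dir, id, "trends.csv"))
  tt <- truth[truth$indicator_id == id, c("block_id", "true_or")]
  m <- merge(tr, tt, by = "block_id")
  up <- m$true_or > 1 + 1e-9; dn <- m$true_or < 1 - 1e-9
  rows[[id]] <- data.frame(
    indicator_id = id,
    blocks = nrow(m),
    true_rising = sum(up), called_increase = sum(m$category == "increase"),
    true_declining = sum(dn), called_decrease = sum(m$category == "decrease"),
    sign_accuracy = round(mean(
      sign(m$or_point - 1)[up | dn] == sign(m$true_or - 1)[up | dn]), 3))
  utils::write.csv(m[, c("indicator_id", "block_id", "or_point", "lo", "hi",
                         "category", "true_or")],
                   file.path("scratch/analysis",
                             paste0("trends_", id, ".csv")),
                   row.names = FALSE)
}
cls <- do.call(rbind, rows)
print(cls, row.names = FALSE)
utils::write.csv(cls, file.path(out_dir, "classification_vs_truth.csv"),
                 row.names = FALSE)
utils::write.csv(summary, file.path(out_dir, "combined_summary.csv"),
                 row.names = FALSE)

# choropleth-ready map for the indicator with the strongest interaction
pick <- summary$indicator_id[which.max(summary$dic_no_int - summary$dic_int)]
tr <- utils::read.csv(file.path(run_dir, pick, "trends.csv"))
write_trends_geojson("scratch/analysis/data/blocks.geojson", tr,
                     file.path("scratch/analysis", paste0("map_", pick, ".geojson")))
cat("\nannotated map for '", pick, "' written under scratch/analysis/\n",
    sep = "")
cat("summary tables written under ", out_dir, "\n", sep = "")
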