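#!/usr/bin/env Rscript
# Compute every outcome measure on the serialized cohort: reach test scores
# per direction, workspace polygon areas, COP excursion/velocity/entropy,
# high-intense-activity rate, reach task scores and questionnaire scores.
# Writes results/metric_table.csv.

suppressPackageStartupMessages(library(starsit))

cohort <- read_cohort(file.path("results", "cohort"))
cat(sprintf("Loaded cohort of %d subjects.\n", length(cohort$subjects)))

mt <- compute_metric_table(cohort)
utils::write.csv(mt, file.path("results", "metric_table.csv"),
                 row.names = FALSE)
cat(sprintf("Metric table: %d rows, %d metrics -> results/metric_table.csv\n",
            nrow(mt), length(unique(mt$metric))))

cat("\nGroup means of headline measures:\n")
for (m in c("frts_mean", "workspace_area", "hiar", "reach_task_score")) {
  d <- mt[mt$metric == m, ]
  key <- if (all(is.na(d$time))) d$group else paste(d$group, d$time)
  cat(sprintf("%-18s %s\n", m,
              paste(sprintf("%s=%.3f", names(tapply(d$value, key, mean)),
                            tapply(d$value, key, mean)), collapse = "  ")))
}
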