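#!/usr/bin/env Rscript
# Run the statistics layer on the computed metric table: split-plot ANOVAs
# (arm x test time) for the pre/post measures, one-way ANOVAs for the
# training-intensity and questionnaire measures, Bonferroni post-hocs gated
# on the omnibus tests, and Levene / Shapiro-Wilk diagnostics.

suppressPackageStartupMessages(library(starsit))

mt <- utils::read.csv(file.path("results", "metric_table.csv"),
                      stringsAsFactors = FALSE)
st <- run_stats(mt)

for (nm in names(st)) {
  if (!is.null(st[[nm]])) {
    utils::write.csv(st[[nm]],
                     file.path("results", paste0(nm, "_results.csv")),
                     row.names = FALSE)
  }
}
cat("Wrote anova/within/posthoc/diagnostics tables under results/.\n\n")

an <- st$anova
key <- an[an$metric %in% c("frts_mean", "workspace_area", "cop_apen",
                           "ssq", "hiar", "reach_task_score"), ]
cat("Key effects:\n")
print(key[, c("metric", "effect", "df_num", "df_den", "F", "p",
              "partial_eta_sq")], digits = 3, row.names = FALSE)

ph <- st$posthoc
ws <- ph[ph$metric == "workspace_area", ]
cat("\nWorkspace-area change, pairwise arms (Bonferroni):\n")
print(ws[, c("group1", "group2", "p_adj", "omnibus_significant")],
      digits = 3, row.names = FALSE)
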