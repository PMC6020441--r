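#!/usr/bin/env Rscript
# Pool weighted carrier proportions across cohorts per gene group with the
# Freeman-Tukey random-effects meta-analysis; write the forest table (the
# tabular twin of a forest plot).

suppressPackageStartupMessages(library(carrierburden))

gc <- default_gene_config()
dir.create("results", showWarnings = FALSE)

run_meta <- function(summaries, label) {
  rows <- list(); forest <- list()
  for (g in unique(summaries$group_name)) {
    sg <- summaries[summaries$group_name == g, ]
    studies <- data.frame(study_id = sg$cohort_id, x = sg$weighted_x, n = sg$n)
    rows[[g]] <- meta_proportion(studies, group_name = g)
    forest[[g]] <- forest_table(studies, group_name = g)
  }
  meta <- do.call(rbind, rows); rownames(meta) <- NULL
  write_results(meta, sprintf("results/%s_meta_results.tsv", label), "tsv")
  write_results(do.call(rbind, forest),
                sprintf("results/%s_forest_table.tsv", label), "tsv")
  meta
}

fx <- table1_fixture()
tri <- triage_cohort(fx$variants, gc, fx$cohorts)
meta_fx <- run_meta(tri$summaries, "fixture")
all_row <- meta_fx[meta_fx$group_name == "ALL", ]
message(sprintf(
  "Fixture pooled carrier proportion (all genes, 3 cohorts): %.1f%% (95%% CI %.1f-%.1f), tau2 = %.4f, I2 = %.0f%%, p = %.2g.",
  all_row$pooled_percent, all_row$ci_low, all_row$ci_high,
  all_row$tau2, all_row$I2, all_row$p_value))

if (file.exists("results/sim_cohort_summaries.tsv")) {
  s <- utils::read.delim("results/sim_cohort_summaries.tsv")
  meta_sim <- run_meta(s, "sim")
  hm <- meta_sim[meta_sim$group_name == "high_plus_moderate", ]
  if (nrow(hm)) {
    message(sprintf(
      "Simulated pooled high+moderate burden: %.1f%% (95%% CI %.1f-%.1f).",
      hm$pooled_percent, hm$ci_low, hm$ci_high))
  }
} else {
  message("No simulated summaries found; run analysis/02_triage_burden.R first.")
}
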