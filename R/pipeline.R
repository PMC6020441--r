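# Orchestration: triage -> per-cohort burden -> per-group meta-analysis ->
# SIR versus the reference population, with optional artifact output
# (summaries, forest table, SIR table, exclusion ledger, run log).

#' Proportion of identified carriers not qualifying for genetic testing
#'
#' Among carriers for whom family-history data are available, the fraction
#' that would not have met family-history-based testing criteria -- the gap
#' that sentinel-cancer testing closes.
#'
#' @param n_carriers carriers with family-history data.
#' @param n_qualifying of those, the number meeting testing criteria.
#' @return percent of carriers not qualifying.
#' @export
eligibility_gap <- function(n_carriers, n_qualifying) {
  stopifnot(n_carriers > 0, n_qualifying >= 0, n_qualifying <= n_carriers)
  100 * (n_carriers - n_qualifying) / n_carriers
}

#' Run the full carrier-burden pipeline
#'
#' Triage all variant observations, summarize weighted carrier burden per
#' cohort and gene group, pool proportions across cohorts per group with the
#' random-effects meta-analysis, and (when a reference summary is supplied)
#' compute standardized incidence ratios per group. When `out_dir` is given,
#' writes `cohort_summaries.tsv`, `forest_table.tsv`, `meta_results.tsv`,
#' `sir_table.tsv`, `exclusion_ledger.tsv` and a machine-readable
#' `run_log.json`; given identical inputs the outputs are identical.
#'
#' @param variants annotated variant table (see [read_variant_table()]).
#' @param gene_config gene-panel configuration (see [read_gene_config()]).
#' @param cohorts cohort manifest data.frame (`cohort_id`, `n`).
#' @param reference optional reference summary (see
#'   [read_reference_summary()]).
#' @param level confidence level.
#' @param maf_threshold allele-frequency exclusion threshold.
#' @param out_dir optional output directory (created if needed).
#' @return list with `cohort_summaries`, `carriers`, `exclusions`,
#'   `meta_results`, `forest`, `sir` (NULL without a reference), and
#'   `params`.
#' @export
run_pipeline <- function(variants, gene_config, cohorts, reference = NULL,
                         level = 0.95, maf_threshold = 0.001,
                         out_dir = NULL) {
  tri <- triage_cohort(variants, gene_config, cohorts,
                       maf_threshold = maf_threshold, level = level)
  s <- tri$summaries

  group_names <- unique(s$group_name)
  meta_rows <- list(); forest_rows <- list()
  for (g in group_names) {
    sg <- s[s$group_name == g, , drop = FALSE]
    studies <- data.frame(study_id = sg$cohort_id, x = sg$weighted_x,
                          n = sg$n, stringsAsFactors = FALSE)
    meta_rows[[g]] <- meta_proportion(studies, level, group_name = g)
    forest_rows[[g]] <- forest_table(studies, level, group_name = g)
  }
  meta_results <- do.call(rbind, meta_rows)
  forest <- do.call(rbind, forest_rows)
  rownames(meta_results) <- rownames(forest) <- NULL

  sir <- NULL
  if (!is.null(reference)) {
    n_cases <- sum(cohorts$n)
    agg <- stats::aggregate(weighted_x ~ group_name, data = s, FUN = sum)
    sir <- sir_table(agg, n_cases, reference, level)
  }

  params <- list(level = level, maf_threshold = maf_threshold,
                 n_cohorts = nrow(cohorts), n_cases = sum(cohorts$n),
                 n_variant_rows = nrow(variants),
                 n_excluded = nrow(tri$exclusions),
                 exclusion_counts = as.list(table(tri$exclusions$exclusion_reason)),
                 package_version = as.character(utils::packageVersion("carrierburden")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(s, file.path(out_dir, "cohort_summaries.tsv"), "tsv")
    write_results(forest, file.path(out_dir, "forest_table.tsv"), "tsv")
    write_results(meta_results, file.path(out_dir, "meta_results.tsv"), "tsv")
    if (!is.null(sir)) {
      write_results(sir, file.path(out_dir, "sir_table.tsv"), "tsv")
    }
    write_results(tri$exclusions,
                  file.path(out_dir, "exclusion_ledger.tsv"), "tsv")
    jsonlite::write_json(params, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cohort_summaries = s, carriers = tri$carriers,
       exclusions = tri$exclusions, meta_results = meta_results,
       forest = forest, sir = sir, params = params)
}
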