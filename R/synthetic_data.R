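# Synthetic cohort and reference-population generator. Emulates the
# statistical structure the pipeline assumes -- per-individual carrier draws
# per gene group, variant annotations the triage rules will classify as
# intended, filter-fodder contamination variants, and a large reference
# population -- so every stage is testable without external data. No
# sequence-level realism is attempted.

#' Build a simulation configuration
#'
#' A single integer seed governs all random streams; independent substream
#' seeds for the cohort and reference draws are derived from it
#' deterministically, so the two are jointly reproducible but independent.
#'
#' Defaults mirror the study conditions the pipeline targets: three
#' panel-tested case cohorts of 66, 147 and 61, per-group carrier
#' proportions of a few percent, a roughly 60:40 pathogenic:HiP-VUS mix
#' among true carrier variants, and a reference population of 49,451.
#'
#' @param seed integer master seed.
#' @param cohorts data.frame with `cohort_id` and `n`.
#' @param carrier_probs named numeric: true carrier proportion per gene
#'   group (group names must match the gene-panel config used downstream).
#' @param pathogenic_mix probability a true carrier variant is clearly
#'   pathogenic (truncating, non-final exon); the rest are HiP-VUS.
#' @param hip_splice_frac among HiP-VUS, fraction that are canonical splice
#'   variants with predicted effect (weight 0.97); the rest are missense
#'   judged by the in-silico consensus.
#' @param predictor_severity_hip,predictor_severity_benign per-predictor
#'   probability of a severe call for true HiP-VUS missense variants and for
#'   benign contamination missense variants.
#' @param contamination_rate probability an individual additionally carries
#'   a filter-fodder variant (common, benign-asserted, or silent).
#' @param reference list with `n_ref` and named `carrier_probs` per group.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              cohorts = data.frame(
                                cohort_id = c("sim_a", "sim_b", "sim_c"),
                                n = c(66L, 147L, 61L),
                                stringsAsFactors = FALSE),
                              carrier_probs = c(high_risk_HBOC = 0.027,
                                                LS_MMR = 0.013,
                                                other_high_risk = 0.012,
                                                moderate_HRR_BC = 0.035),
                              pathogenic_mix = 0.6,
                              hip_splice_frac = 0.15,
                              predictor_severity_hip = 0.9,
                              predictor_severity_benign = 0.15,
                              contamination_rate = 0.3,
                              reference = list(
                                n_ref = 49451L,
                                carrier_probs = c(high_risk_HBOC = 0.010,
                                                  LS_MMR = 0.005,
                                                  other_high_risk = 0.005,
                                                  moderate_HRR_BC = 0.015))) {
  probs <- c(carrier_probs, pathogenic_mix, hip_splice_frac,
             predictor_severity_hip, predictor_severity_benign,
             contamination_rate, reference$carrier_probs)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0,1]")
  stopifnot(is.data.frame(cohorts), all(cohorts$n > 0), reference$n_ref > 0)
  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 carrier_probs = carrier_probs,
                 pathogenic_mix = pathogenic_mix,
                 hip_splice_frac = hip_splice_frac,
                 predictor_severity_hip = predictor_severity_hip,
                 predictor_severity_benign = predictor_severity_benign,
                 contamination_rate = contamination_rate,
                 reference = reference),
            class = "sim_config")
}

# Substream seeds derived from the master seed; kept inside 32-bit range.
.substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629) + 1L
}

.blank_variant_row <- function(individual_id, cohort_id, gene, tag) {
  data.frame(individual_id = individual_id, cohort_id = cohort_id,
             gene = gene, hgvs_c = tag, hgvs_p = NA_character_,
             consequence = "missense", exon_index = NA_integer_,
             exon_count = NA_integer_, pop_afs = "", clinvar = "",
             agvgd = "missing", mapp = "missing", polyphen2 = "missing",
             cadd = "missing", prior_p = NA_real_,
             splice_effect_predicted = "unknown", functional_assay = "none",
             splice_demonstrated = FALSE, weight_override = NA_real_,
             stringsAsFactors = FALSE)
}

.draw_predictor_calls <- function(p_severe) {
  ifelse(stats::runif(4) < p_severe, "severe", "not_severe")
}

#' Simulate annotated variant tables for case cohorts
#'
#' Each individual independently carries a group-g variant with the
#' configured probability. Carrier variants are annotated so the triage
#' rules classify them as intended: truncating variants sit outside the
#' final exon (weight 1); HiP-VUS are either canonical splice variants with
#' predicted effect (0.97) or missense variants whose four predictor calls
#' are drawn from the severity profile (so a missense intended as HiP-VUS
#' can still fail the 3-of-4 consensus, as in real data). Contamination
#' variants carry common allele frequencies, benign assertions, or are
#' silent without splice effect, and should be removed by the filters.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @param gene_config gene-panel configuration from [read_gene_config()];
#'   group names must cover `config$carrier_probs`.
#' @return list with `variants` (canonical-dialect data.frame) and
#'   `cohorts` (the manifest). Deterministic given `config$seed`.
#' @export
simulate_cohort <- function(config, gene_config) {
  stopifnot(inherits(config, "sim_config"))
  group_names <- names(config$carrier_probs)
  gene_sets <- lapply(group_names, function(g) group_genes(gene_config, g))
  names(gene_sets) <- group_names
  all_genes <- unique(unlist(gene_sets))

  set.seed(.substream_seed(config$seed, 1L))
  rows <- vector("list", 0L)
  vid <- 0L
  for (ci in seq_len(nrow(config$cohorts))) {
    cid <- config$cohorts$cohort_id[ci]
    for (ind in seq_len(config$cohorts$n[ci])) {
      ind_id <- sprintf("%s_I%04d", cid, ind)
      for (g in group_names) {
        if (stats::runif(1) >= config$carrier_probs[[g]]) next
        vid <- vid + 1L
        gene <- sample(gene_sets[[g]], 1L)
        row <- .blank_variant_row(ind_id, cid, gene, sprintf("c.sim%05d", vid))
        if (stats::runif(1) < config$pathogenic_mix) {
          row$consequence <- sample(c("frameshift", "nonsense"), 1L)
          row$exon_count <- 20L
          row$exon_index <- sample(1:19, 1L)  # never the final exon
        } else if (stats::runif(1) < config$hip_splice_frac) {
          row$consequence <- "canonical_splice"
          row$splice_effect_predicted <- "yes"
        } else {
          calls <- .draw_predictor_calls(config$predictor_severity_hip)
          row$agvgd <- calls[1]; row$mapp <- calls[2]
          row$polyphen2 <- calls[3]; row$cadd <- calls[4]
        }
        rows[[length(rows) + 1L]] <- row
      }
      if (stats::runif(1) < config$contamination_rate) {
        vid <- vid + 1L
        gene <- sample(all_genes, 1L)
        row <- .blank_variant_row(ind_id, cid, gene, sprintf("c.sim%05d", vid))
        kind <- sample(c("common", "benign", "silent"), 1L)
        if (kind == "common") {
          # two-component MAF mixture: contamination draws the common arm
          row$pop_afs <- sprintf("NFE=%0.6f", stats::runif(1, 0.001, 0.05))
          calls <- .draw_predictor_calls(config$predictor_severity_benign)
          row$agvgd <- calls[1]; row$mapp <- calls[2]
          row$polyphen2 <- calls[3]; row$cadd <- calls[4]
        } else if (kind == "benign") {
          row$clinvar <- "benign=2;likely_benign=1"
        } else {
          row$consequence <- sample(c("synonymous", "intronic"), 1L)
          row$splice_effect_predicted <- "no"
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    .blank_variant_row(character(0), character(0), character(0), character(0))
  rownames(variants) <- NULL
  list(variants = variants, cohorts = config$cohorts)
}

#' Simulate a reference-population carrier summary
#'
#' Binomial draws of weighted carriers per gene group at the configured
#' reference proportions; deterministic given the master seed and
#' independent of the cohort stream.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return list with `n_ref` and named `weighted_carriers_by_group`, the
#'   format [read_reference_summary()] returns.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, 2L))
  probs <- config$reference$carrier_probs
  counts <- vapply(probs, function(p) {
    as.numeric(stats::rbinom(1L, config$reference$n_ref, p))
  }, numeric(1))
  list(n_ref = config$reference$n_ref,
       weighted_carriers_by_group = counts)
}

#' Packaged fixture of published per-variant carrier weights
#'
#' Twenty-seven variant observations across three panel-tested pancreatic
#' cancer cohorts (6 + 13 + 8 variants; n = 66, 147, 61), annotated so the
#' triage rules reproduce each published carrier weight. Two same-individual
#' variant pairs share `individual_id`. Two published weights that no triage
#' rule reaches (a CHEK2 missense at 0.95 and a CDKN2A missense at 1) are
#' carried as explicit `weight_override` values and flagged by the engine;
#' one RAD50 missense published without a weight is annotated to fail the
#' in-silico consensus (weight 0).
#'
#' @return list with `variants` (annotated variant table), `cohorts`
#'   (manifest: c34/n=66, c59/n=147, c14/n=61) and `printed_weights`
#'   (per-row published weight; `NA` for the two rows published without an
#'   individual weight).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_variants.tsv",
                      package = "carrierburden", mustWork = TRUE)
  variants <- read_variant_table(path, dialect = "tsv")
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  cohorts <- data.frame(cohort_id = c("c34", "c59", "c14"),
                        n = c(66L, 147L, 61L), stringsAsFactors = FALSE)
  list(variants = variants, cohorts = cohorts,
       printed_weights = as.numeric(raw$printed_weight))
}

#' Packaged gene-panel configuration
#'
#' Gene groups and risk tiers used throughout the examples and tests:
#' high-risk HBOC (BRCA1, BRCA2, PALB2), Lynch-syndrome mismatch-repair
#' genes, other high-risk genes (TP53, CDKN2A, STK11, APC), the
#' moderate-risk HRR breast-cancer genes (ATM, BARD1, CHEK2, NBN), an
#' interstrand-crosslink-repair group, and aggregate groups for the
#' high-risk and high-plus-moderate analyses.
#'
#' @return gene-panel configuration (see [read_gene_config()]).
#' @export
default_gene_config <- function() {
  read_gene_config(system.file("extdata", "gene_panel.yaml",
                               package = "carrierburden", mustWork = TRUE))
}
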