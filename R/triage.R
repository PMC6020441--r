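# Variant triage: exclusion filters, classification rules, carrier weights,
# and per-individual combination. Weights are probability-like values in
# [0, 1]; clearly pathogenic variants get 1, high-probability-of-pathogenicity
# VUS (HiP-VUS) get fractional weights.

WEIGHT_CONSENSUS <- 0.81   # >= 3 of 4 in-silico predictors severe
WEIGHT_SPLICE <- 0.97      # canonical splice, predicted effect, not demonstrated
WEIGHT_FUNCTIONAL <- 0.99  # missense shown damaging in a functional assay
PRIOR_P_CUTOFF <- 0.8      # calibrated prior must exceed this to count

TRIAGE_CATEGORIES <- c("PATHOGENIC_TRUNCATING", "PATHOGENIC_ASSERTED",
                       "HIP_VUS_PRIOR", "HIP_VUS_CONSENSUS", "HIP_VUS_SPLICE",
                       "HIP_VUS_FUNCTIONAL", "EXCLUDED")
EXCLUSION_REASONS <- c("maf", "clinvar_benign", "silent_no_splice",
                       "consensus_failed", "final_exon_truncation", "none")

#' Population allele-frequency filter
#'
#' A variant too common in any reference population is excluded from the
#' actionable-carrier analysis: the filter fails as soon as the minor allele
#' frequency reaches the threshold (default 0.1 percent) in one or more
#' populations. The comparison is inclusive (AF equal to the threshold
#' excludes). Variants absent from the reference (no recorded frequencies)
#' pass.
#'
#' @param pop_afs named numeric vector of per-population allele frequencies,
#'   or the `key=value;...` string encoding used in variant tables.
#' @param threshold exclusion threshold on the frequency scale (default 1e-3).
#' @return `TRUE` if the variant survives the filter.
#' @export
passes_frequency_filter <- function(pop_afs, threshold = 0.001) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.character(pop_afs)) pop_afs <- parse_kv_field(pop_afs)
  if (!length(pop_afs)) return(TRUE)
  all(pop_afs < threshold)
}

#' Clinical-assertion (benign consensus) filter
#'
#' Excludes variants asserted benign or likely benign by more than one source
#' with no conflicting report: at least two benign/likely-benign sources and
#' zero pathogenic, likely-pathogenic or uncertain sources. A single benign
#' source, or any conflict, is not enough to exclude.
#'
#' @param clinvar named numeric vector of assertion counts per class
#'   (`pathogenic`, `likely_pathogenic`, `uncertain`, `likely_benign`,
#'   `benign`), or its string encoding.
#' @return `TRUE` if the variant survives the filter.
#' @export
passes_clinvar_filter <- function(clinvar) {
  if (is.character(clinvar)) clinvar <- parse_kv_field(clinvar)
  cnt <- function(k) if (k %in% names(clinvar)) clinvar[[k]] else 0
  benign <- cnt("benign") + cnt("likely_benign")
  other <- cnt("pathogenic") + cnt("likely_pathogenic") + cnt("uncertain")
  !(benign >= 2 && other == 0)
}

#' Silent/intronic splice filter
#'
#' Synonymous and intronic variants are retained only when a splice-effect
#' prediction flags them; all other consequences pass unconditionally.
#'
#' @param consequence consequence string.
#' @param splice_effect_predicted `"yes"`, `"no"` or `"unknown"`.
#' @return `TRUE` if the variant survives the filter.
#' @export
passes_silent_splice_filter <- function(consequence, splice_effect_predicted) {
  if (!consequence %in% c("synonymous", "intronic")) return(TRUE)
  identical(splice_effect_predicted, "yes")
}

#' In-silico consensus rule for missense HiP-VUS
#'
#' A missense VUS qualifies as a high-probability-of-pathogenicity VUS when at
#' least three of the four predictors (Align-GVGD, MAPP, PolyPhen-2, CADD)
#' call it severe. A missing call counts as not severe.
#'
#' @param calls character vector of the four predictor calls (`"severe"`,
#'   `"not_severe"` or `"missing"`), or a named list/vector keyed by
#'   predictor.
#' @return `TRUE` if the 3-of-4 consensus is met.
#' @export
consensus_hip_vus <- function(calls) {
  calls <- unlist(calls, use.names = FALSE)
  stopifnot(length(calls) == 4L, all(calls %in% PREDICTOR_CALLS))
  sum(calls == "severe") >= 3L
}

.classified_row <- function(v, category, reason, weight, rule_unattributed = FALSE) {
  data.frame(individual_id = v$individual_id, cohort_id = v$cohort_id,
             gene = v$gene, hgvs_c = v$hgvs_c,
             category = category, exclusion_reason = reason,
             weight = weight, rule_unattributed = rule_unattributed,
             stringsAsFactors = FALSE)
}

#' Classify one variant and assign its carrier weight
#'
#' Applies the three exclusion filters, then the classification rules in
#' fixed precedence order:
#' \enumerate{
#'   \item frameshift/nonsense outside the gene's final exon: pathogenic,
#'     weight 1;
#'   \item canonical splice variant with experimentally demonstrated effect:
#'     pathogenic, weight 1;
#'   \item canonical splice variant with predicted (undemonstrated) effect:
#'     HiP-VUS, weight 0.97;
#'   \item missense shown damaging in a functional assay: HiP-VUS, weight
#'     0.99;
#'   \item missense in a calibrated gene with prior probability of
#'     pathogenicity above 0.8: HiP-VUS, weight equal to the prior;
#'   \item missense meeting the 3-of-4 in-silico consensus: HiP-VUS, weight
#'     0.81;
#'   \item otherwise excluded (weight 0).
#' }
#' Truncating variants in the final exon are excluded (no assumption about
#' nonsense-mediated decay escape is made beyond the final-exon rule itself).
#' A `weight_override` value in the input replaces the rule-derived weight
#' and flags the record; a record that no rule reaches but that carries an
#' override is likewise flagged as rule-unattributed.
#'
#' @param v one-row data.frame (or coercible list) of an annotated variant
#'   observation, as returned by [read_variant_table()].
#' @param maf_threshold allele-frequency exclusion threshold.
#' @return one-row data.frame with `category`, `exclusion_reason`, `weight`
#'   and a `rule_unattributed` flag.
#' @export
classify_and_weight <- function(v, maf_threshold = 0.001) {
  v <- as.list(v)
  override <- if (!is.null(v$weight_override)) v$weight_override else NA_real_

  if (!passes_frequency_filter(v$pop_afs, maf_threshold)) {
    return(.classified_row(v, "EXCLUDED", "maf", 0))
  }
  if (!passes_clinvar_filter(v$clinvar)) {
    return(.classified_row(v, "EXCLUDED", "clinvar_benign", 0))
  }
  if (!passes_silent_splice_filter(v$consequence, v$splice_effect_predicted)) {
    return(.classified_row(v, "EXCLUDED", "silent_no_splice", 0))
  }

  finish <- function(category, weight) {
    if (!is.na(override)) {
      .classified_row(v, category, "none", override,
                      rule_unattributed = abs(override - weight) > 1e-12)
    } else {
      .classified_row(v, category, "none", weight)
    }
  }

  if (v$consequence %in% c("frameshift", "nonsense")) {
    if (is.na(v$exon_index) || is.na(v$exon_count)) {
      stop(sprintf("%s %s: truncating variant needs exon_index and exon_count",
                   v$gene, v$hgvs_c))
    }
    if (v$exon_index < v$exon_count) {
      return(finish("PATHOGENIC_TRUNCATING", 1))
    }
    return(.classified_row(v, "EXCLUDED", "final_exon_truncation", 0))
  }

  if (v$consequence == "canonical_splice") {
    if (isTRUE(v$splice_demonstrated)) {
      return(finish("PATHOGENIC_ASSERTED", 1))
    }
    if (identical(v$splice_effect_predicted, "yes")) {
      return(finish("HIP_VUS_SPLICE", WEIGHT_SPLICE))
    }
    return(.classified_row(v, "EXCLUDED", "consensus_failed", 0))
  }

  if (v$consequence == "missense") {
    if (identical(v$functional_assay, "damaging")) {
      return(finish("HIP_VUS_FUNCTIONAL", WEIGHT_FUNCTIONAL))
    }
    if (!is.na(v$prior_p) && v$prior_p > PRIOR_P_CUTOFF) {
      return(finish("HIP_VUS_PRIOR", v$prior_p))
    }
    calls <- c(v$agvgd, v$mapp, v$polyphen2, v$cadd)
    if (consensus_hip_vus(calls)) {
      return(finish("HIP_VUS_CONSENSUS", WEIGHT_CONSENSUS))
    }
  }

  if (!is.na(override)) {
    return(.classified_row(v, "HIP_VUS_CONSENSUS", "none", override,
                           rule_unattributed = TRUE))
  }
  .classified_row(v, "EXCLUDED", "consensus_failed", 0)
}

#' Triage a table of variant observations
#'
#' Vectorized driver over [classify_and_weight()]; keeps input row order.
#'
#' @param variants data.frame from [read_variant_table()].
#' @param maf_threshold allele-frequency exclusion threshold.
#' @return data.frame of classified variants, one row per input row.
#' @export
triage_variants <- function(variants, maf_threshold = 0.001) {
  if (!nrow(variants)) {
    return(.classified_row(list(individual_id = character(0),
                                cohort_id = character(0),
                                gene = character(0), hgvs_c = character(0)),
                           character(0), character(0), numeric(0),
                           logical(0)))
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    classify_and_weight(variants[i, , drop = FALSE], maf_threshold)
  })
  do.call(rbind, rows)
}

#' Combine one individual's variant weights into a carrier weight
#'
#' An individual carrying several weighted variants is counted once, with a
#' combined weight equal to the probability that at least one variant is
#' truly pathogenic under independence (noisy-OR):
#' \eqn{1 - \prod_i (1 - w_i)}. Excluded variants (weight 0) do not
#' contribute; an individual with no surviving variant has combined weight 0.
#' The combination is order-invariant, monotone non-decreasing in each
#' weight, and never below the largest single weight.
#'
#' @param weights numeric vector of per-variant carrier weights in [0, 1].
#' @return combined carrier weight in [0, 1].
#' @export
combine_weights <- function(weights) {
  stopifnot(all(weights >= 0), all(weights <= 1))
  if (!length(weights)) return(0)
  min(1, 1 - prod(1 - weights))
}

#' Build per-individual carrier records from classified variants
#'
#' @param classified data.frame from [triage_variants()].
#' @param genes optional gene set restricting which variants contribute
#'   (used for per-group burdens); `NULL` means all genes.
#' @return data.frame with one row per individual carrying at least one
#'   non-excluded variant (in `genes` if given): `individual_id`,
#'   `cohort_id`, `combined_weight`, `n_variants`.
#' @export
combine_individuals <- function(classified, genes = NULL) {
  keep <- classified$category != "EXCLUDED"
  if (!is.null(genes)) keep <- keep & classified$gene %in% genes
  surv <- classified[keep, , drop = FALSE]
  if (!nrow(surv)) {
    return(data.frame(individual_id = character(0), cohort_id = character(0),
                      combined_weight = numeric(0), n_variants = integer(0),
                      stringsAsFactors = FALSE))
  }
  split_idx <- split(seq_len(nrow(surv)),
                     paste(surv$cohort_id, surv$individual_id, sep = "\r"))
  rows <- lapply(split_idx, function(idx) {
    data.frame(individual_id = surv$individual_id[idx[1]],
               cohort_id = surv$cohort_id[idx[1]],
               combined_weight = combine_weights(surv$weight[idx]),
               n_variants = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cohort_id, out$individual_id), , drop = FALSE]
}

#' Triage a cohort and summarize weighted carrier burden per gene group
#'
#' Runs the full triage on a cohort's variant observations, combines weights
#' per individual (overall, and restricted to each gene group), and returns
#' cohort summaries together with the carrier records and an exclusion
#' ledger. Every input variant lands exactly once in either a carrier
#' record's contributing set or the exclusion ledger.
#'
#' @param variants data.frame of annotated variant observations for one or
#'   more cohorts.
#' @param config gene-panel configuration from [read_gene_config()].
#' @param cohort_n named integer vector (or data.frame with `cohort_id`, `n`)
#'   giving each cohort's sample size; individuals with no variants still
#'   count in `n`.
#' @param maf_threshold allele-frequency exclusion threshold.
#' @param level confidence level for the per-cohort interval.
#' @return list with `summaries` (cohort x group rows: `cohort_id`,
#'   `group_name`, `weighted_x`, `n`, `percent`, `ci_low`, `ci_high`),
#'   `carriers` (per-individual records, overall), `classified` (all
#'   classified variants) and `exclusions` (the ledger: one row per excluded
#'   variant with its reason code).
#' @export
triage_cohort <- function(variants, config, cohort_n, maf_threshold = 0.001,
                          level = 0.95) {
  if (is.data.frame(cohort_n)) {
    cohort_n <- stats::setNames(as.integer(cohort_n$n), cohort_n$cohort_id)
  }
  classified <- triage_variants(variants, maf_threshold)
  carriers <- combine_individuals(classified)

  for (cid in names(cohort_n)) {
    k <- sum(carriers$cohort_id == cid)
    if (k > cohort_n[[cid]]) {
      stop(sprintf("cohort '%s': %d distinct carriers exceed n = %d",
                   cid, k, cohort_n[[cid]]))
    }
  }
  unknown <- setdiff(unique(classified$cohort_id), names(cohort_n))
  if (length(unknown)) {
    stop(sprintf("no sample size given for cohort '%s'", unknown[1]))
  }

  group_sets <- c(list(ALL = NULL),
                  stats::setNames(lapply(config$groups, `[[`, "genes"),
                                  vapply(config$groups, `[[`, "", "name")))
  rows <- list()
  for (cid in names(cohort_n)) {
    cls_c <- classified[classified$cohort_id == cid, , drop = FALSE]
    for (gname in names(group_sets)) {
      cr <- combine_individuals(cls_c, genes = group_sets[[gname]])
      wx <- sum(cr$combined_weight)
      n <- cohort_n[[cid]]
      ci <- frequency_ci(wx, n, level)
      rows[[length(rows) + 1L]] <- data.frame(
        cohort_id = cid, group_name = gname, weighted_x = wx, n = n,
        percent = weighted_frequency(wx, n),
        ci_low = ci[[1]], ci_high = ci[[2]], stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL

  exclusions <- classified[classified$category == "EXCLUDED",
                           c("individual_id", "cohort_id", "gene", "hgvs_c",
                             "exclusion_reason"), drop = FALSE]
  rownames(exclusions) <- NULL
  list(summaries = summaries, carriers = carriers, classified = classified,
       exclusions = exclusions)
}
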