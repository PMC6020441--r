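#' @keywords internal
"_PACKAGE"

# Canonical enum levels shared across readers and the triage engine.
CONSEQUENCES <- c("frameshift", "nonsense", "canonical_splice", "missense",
                  "synonymous", "intronic", "inframe_indel")
PREDICTORS <- c("agvgd", "mapp", "polyphen2", "cadd")
PREDICTOR_CALLS <- c("severe", "not_severe", "missing")
SPLICE_STATES <- c("yes", "no", "unknown")
ASSAY_STATES <- c("damaging", "neutral", "none")
CLINVAR_CLASSES <- c("pathogenic", "likely_pathogenic", "uncertain",
                     "likely_benign", "benign")

.mandatory_cols <- c("individual_id", "cohort_id", "gene", "hgvs_c",
                     "consequence")

# Optional columns with the explicit missing state each takes when absent.
.optional_defaults <- list(
  hgvs_p = NA_character_,
  exon_index = NA_integer_,
  exon_count = NA_integer_,
  pop_afs = "",
  clinvar = "",
  agvgd = "missing",
  mapp = "missing",
  polyphen2 = "missing",
  cadd = "missing",
  prior_p = NA_real_,
  splice_effect_predicted = "unknown",
  functional_assay = "none",
  splice_demonstrated = FALSE,
  weight_override = NA_real_
)

#' Parse a `key=value;key=value` field into a named numeric vector
#'
#' Used for the per-population allele-frequency column (`pop_afs`) and the
#' clinical-assertion count column (`clinvar`). Empty strings and `NA` give a
#' zero-length vector.
#'
#' @param x a single character string, e.g. `"NFE=0.002;AFR=0"`.
#' @return named numeric vector (possibly empty).
#' @export
parse_kv_field <- function(x) {
  if (length(x) != 1L) stop("parse_kv_field() expects a single string")
  if (is.na(x) || !nzchar(trimws(x))) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop(sprintf("malformed key=value entry: '%s'", parts[bad][1]))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2L)))
  names(vals) <- trimws(vapply(kv, `[`, character(1), 1L))
  if (anyNA(vals)) stop(sprintf("non-numeric value in field '%s'", x))
  vals
}

.validate_variants <- function(df) {
  bad <- !df$consequence %in% CONSEQUENCES
  if (any(bad)) {
    stop(sprintf("row %d: unknown consequence '%s'",
                 which(bad)[1], df$consequence[which(bad)[1]]))
  }
  for (p in PREDICTORS) {
    bad <- !df[[p]] %in% PREDICTOR_CALLS
    if (any(bad)) {
      stop(sprintf("row %d: invalid %s call '%s'", which(bad)[1], p,
                   df[[p]][which(bad)[1]]))
    }
  }
  bad <- !df$splice_effect_predicted %in% SPLICE_STATES
  if (any(bad)) stop(sprintf("row %d: invalid splice_effect_predicted", which(bad)[1]))
  bad <- !df$functional_assay %in% ASSAY_STATES
  if (any(bad)) stop(sprintf("row %d: invalid functional_assay", which(bad)[1]))

  for (i in seq_len(nrow(df))) {
    afs <- parse_kv_field(df$pop_afs[i])
    if (length(afs) && (any(afs < 0) || any(afs > 1))) {
      stop(sprintf("row %d: allele frequency outside [0,1]: %s=%g",
                   i, names(afs)[afs < 0 | afs > 1][1],
                   afs[afs < 0 | afs > 1][1]))
    }
    cv <- parse_kv_field(df$clinvar[i])
    if (length(cv)) {
      unknown <- setdiff(names(cv), CLINVAR_CLASSES)
      if (length(unknown)) {
        stop(sprintf("row %d: unknown clinical-assertion class '%s'", i, unknown[1]))
      }
      if (any(cv < 0) || any(cv != floor(cv))) {
        stop(sprintf("row %d: assertion counts must be non-negative integers", i))
      }
    }
  }
  both <- !is.na(df$exon_index) & !is.na(df$exon_count)
  bad <- both & df$exon_index > df$exon_count
  if (any(bad)) stop(sprintf("row %d: exon_index exceeds exon_count", which(bad)[1]))
  bad <- !is.na(df$prior_p) & (df$prior_p < 0 | df$prior_p > 1)
  if (any(bad)) stop(sprintf("row %d: prior_p outside [0,1]", which(bad)[1]))
  invisible(df)
}

.coerce_variant_types <- function(df) {
  df$individual_id <- as.character(df$individual_id)
  df$cohort_id <- as.character(df$cohort_id)
  df$gene <- as.character(df$gene)
  df$hgvs_c <- as.character(df$hgvs_c)
  df$hgvs_p <- as.character(df$hgvs_p)
  df$consequence <- as.character(df$consequence)
  df$exon_index <- as.integer(df$exon_index)
  df$exon_count <- as.integer(df$exon_count)
  df$pop_afs <- ifelse(is.na(df$pop_afs), "", as.character(df$pop_afs))
  df$clinvar <- ifelse(is.na(df$clinvar), "", as.character(df$clinvar))
  for (p in PREDICTORS) {
    df[[p]] <- ifelse(is.na(df[[p]]) | !nzchar(df[[p]]), "missing", as.character(df[[p]]))
  }
  df$prior_p <- as.numeric(df$prior_p)
  df$splice_effect_predicted <- ifelse(is.na(df$splice_effect_predicted) |
                                         !nzchar(df$splice_effect_predicted),
                                       "unknown", as.character(df$splice_effect_predicted))
  df$functional_assay <- ifelse(is.na(df$functional_assay) |
                                  !nzchar(df$functional_assay),
                                "none", as.character(df$functional_assay))
  df$splice_demonstrated <- as.logical(df$splice_demonstrated)
  df$splice_demonstrated[is.na(df$splice_demonstrated)] <- FALSE
  df$weight_override <- as.numeric(df$weight_override)
  df
}

#' Read an annotated germline variant table
#'
#' One row per (individual, variant) observation, carrying all annotations the
#' triage rules consume: consequence, exon position, per-population allele
#' frequencies, clinical-assertion counts, the four in-silico predictor calls,
#' an optional calibrated prior probability of pathogenicity, splice-effect
#' prediction, functional-assay result, and experimental splice evidence.
#'
#' Two dialects are supported. The canonical flat TSV carries every field in
#' one table (columns `individual_id, cohort_id, gene, hgvs_c, consequence`
#' mandatory; see [parse_kv_field()] for the `pop_afs` and `clinvar`
#' encodings). The VCF dialect reads per-sample genotypes from a VCF 4.x file
#' and joins a sidecar annotation TSV keyed by the VCF `ID` column; carriers
#' are the samples with at least one alternate allele.
#'
#' @param path path to the variant TSV or VCF.
#' @param dialect `"tsv"` (default) or `"vcf_plus_annot"`.
#' @param annotation_path sidecar annotation TSV (VCF dialect only); must have
#'   a `variant_id` column matching the VCF `ID` field plus the annotation
#'   columns of the canonical dialect.
#' @param cohort_id cohort label assigned to carriers found in a VCF (VCF
#'   dialect only).
#' @return data.frame of annotated variant observations with validated,
#'   consistently typed columns; missing optional fields are set to their
#'   explicit missing states (`"missing"`, `"unknown"`, `"none"`, `NA`).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_plus_annot"),
                               annotation_path = NULL, cohort_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (dialect == "tsv") {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = c("NA"))
  } else {
    df <- .read_vcf_variants(path, annotation_path, cohort_id)
  }
  missing_cols <- setdiff(.mandatory_cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in names(.optional_defaults)) {
    if (!col %in% names(df)) df[[col]] <- .optional_defaults[[col]]
  }
  df <- .coerce_variant_types(df)
  .validate_variants(df)
  df[, c(.mandatory_cols, names(.optional_defaults))]
}

.read_vcf_variants <- function(path, annotation_path, cohort_id) {
  if (is.null(annotation_path) || is.null(cohort_id)) {
    stop("vcf_plus_annot dialect needs annotation_path and cohort_id")
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcf_plus_annot dialect requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ann <- utils::read.delim(annotation_path, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (!"variant_id" %in% names(ann)) {
    stop("missing mandatory column(s): variant_id")
  }
  ids <- vcfR::getID(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rows <- list()
  for (i in seq_along(ids)) {
    carriers <- colnames(gt)[grepl("1", gt[i, ])]
    carriers <- carriers[!is.na(carriers)]
    arow <- ann[ann$variant_id == ids[i], , drop = FALSE]
    if (nrow(arow) != 1L) {
      stop(sprintf("annotation table must have exactly one row for variant '%s'",
                   ids[i]))
    }
    for (ind in carriers) {
      r <- arow[, setdiff(names(arow), "variant_id"), drop = FALSE]
      r$individual_id <- ind
      r$cohort_id <- cohort_id
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) {
    out <- ann[0, setdiff(names(ann), "variant_id"), drop = FALSE]
    out$individual_id <- character(0)
    out$cohort_id <- character(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Read a gene-panel configuration
#'
#' YAML file defining named gene groups with a risk tier each. Tiers encode
#' cumulative cancer risk at age 80 for the most closely associated cancer:
#' `high` (> 32 percent), `moderate` (19-32 percent), or `other`. A gene may
#' belong to several overlapping groups (e.g. a breast-cancer gene that is
#' also a homologous-recombination-repair gene), but the high/moderate tier
#' partition used in tier-level analyses must be disjoint.
#'
#' @param path path to the YAML config.
#' @return list with `panel_name` and `groups` (each group: `name`, `genes`,
#'   `risk_tier`).
#' @export
read_gene_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) cfg$groups <- list()
  tiers_by_gene <- list()
  for (g in cfg$groups) {
    if (is.null(g$name) || is.null(g$risk_tier)) {
      stop("each group needs 'name' and 'risk_tier'")
    }
    if (!g$risk_tier %in% c("high", "moderate", "other")) {
      stop(sprintf("group '%s': unknown risk_tier '%s'", g$name, g$risk_tier))
    }
    genes <- unlist(g$genes)
    if (anyDuplicated(genes)) {
      stop(sprintf("group '%s': duplicate gene symbols", g$name))
    }
    if (g$risk_tier %in% c("high", "moderate")) {
      for (gene in genes) {
        prev <- tiers_by_gene[[gene]]
        if (!is.null(prev) && prev != g$risk_tier) {
          stop(sprintf("gene '%s' assigned two different risk tiers (%s, %s)",
                       gene, prev, g$risk_tier))
        }
        tiers_by_gene[[gene]] <- g$risk_tier
      }
    }
  }
  if (is.null(cfg$panel_name)) cfg$panel_name <- "unnamed_panel"
  cfg$groups <- lapply(cfg$groups, function(g) {
    list(name = g$name, genes = as.character(unlist(g$genes)),
         risk_tier = g$risk_tier)
  })
  cfg
}

#' Genes belonging to a named group
#' @param config gene-panel configuration from [read_gene_config()].
#' @param group_name group name.
#' @return character vector of gene symbols.
#' @export
group_genes <- function(config, group_name) {
  for (g in config$groups) if (g$name == group_name) return(g$genes)
  stop(sprintf("no group named '%s'", group_name))
}

#' Read a cohort manifest
#'
#' TSV with columns `cohort_id` and `n` (number of cases tested, including
#' individuals in whom no variant survived triage).
#'
#' @param path path to the manifest TSV.
#' @return data.frame with character `cohort_id` and integer `n`.
#' @export
read_cohort_manifest <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("cohort_id", "n") %in% names(df))) {
    stop("cohort manifest needs columns cohort_id and n")
  }
  df$cohort_id <- as.character(df$cohort_id)
  df$n <- as.integer(df$n)
  if (any(is.na(df$n)) || any(df$n <= 0)) stop("cohort n must be positive")
  df
}

#' Read a reference-population carrier summary
#'
#' TSV with columns `group_name` and `weighted_carriers`, plus the reference
#' sample size either as an `n_ref` column (constant) or supplied as an
#' argument. The weighted carrier counts must come from the same grading
#' scheme applied to the cases, so case and reference burdens are
#' bioinformatically equivalent.
#'
#' @param path path to the summary TSV.
#' @param n_ref reference population size; overrides any `n_ref` column.
#' @return list with `n_ref` and named numeric `weighted_carriers_by_group`.
#' @export
read_reference_summary <- function(path, n_ref = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("group_name", "weighted_carriers") %in% names(df))) {
    stop("reference summary needs columns group_name and weighted_carriers")
  }
  if (is.null(n_ref)) {
    if (!"n_ref" %in% names(df)) stop("supply n_ref (argument or column)")
    n_ref <- unique(as.integer(df$n_ref))
    if (length(n_ref) != 1L) stop("n_ref column must be constant")
  }
  wc <- as.numeric(df$weighted_carriers)
  if (any(wc < 0)) stop("weighted carrier counts must be non-negative")
  if (n_ref <= 0) stop("n_ref must be positive")
  if (any(wc > n_ref)) stop("weighted carriers cannot exceed n_ref")
  list(n_ref = n_ref,
       weighted_carriers_by_group = stats::setNames(wc, df$group_name))
}

#' Write a result table
#'
#' Writes a data.frame as TSV (fixed column order, numerics at 6 significant
#' digits) or as JSON (lossless round trip via `jsonlite`).
#'
#' @param results data.frame of results.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return invisibly, the path written.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (format == "tsv") {
    out <- results
    for (col in names(out)) {
      if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
        out[[col]] <- signif(out[[col]], 6)
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
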