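# Construct a single annotated-variant row with sensible defaults; tests
# override only the fields a rule looks at.
make_variant <- function(individual_id = "I1", cohort_id = "c1",
                         gene = "BRCA2", hgvs_c = "c.1A>G",
                         hgvs_p = NA_character_, consequence = "missense",
                         exon_index = NA_integer_, exon_count = NA_integer_,
                         pop_afs = "", clinvar = "",
                         agvgd = "missing", mapp = "missing",
                         polyphen2 = "missing", cadd = "missing",
                         prior_p = NA_real_,
                         splice_effect_predicted = "unknown",
                         functional_assay = "none",
                         splice_demonstrated = FALSE,
                         weight_override = NA_real_) {
  data.frame(individual_id = individual_id, cohort_id = cohort_id,
             gene = gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
             consequence = consequence,
             exon_index = as.integer(exon_index),
             exon_count = as.integer(exon_count),
             pop_afs = pop_afs, clinvar = clinvar, agvgd = agvgd,
             mapp = mapp, polyphen2 = polyphen2, cadd = cadd,
             prior_p = prior_p,
             splice_effect_predicted = splice_effect_predicted,
             functional_assay = functional_assay,
             splice_demonstrated = splice_demonstrated,
             weight_override = weight_override, stringsAsFactors = FALSE)
}

# A minimal two-group panel used by unit tests that don't need the packaged
# panel.
tiny_gene_config <- function() {
  list(panel_name = "tiny",
       groups = list(
         list(name = "grpA", genes = c("BRCA2", "MSH6"), risk_tier = "high"),
         list(name = "grpB", genes = c("ATM", "CHEK2"), risk_tier = "moderate")))
}
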