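test_that("allele-frequency filter excludes at >= 0.1% in any population, inclusively", {
  expect_false(passes_frequency_filter(c(NFE = 0.002, AFR = 0)))
  expect_true(passes_frequency_filter(stats::setNames(numeric(0), character(0))))
  expect_true(passes_frequency_filter(""))
  expect_false(passes_frequency_filter(c(NFE = 0.001)))  # boundary is inclusive
  expect_true(passes_frequency_filter(c(NFE = 0.000999)))
  expect_true(passes_frequency_filter("NFE=0.0005;AFR=0.0002"))
})

test_that("benign-assertion filter needs >1 benign source and no conflict", {
  expect_false(passes_clinvar_filter(c(benign = 3)))
  expect_false(passes_clinvar_filter(c(benign = 1, likely_benign = 1)))
  expect_true(passes_clinvar_filter(c(benign = 2, pathogenic = 1)))
  expect_true(passes_clinvar_filter(c(benign = 2, uncertain = 1)))
  expect_true(passes_clinvar_filter(c(benign = 1)))
  expect_true(passes_clinvar_filter(""))
})

test_that("silent/intronic variants survive only with a predicted splice effect", {
  expect_false(passes_silent_splice_filter("synonymous", "no"))
  expect_false(passes_silent_splice_filter("intronic", "unknown"))
  expect_true(passes_silent_splice_filter("intronic", "yes"))
  expect_true(passes_silent_splice_filter("missense", "unknown"))
  expect_true(passes_silent_splice_filter("frameshift", "no"))
})

test_that("3-of-4 consensus matches brute-force enumeration over all 81 patterns", {
  states <- c("severe", "not_severe", "missing")
  grid <- expand.grid(a = states, b = states, c = states, d = states,
                      stringsAsFactors = FALSE)
  qualifying <- 0L
  for (i in seq_len(nrow(grid))) {
    calls <- unlist(grid[i, ])
    expect_identical(consensus_hip_vus(calls),
                     sum(calls == "severe") >= 3L)
    if (sum(calls == "severe") >= 3L) qualifying <- qualifying + 1L
  }
  # severe count per slot is Bernoulli over 3 states: C(4,3)*2 + 1 = 9 of 81
  expect_equal(qualifying, 9L)
  # restricted to binary calls, 5 of 16 patterns qualify
  bin <- expand.grid(rep(list(c("severe", "not_severe")), 4),
                     stringsAsFactors = FALSE)
  expect_equal(sum(apply(bin, 1, function(r) consensus_hip_vus(r))), 5L)
})

test_that("classification precedence reproduces the published weighting rules", {
  w <- function(v) classify_and_weight(v)$weight
  cat <- function(v) classify_and_weight(v)$category

  trunc <- make_variant(gene = "MSH6", consequence = "frameshift",
                        exon_index = 5, exon_count = 10)
  expect_equal(w(trunc), 1)
  expect_equal(cat(trunc), "PATHOGENIC_TRUNCATING")

  consensus <- make_variant(gene = "ATM", agvgd = "severe", mapp = "severe",
                            polyphen2 = "severe", cadd = "not_severe")
  expect_equal(w(consensus), 0.81)
  expect_equal(cat(consensus), "HIP_VUS_CONSENSUS")

  prior <- make_variant(gene = "MSH6", prior_p = 0.94, agvgd = "severe",
                        mapp = "severe", polyphen2 = "severe", cadd = "severe")
  expect_equal(w(prior), 0.94)
  expect_equal(cat(prior), "HIP_VUS_PRIOR")

  func <- make_variant(gene = "CHEK2", functional_assay = "damaging")
  expect_equal(w(func), 0.99)
  expect_equal(cat(func), "HIP_VUS_FUNCTIONAL")

  splice_pred <- make_variant(consequence = "canonical_splice",
                              splice_effect_predicted = "yes")
  expect_equal(w(splice_pred), 0.97)
  expect_equal(cat(splice_pred), "HIP_VUS_SPLICE")

  splice_demo <- make_variant(consequence = "canonical_splice",
                              splice_effect_predicted = "yes",
                              splice_demonstrated = TRUE)
  expect_equal(w(splice_demo), 1)
  expect_equal(cat(splice_demo), "PATHOGENIC_ASSERTED")

  final_exon <- make_variant(consequence = "frameshift",
                             exon_index = 27, exon_count = 27)
  cls <- classify_and_weight(final_exon)
  expect_equal(cls$category, "EXCLUDED")
  expect_equal(cls$exclusion_reason, "final_exon_truncation")
  expect_equal(cls$weight, 0)

  # calibrated gene with prior <= 0.8 falls through to the consensus rule
  low_prior <- make_variant(gene = "MSH6", prior_p = 0.5, agvgd = "severe",
                            mapp = "severe", polyphen2 = "severe",
                            cadd = "severe")
  expect_equal(w(low_prior), 0.81)
  low_prior_fail <- make_variant(gene = "MSH6", prior_p = 0.5,
                                 agvgd = "severe", mapp = "severe")
  expect_equal(classify_and_weight(low_prior_fail)$exclusion_reason,
               "consensus_failed")

  expect_error(classify_and_weight(make_variant(consequence = "nonsense")),
               "exon_index")
})

test_that("exclusion filters precede classification and set weight 0", {
  common <- make_variant(consequence = "frameshift", exon_index = 2,
                         exon_count = 20, pop_afs = "NFE=0.01")
  cls <- classify_and_weight(common)
  expect_equal(cls$exclusion_reason, "maf")
  expect_equal(cls$weight, 0)

  benign <- make_variant(clinvar = "benign=2;likely_benign=1")
  expect_equal(classify_and_weight(benign)$exclusion_reason, "clinvar_benign")

  silent <- make_variant(consequence = "synonymous",
                         splice_effect_predicted = "no")
  expect_equal(classify_and_weight(silent)$exclusion_reason, "silent_no_splice")
})

test_that("weight overrides replace the rule weight and are flagged", {
  ov <- make_variant(gene = "CHEK2", agvgd = "severe", mapp = "severe",
                     polyphen2 = "severe", weight_override = 0.95)
  cls <- classify_and_weight(ov)
  expect_equal(cls$weight, 0.95)
  expect_true(cls$rule_unattributed)
  # an override matching the rule weight is not flagged
  same <- make_variant(gene = "ATM", agvgd = "severe", mapp = "severe",
                       polyphen2 = "severe", weight_override = 0.81)
  expect_false(classify_and_weight(same)$rule_unattributed)
})

test_that("noisy-OR combination matches the exhaustive two-event probability table", {
  expect_equal(combine_weights(c(0.97, 1.0)), 1.0)
  expect_equal(combine_weights(0.81), 0.81)
  expect_equal(combine_weights(c(0.5, 0.5)), 0.75)
  expect_equal(combine_weights(numeric(0)), 0)
  # exhaustive check over a grid of two-event probabilities: the combined
  # weight is P(at least one event) from the 2x2 joint table under
  # independence
  for (w1 in seq(0, 1, by = 0.25)) {
    for (w2 in seq(0, 1, by = 0.25)) {
      p_table <- c(w1 * w2, w1 * (1 - w2), (1 - w1) * w2)  # at-least-one cells
      expect_equal(combine_weights(c(w1, w2)), sum(p_table))
    }
  }
})

test_that("combination is permutation-invariant, monotone, and >= max weight", {
  set.seed(42)
  for (i in 1:25) {
    w <- runif(sample(1:5, 1))
    expect_equal(combine_weights(w), combine_weights(rev(w)))
    expect_equal(combine_weights(w), combine_weights(sample(w)))
    expect_gte(combine_weights(w), max(w))
    expect_lte(combine_weights(w), 1)
    expect_gte(combine_weights(c(w, 0.3)), combine_weights(w))
  }
})

test_that("cohort triage conserves rows: each variant is counted once or ledgered", {
  fx <- table1_fixture()
  tri <- triage_cohort(fx$variants, default_gene_config(), fx$cohorts)
  expect_equal(sum(tri$carriers$n_variants) + nrow(tri$exclusions),
               nrow(fx$variants))
  # the only ledgered fixture variant is the RAD50 missense failing consensus
  expect_equal(tri$exclusions$gene, "RAD50")
  expect_equal(tri$exclusions$exclusion_reason, "consensus_failed")
})

test_that("cohort triage handles empty cohorts and inconsistent n", {
  cfg <- tiny_gene_config()
  tri <- triage_cohort(make_variant()[0, ], cfg, c(c1 = 10L))
  expect_true(all(tri$summaries$weighted_x == 0))
  expect_true(all(tri$summaries$percent == 0))

  many <- do.call(rbind, lapply(1:5, function(i) {
    make_variant(individual_id = paste0("I", i), consequence = "frameshift",
                 exon_index = 2, exon_count = 20)
  }))
  expect_error(triage_cohort(many, cfg, c(c1 = 3L)), "exceed")
})

test_that("per-group burdens restrict the combination to the group's genes", {
  cfg <- tiny_gene_config()
  v <- rbind(
    make_variant(individual_id = "I1", gene = "BRCA2",
                 consequence = "frameshift", exon_index = 2, exon_count = 20),
    make_variant(individual_id = "I1", gene = "ATM", hgvs_c = "c.2A>G",
                 agvgd = "severe", mapp = "severe", polyphen2 = "severe"))
  tri <- triage_cohort(v, cfg, c(c1 = 50L))
  s <- tri$summaries
  expect_equal(s$weighted_x[s$group_name == "grpA"], 1)
  expect_equal(s$weighted_x[s$group_name == "grpB"], 0.81)
  # overall: one individual, noisy-OR of both variants
  expect_equal(s$weighted_x[s$group_name == "ALL"], 1 - (1 - 1) * (1 - 0.81))
})
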