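t0 <- hm_thresholds()

# profile echoing the top-ranked candidate pattern: 8 of 9 categorical tools
# damaging (LRT tolerated), DANN 0.999
csmd1_like <- list(
  sift = "damaging", polyphen2_hdiv = "damaging", polyphen2_hvar = "damaging",
  mutation_taster = "damaging", lrt = "tolerated",
  mutation_assessor = "damaging", fathmm = "damaging", radialsvm = "damaging",
  lr = "damaging", dann = 0.999
)

test_that("damaging call counting, PolyPhen collapse and DANN threshold", {
  expect_equal(damaging_call_count(csmd1_like, t0, collapse_polyphen = TRUE), 8L)
  expect_equal(damaging_call_count(csmd1_like, t0, collapse_polyphen = FALSE), 9L)
  all_missing <- stats::setNames(
    as.list(rep(NA_character_, 9)),
    c("sift", "polyphen2_hdiv", "polyphen2_hvar", "mutation_taster", "lrt",
      "mutation_assessor", "fathmm", "radialsvm", "lr"))
  all_missing$dann <- NA_real_
  expect_equal(damaging_call_count(all_missing, t0), 0L)
  # DANN below the threshold does not count
  weak <- csmd1_like; weak$dann <- 0.89
  expect_equal(damaging_call_count(weak, t0, collapse_polyphen = TRUE), 7L)
  # only one PolyPhen submodel damaging still counts once under collapse
  one_pp <- csmd1_like; one_pp$polyphen2_hvar <- "tolerated"
  expect_equal(damaging_call_count(one_pp, t0, collapse_polyphen = TRUE), 8L)
  expect_equal(damaging_call_count(one_pp, t0, collapse_polyphen = FALSE), 8L)
})

test_that("frequency classes: novel / rare / low_frequency", {
  expect_equal(frequency_class(list(maf_exac = NA, maf_1000g = NA,
                                    maf_gnomad = NA), t0), "novel")
  expect_equal(frequency_class(list(maf_exac = 0.0005, maf_1000g = NA,
                                    maf_gnomad = NA), t0), "rare")
  # strict < 0.001 in every present database: 0.001/0.0003/0.002456 is not rare
  expect_equal(frequency_class(list(maf_exac = 0.0003, maf_1000g = 0.001,
                                    maf_gnomad = 0.002456), t0),
               "low_frequency")
  # the 0.0014 case falls on the low-frequency side of the strict rule
  expect_equal(frequency_class(list(maf_exac = 0.0014, maf_1000g = NA,
                                    maf_gnomad = NA), t0), "low_frequency")
})

full_sets <- structure(list(
  known_hm = "GENE1", hm_related = "GENE1", ocular_disease = "GENE1",
  adult_ocular = "GENE1", embryonic_ocular = "GENE1",
  myp_map = c(GENE1 = "MYP10")
), class = "hm_gene_sets")

cand_row <- function(consequence = "missense", maf_exac = NA_real_,
                     maf_1000g = NA_real_, maf_gnomad = NA_real_,
                     profile = csmd1_like) {
  df <- data.frame(consequence = consequence, maf_exac = maf_exac,
                   maf_1000g = maf_1000g, maf_gnomad = maf_gnomad,
                   stringsAsFactors = FALSE)
  for (nm in names(profile)) df[[nm]] <- profile[[nm]]
  df
}

test_that("evidence matrix computes bits, exclusivity and weighted totals", {
  ge_full <- gene_evidence("GENE1", full_sets)
  ev <- evidence_matrix(cand_row(), ge_full, t0)
  for (bit in c("known_hm_gene", "hm_related_gene", "ocular_disease_gene",
                "at_myp_locus", "multi_tool_damaging",
                "exonic_protein_altering", "expressed_adult_ocular",
                "expressed_embryonic_ocular", "freq_novel")) {
    expect_true(ev[[bit]], info = bit)
  }
  expect_false(ev$non_protein_altering)
  expect_false(ev$freq_rare)
  expect_equal(ev$weighted_total, 9.0) # all nine compatible bits at weight 1

  # splice candidate: annotation pair flips, default weight contributes 0
  ev_sp <- evidence_matrix(cand_row(consequence = "splice_site"), ge_full, t0)
  expect_true(ev_sp$non_protein_altering)
  expect_false(ev_sp$exonic_protein_altering)
  expect_equal(ev_sp$weighted_total, 8.0)

  # exactly one annotation bit and at most one frequency bit, always
  for (cq in c("missense", "splice_site", "nonsense")) {
    for (mafs in list(c(NA, NA, NA), c(0.0005, NA, NA), c(0.005, NA, NA))) {
      e <- evidence_matrix(cand_row(consequence = cq, maf_exac = mafs[1],
                                    maf_1000g = mafs[2], maf_gnomad = mafs[3]),
                           ge_full, t0)
      expect_equal(e$exonic_protein_altering + e$non_protein_altering, 1L)
      expect_lte(e$freq_novel + e$freq_rare, 1L)
    }
  }

  # no gene evidence, no damaging tools, low frequency: annotation bit only
  none <- gene_evidence("NOWHERE", full_sets)
  quiet <- stats::setNames(as.list(rep("tolerated", 9)), names(csmd1_like)[1:9])
  quiet$dann <- 0.1
  ev0 <- evidence_matrix(cand_row(maf_exac = 0.005, profile = quiet), none, t0)
  expect_equal(ev0$weighted_total, 1.0)

  # monotonicity: granting extra evidence never lowers the total
  ev_rare <- evidence_matrix(cand_row(maf_exac = 0.0005), none, t0)
  ev_rare_full <- evidence_matrix(cand_row(maf_exac = 0.0005), ge_full, t0)
  expect_gte(ev_rare_full$weighted_total, ev_rare$weighted_total)
})

test_that("ranking is by total then max-MAF then gene then key, and stable", {
  mk <- function(total, gene, key, exac = NA_real_) {
    data.frame(weighted_total = total, gene = gene, key = key,
               maf_exac = exac, maf_1000g = NA_real_, maf_gnomad = NA_real_,
               stringsAsFactors = FALSE)
  }
  df <- rbind(mk(5, "B", "1:5:A:G"), mk(9, "A", "1:1:A:G"),
              mk(7, "C", "1:3:A:G"))
  expect_equal(rank_candidates(df)$weighted_total, c(9, 7, 5))

  # equal totals: novel (absent MAF) outranks rare
  tie <- rbind(mk(5, "Z", "1:9:A:G", exac = 0.0005), mk(5, "Z", "1:8:A:G"))
  expect_equal(rank_candidates(tie)$key, c("1:8:A:G", "1:9:A:G"))

  # gene then key tie-breaks; permutation invariance
  tie2 <- rbind(mk(5, "B", "1:2:A:G"), mk(5, "A", "1:4:A:G"),
                mk(5, "A", "1:3:A:G"))
  ranked <- rank_candidates(tie2)
  expect_equal(ranked$key, c("1:3:A:G", "1:4:A:G", "1:2:A:G"))
  set.seed(1)
  for (i in 1:5) {
    expect_equal(rank_candidates(tie2[sample(3), ]), ranked)
  }
})

test_that("ACMG tags and classification", {
  expect_setequal(acmg_evidence("novel", TRUE, TRUE), c("PM2", "PP1", "PP3"))
  expect_equal(acmg_evidence("low_frequency", FALSE, FALSE), character(0))
  expect_setequal(acmg_evidence("rare", TRUE, FALSE), c("PM2", "PP1"))

  expect_equal(acmg_classify(c("PM2", "PP1", "PP3")), "uncertain_significance")
  expect_equal(acmg_classify(character(0)), "likely_benign")
  expect_equal(acmg_classify("PM2"), "uncertain_significance")
  # config-overridable combining table
  map <- list("PM2+PP1+PP3" = "likely_pathogenic")
  expect_equal(acmg_classify(c("PP1", "PM2", "PP3"), map), "likely_pathogenic")
  expect_equal(acmg_classify("PM2", map), "uncertain_significance")
  expect_error(acmg_classify("PM2", list(PM2 = "bogus")), "invalid")
})
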