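t0 <- hm_thresholds()

test_that("filter_consequence keeps protein/splice classes only", {
  v <- data.frame(consequence = c("missense", "synonymous", "splice_site",
                                  "intronic", "utr", "nonsense"),
                  stringsAsFactors = FALSE)
  res <- filter_consequence(v)
  expect_equal(res$kept$consequence, c("missense", "splice_site", "nonsense"))
  expect_equal(res$removed$consequence, c("synonymous", "intronic", "utr"))
  expect_error(filter_consequence(data.frame(consequence = "nonsynonymous")),
               "unknown consequence")
})

test_that("frequency exclusion is inclusive at the boundary, absent never removes", {
  expect_true(filter_frequency(list(maf_exac = 0.0014, maf_1000g = NA,
                                    maf_gnomad = NA), t0))
  expect_false(filter_frequency(list(maf_exac = NA, maf_1000g = NA,
                                     maf_gnomad = 0.01), t0))
  expect_true(filter_frequency(list(maf_exac = NA, maf_1000g = NA,
                                    maf_gnomad = NA), t0))
  expect_true(filter_frequency(list(maf_exac = 0.0099, maf_1000g = 0.0099,
                                    maf_gnomad = 0.0099), t0))
})

test_that("inheritance model assignment follows vertical transmission", {
  expect_equal(assign_inheritance_model(ad_trio()), "AD")
  sibs <- make_ped("F2", c("fa", "mo", "c1", "c2"),
                   c(NA, NA, "fa", "fa"), c(NA, NA, "mo", "mo"),
                   c("unaffected", "unaffected", "affected", "affected"))
  expect_equal(assign_inheritance_model(sibs), "AR")
  solo <- make_ped("F3", c("fa", "mo", "ch"), c(NA, NA, "fa"),
                   c(NA, NA, "mo"),
                   c("unaffected", "unaffected", "affected"))
  expect_equal(assign_inheritance_model(solo), "AR")
  expect_equal(assign_inheritance_model(solo, override = "AD"), "AD")
  none <- make_ped("F4", "x", NA_character_, NA_character_, "unaffected")
  expect_error(assign_inheritance_model(none), "no affected")
})

test_that("genotype-model filter enforces het-in-AD / hom-in-AR over typed members", {
  ped <- ad_trio()
  g <- gmat(list(k1 = c(fa = 1L, mo = 0L, ch = 1L),
                 k2 = c(fa = 1L, mo = 0L, ch = 2L),
                 k3 = c(fa = 1L, mo = 0L, ch = NA),
                 k4 = c(fa = NA, mo = 0L, ch = NA)))
  expect_true(filter_genotype_model("k1", g, ped, "AD", t0)$keep)
  expect_false(filter_genotype_model("k2", g, ped, "AD", t0)$keep)
  expect_false(filter_genotype_model("k2", g, ped, "AR", t0)$keep)
  # missing genotypes do not veto
  expect_true(filter_genotype_model("k3", g, ped, "AD", t0)$keep)
  # no genotyped affected member
  res <- filter_genotype_model("k4", g, ped, "AD", t0)
  expect_false(res$keep)
  expect_equal(res$reason, "untyped")
  # AR: affected het is removed
  ar <- make_ped("F2", c("fa", "mo", "ch"), c(NA, NA, "fa"), c(NA, NA, "mo"),
                 c("unaffected", "unaffected", "affected"))
  expect_false(filter_genotype_model("k1", g0 <- gmat(list(
    k1 = c(fa = 1L, mo = 1L, ch = 1L))), ar, "AR", t0)$keep)
  expect_true(filter_genotype_model("k1", gmat(list(
    k1 = c(fa = 1L, mo = 1L, ch = 2L))), ar, "AR", t0)$keep)
})

test_that("de novo detection requires both parents typed and homozygous reference", {
  ped <- ad_trio()
  g <- gmat(list(k1 = c(fa = 0L, mo = 0L, ch = 1L),
                 k2 = c(fa = NA, mo = 0L, ch = 1L),
                 k3 = c(fa = 0L, mo = 1L, ch = 1L)))
  expect_true(detect_de_novo("k1", g, ped, t0))
  expect_false(detect_de_novo("k2", g, ped, t0)) # missing parent: conservative
  expect_false(detect_de_novo("k3", g, ped, t0)) # inherited from carrier mother
})

test_that("constructed 10-variant fixture yields the hand-computed funnel", {
  fx <- cascade_fixture()
  casc <- run_cascade(fx$variants, fx$genotypes, list(fx$ped),
                      fx$annotations, t0)
  f <- casc$funnel
  expect_equal(f$stage, c("exonic", "synonymous", "frequency",
                          "genotype_model", "de_novo"))
  expect_equal(f$input, c(10L, 8L, 6L, 4L, 2L))
  expect_equal(f$kept, c(8L, 6L, 4L, 2L, 2L))
  expect_equal(f$removed, c(2L, 2L, 2L, 2L, 0L))
  expect_equal(sort(casc$survivors$pos), c(1009L, 1010L))
  # every removed candidate has exactly one earliest removal stage
  removed <- casc$candidates[!casc$candidates$kept, ]
  expect_false(any(is.na(removed$removed_stage)))
  expect_true(all(is.na(casc$candidates$removed_stage[casc$candidates$kept])))
})

test_that("degenerate cascades: empty input and all-clean input", {
  fx <- cascade_fixture()
  empty_g <- fx$genotypes[0, , drop = FALSE]
  casc <- run_cascade(fx$variants[0, ], empty_g, list(fx$ped),
                      fx$annotations, t0)
  expect_equal(casc$funnel$input, rep(0L, 5))
  expect_equal(casc$funnel$removed, rep(0L, 5))
  expect_equal(nrow(casc$survivors), 0L)

  clean_keys <- fx$annotations$key[9:10]
  casc2 <- run_cascade(fx$variants[fx$variants$key %in% clean_keys, ],
                       fx$genotypes[clean_keys, , drop = FALSE],
                       list(fx$ped), fx$annotations, t0)
  expect_equal(casc2$funnel$removed, rep(0L, 5))
  expect_equal(nrow(casc2$survivors), 2L)
})

test_that("cascade invariants hold on simulated cohorts", {
  for (seed in c(31, 32)) {
    sim <- simulate_cohort(sim_params(n_families = 4, n_ar = 3, n_ad = 1,
                                      n_background = 40, seed = seed))
    casc <- run_cascade(sim$variants, sim$genotypes, sim$pedigrees,
                        sim$annotations, t0)
    f <- casc$funnel
    # conservation at every stage, stage chaining, survivor count
    expect_equal(f$kept + f$removed, f$input)
    expect_equal(f$input[-1], f$kept[-nrow(f)])
    expect_equal(f$kept[nrow(f)], nrow(casc$survivors))
    expect_equal(sum(f$removed) + nrow(casc$survivors), f$input[1])

    # order-independence: permuting input variants leaves the surviving set
    set.seed(seed + 100)
    perm <- sample(nrow(sim$variants))
    casc_p <- run_cascade(sim$variants[perm, ],
                          sim$genotypes[perm, , drop = FALSE],
                          sim$pedigrees, sim$annotations, t0)
    id <- function(x) sort(paste(x$family_id, x$key))
    expect_equal(id(casc_p$survivors), id(casc$survivors))

    # monotonicity: lowering maf_exclusion never enlarges the surviving set
    t_strict <- hm_thresholds(maf_exclusion = 0.001, rare_maf = 5e-4)
    casc_s <- run_cascade(sim$variants, sim$genotypes, sim$pedigrees,
                          sim$annotations, t_strict)
    expect_true(all(id(casc_s$survivors) %in% id(casc$survivors)))
  }
})
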