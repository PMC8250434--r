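test_that("read_vcf maps genotypes and decomposes multi-allelic records", {
  path <- write_tmp_vcf(
    samples = c("P", "F"),
    records = list(
      list(chrom = "chr8", pos = 2913, ref = "C", alt = "T",
           gt = c("0/1", "0/0")),
      list(chrom = "2", pos = 500, ref = "A", alt = "G,T",
           gt = c("1/2", "0/2")),
      list(chrom = "3", pos = 77, ref = "G", alt = "A",
           gt = c("./.", "1|1"))
    )
  )
  vc <- read_vcf(path)
  expect_equal(nrow(vc$variants), 4L) # record 2 decomposed into two
  expect_equal(vc$variants$key,
               c("8:2913:C:T", "2:500:A:G", "2:500:A:T", "3:77:G:A"))
  expect_equal(vc$genotypes["8:2913:C:T", ], c(P = 1L, F = 0L))
  # 1/2 is het for each decomposed alt; the other alt counts as reference
  expect_equal(vc$genotypes["2:500:A:G", ], c(P = 1L, F = 0L))
  expect_equal(vc$genotypes["2:500:A:T", ], c(P = 1L, F = 1L))
  expect_true(is.na(vc$genotypes["3:77:G:A", "P"]))
  expect_equal(vc$genotypes["3:77:G:A", "F"], 2L)
  expect_error(read_vcf(tempfile()), "not found")
})

test_that("decomposition conserves non-reference allele observations", {
  set.seed(11)
  samples <- paste0("s", 1:6)
  records <- lapply(1:20, function(i) {
    n_alt <- sample(1:3, 1)
    alts <- sample(setdiff(c("A", "C", "G", "T"), "A"), n_alt)
    gt <- vapply(samples, function(s) {
      if (stats::runif(1) < 0.1) return("./.")
      paste(sample(0:n_alt, 2, replace = TRUE), collapse = "/")
    }, character(1))
    list(chrom = "1", pos = 1000 + i, ref = "A",
         alt = paste(alts, collapse = ","), gt = gt)
  })
  vc <- read_vcf(write_tmp_vcf(samples, records))
  for (i in seq_along(records)) {
    keys <- grep(paste0("^1:", 1000 + i, ":"), rownames(vc$genotypes),
                 value = TRUE)
    gt <- records[[i]]$gt
    for (s in samples) {
      if (gt[s] == "./.") {
        expect_true(all(is.na(vc$genotypes[keys, s])))
      } else {
        original <- sum(as.integer(strsplit(gt[s], "/")[[1]]) > 0)
        expect_equal(sum(vc$genotypes[keys, s]), original)
      }
    }
  }
})

test_that("VCF dosage round-trips through write_vcf", {
  sim <- simulate_cohort(sim_params(n_families = 2, n_ar = 1, n_ad = 1,
                                    n_background = 10, seed = 5))
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$variants, sim$genotypes, path)
  back <- read_vcf(path)
  expect_setequal(rownames(back$genotypes), rownames(sim$genotypes))
  ord <- rownames(sim$genotypes)
  expect_equal(back$genotypes[ord, colnames(sim$genotypes)], sim$genotypes)
})

test_that("read_ped parses trios, founders and rejects invalid parentage", {
  path <- tempfile()
  writeLines(c("FAM1\tF\t0\t0\t1\t2",
               "FAM1\tM\t0\t0\t2\t1",
               "FAM1\tC\tF\tM\t1\t2",
               "FAM2\tX\t0\t0\t0\t0"), path)
  peds <- read_ped(path)
  expect_named(peds, c("FAM1", "FAM2"))
  ch <- peds$FAM1$members[peds$FAM1$members$id == "C", ]
  expect_equal(ch$father_id, "F")
  expect_equal(ch$mother_id, "M")
  expect_equal(ch$declared_status, "affected")
  expect_true(is.na(peds$FAM1$members$father_id[1])) # "0" parent => founder
  expect_equal(peds$FAM2$members$declared_status, "unknown")
  expect_setequal(founders(peds$FAM1), c("F", "M"))

  self <- tempfile()
  writeLines("FAM1\tA\tA\t0\t1\t2", self)
  expect_error(read_ped(self), "own parent")

  dup <- tempfile()
  writeLines(c("FAM1\tA\t0\t0\t1\t2", "FAM1\tA\t0\t0\t1\t2"), dup)
  expect_error(read_ped(dup), "duplicate")
})

test_that("pedigree validation agrees with igraph DAG oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    ids <- paste0("m", seq_len(n))
    fathers <- rep(NA_character_, n)
    mothers <- rep(NA_character_, n)
    for (i in seq_len(n)) { # parents sampled anywhere, cycles possible
      if (stats::runif(1) < 0.7) fathers[i] <- sample(setdiff(ids, ids[i]), 1)
      if (stats::runif(1) < 0.7) mothers[i] <- sample(setdiff(ids, ids[i]), 1)
    }
    edges <- character(0)
    for (i in seq_len(n)) {
      for (p in c(fathers[i], mothers[i])) {
        if (!is.na(p)) edges <- c(edges, p, ids[i])
      }
    }
    g <- igraph::make_graph(edges, directed = TRUE)
    acyclic <- igraph::is_dag(g)
    build <- function() make_ped("R", ids, fathers, mothers,
                                 status = rep("unknown", n))
    if (acyclic) expect_silent(build())
    else expect_error(build(), "ancestor")
  }
})

test_that("read_annotation_table parses frequencies, calls and rejects bad input", {
  path <- write_tmp_annotations(list(
    ann_row("8", 2913, "C", "T", gene = "CSMD1", maf_exac = 0.0014,
            sift = "damaging", dann = 0.999),
    ann_row("1", 100, "A", "G", gene = "NOVELG")
  ))
  ann <- read_annotation_table(path)
  expect_equal(ann["8:2913:C:T", "maf_exac"], 0.0014)
  expect_true(is.na(ann["8:2913:C:T", "maf_1000g"]))
  expect_true(is.na(ann["8:2913:C:T", "maf_gnomad"]))
  expect_true(all(is.na(ann["1:100:A:G",
                            c("maf_exac", "maf_1000g", "maf_gnomad")])))
  expect_equal(ann["8:2913:C:T", "sift"], "damaging")

  expect_error(read_annotation_table(write_tmp_annotations(list(
    ann_row("1", 1, "A", "G", dann = 1.3)))), "dann out of")
  expect_error(read_annotation_table(write_tmp_annotations(list(
    ann_row("1", 1, "A", "G", maf_exac = 2)))), "out of")
  expect_error(read_annotation_table(write_tmp_annotations(list(
    ann_row("1", 1, "A", "G", consequence = "weird")))), "consequence")

  extra <- tempfile(fileext = ".tsv")
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  tab$cadd <- "1"
  utils::write.table(tab, extra, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation_table(extra), "unknown annotation columns")
})

test_that("gene sets resolve to evidence rows, absent genes all-false", {
  d <- tempfile(); dir.create(d)
  writeLines("ZNF644", file.path(d, "known_hm.txt"))
  writeLines(c("CSMD1\tMYP10", "FNDC3B\tMYP8"), file.path(d, "myp_map.tsv"))
  sets <- read_gene_sets_dir(d)
  ev <- gene_evidence(c("ZNF644", "CSMD1", "NOWHERE"), sets)
  expect_true(ev$is_known_hm_gene[1])
  expect_false(any(ev$is_known_hm_gene[-1]))
  expect_equal(ev$myp_locus[2], "MYP10")
  expect_true(is.na(ev$myp_locus[1]))
  expect_false(any(unlist(ev[3, c("is_known_hm_gene", "is_hm_related",
                                  "is_ocular_disease_gene",
                                  "expressed_adult_ocular",
                                  "expressed_embryonic_ocular")])))
  expect_error(read_gene_sets(list(known_hm = tempfile())), "known_hm")
  expect_error(read_gene_sets(list(bogus = "x")), "unknown gene-set")
})

test_that("clinical table parsing handles ranges, degenerate rows and errors", {
  path <- tempfile()
  writeLines(c("family\tproband_age\taffected\tse_range\tse_median\tal_range\tal_median",
               "85\t57\t2\t-19.50/-23.75\t-20.25\t29.61/31.72\t30.85",
               "102\t17\t1\t-7.50/-7.50\t-7.50\t27.46/27.50\t27.48"), path)
  clin <- read_clinical_table(path)
  expect_equal(clin$se_low[1], -23.75)
  expect_equal(clin$se_high[1], -19.50)
  expect_equal(clin$se_median[1], -20.25)
  expect_equal(clin$al_median[1], 30.85)
  expect_equal(clin$se_low[2], clin$se_high[2]) # degenerate range accepted

  bad <- tempfile()
  writeLines(c("family\tproband_age\taffected\tse_range\tse_median\tal_range\tal_median",
               "9\t20\t1\tx/-7\t-7\t26/27\t26.5"), bad)
  expect_error(read_clinical_table(bad), "family 9")
})

test_that("variant_key normalizes chromosome labels and is stable", {
  expect_equal(variant_key("chr8", 2913, "C", "T"),
               variant_key("8", 2913, "C", "T"))
  expect_false(variant_key("8", 2913, "C", "T") ==
                 variant_key("8", 2913, "C", "A"))
  expect_equal(variant_key("chrX", 5, "A", "G"), "X:5:A:G")
  v <- variant_key("chr2", 10, "A", "T")
  expect_identical(v, variant_key("chr2", 10, "A", "T"))
})

test_that("ranked table read/write round-trips all fields", {
  path <- tempfile(fileext = ".tsv")
  write_ranked_table(path, data.frame())
  empty <- read_ranked_table(path)
  expect_equal(nrow(empty), 0L)

  sim <- simulate_cohort(sim_params(n_families = 3, n_ar = 2, n_ad = 1,
                                    n_background = 20, seed = 9))
  ranked <- score_cohort(sim)$ranked
  expect_gt(nrow(ranked), 1L)
  write_ranked_table(path, ranked)
  back <- read_ranked_table(path)
  cats <- c("known_hm_gene", "hm_related_gene", "ocular_disease_gene",
            "at_myp_locus", "multi_tool_damaging", "exonic_protein_altering",
            "non_protein_altering", "expressed_adult_ocular",
            "expressed_embryonic_ocular", "freq_novel", "freq_rare")
  for (cc in cats) expect_equal(back[[cc]], ranked[[cc]], info = cc)
  expect_equal(back$weighted_total, ranked$weighted_total)
  expect_equal(back$variant_key, ranked$variant_key)
  # write -> read -> write is idempotent
  path2 <- tempfile(fileext = ".tsv")
  write_ranked_table(path2, back)
  expect_identical(readLines(path), readLines(path2))
})
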