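# shared fixture builders and independent oracles

# quick pedigree: statuses named by role id
make_ped <- function(family = "FAM1", ids, fathers, mothers, status,
                     se_right = NA_real_, se_left = NA_real_,
                     al_right = NA_real_, al_left = NA_real_) {
  pedigree(family, data.frame(
    id = ids, father_id = fathers, mother_id = mothers,
    sex = "unknown", declared_status = status,
    se_right = se_right, se_left = se_left,
    al_right = al_right, al_left = al_left,
    stringsAsFactors = FALSE
  ))
}

# AD-style trio: affected father, unaffected mother, affected child
ad_trio <- function(family = "FAM1") {
  make_ped(family, c("fa", "mo", "ch"),
           c(NA, NA, "fa"), c(NA, NA, "mo"),
           c("affected", "unaffected", "affected"))
}

# dosage matrix from a named list key -> c(member = dosage)
gmat <- function(rows) {
  ids <- unique(unlist(lapply(rows, names)))
  m <- matrix(NA_integer_, length(rows), length(ids),
              dimnames = list(names(rows), ids))
  for (k in names(rows)) m[k, names(rows[[k]])] <- rows[[k]]
  m
}

write_tmp_vcf <- function(samples, records) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  for (r in records) {
    lines <- c(lines, paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
                              ".", "GT", r$gt), collapse = "\t"))
  }
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

# annotation TSV writer covering the full schema; `rows` is a list of named
# lists, unspecified cells are empty (absent)
write_tmp_annotations <- function(rows) {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "transcript", "cdna_hgvs",
            "consequence", "maf_exac", "maf_1000g", "maf_gnomad",
            "popmax_filtering_af", "sift", "polyphen2_hdiv", "polyphen2_hvar",
            "mutation_taster", "lrt", "mutation_assessor", "fathmm",
            "radialsvm", "lr", "dann")
  lines <- paste(cols, collapse = "\t")
  for (r in rows) {
    vals <- vapply(cols, function(cc) {
      v <- r[[cc]]
      if (is.null(v) || is.na(v)) "" else as.character(v)
    }, character(1))
    lines <- c(lines, paste(vals, collapse = "\t"))
  }
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# annotation row defaults for a clean rare missense variant
ann_row <- function(chrom, pos, ref, alt, consequence = "missense",
                    gene = "GENEX", ...) {
  utils::modifyList(
    list(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
         consequence = consequence),
    list(...)
  )
}

# independent cosegregation oracle: literal member-by-member transcription of
# the rule, kept deliberately separate from the package implementation
oracle_coseg <- function(status, dos, model) {
  for (id in names(status)) {
    d <- dos[[id]]
    if (is.null(d) || is.na(d)) next
    st <- status[[id]]
    if (model == "AD") {
      if (st == "affected" && d != 1) return(FALSE)
      if (st == "unaffected" && d != 0) return(FALSE)
    } else {
      if (st == "affected" && d != 2) return(FALSE)
      if (st == "unaffected" && d == 2) return(FALSE)
    }
  }
  TRUE
}

# random pedigree with n members (first two founders, later members children
# of random earlier members or founders) and random declared statuses
random_pedigree <- function(n, family = "R1") {
  ids <- paste0("m", seq_len(n))
  fathers <- rep(NA_character_, n)
  mothers <- rep(NA_character_, n)
  for (i in 3:n) {
    if (stats::runif(1) < 0.6) {
      parents <- sample(ids[seq_len(i - 1)], 2)
      fathers[i] <- parents[1]
      mothers[i] <- parents[2]
    }
  }
  make_ped(family, ids, fathers, mothers,
           status = sample(c("affected", "unaffected", "unknown"), n,
                           replace = TRUE))
}

# hand-built 10-variant cascade fixture on one AD trio: two intronic, two
# synonymous, two common (MAF 0.05), two model-inconsistent, two clean
cascade_fixture <- function() {
  ped <- ad_trio("FAM1")
  specs <- list(
    v1 = list(consequence = "intronic"), v2 = list(consequence = "intronic"),
    v3 = list(consequence = "synonymous"), v4 = list(consequence = "synonymous"),
    v5 = list(consequence = "missense", maf_exac = 0.05),
    v6 = list(consequence = "missense", maf_gnomad = 0.05),
    v7 = list(consequence = "missense"), v8 = list(consequence = "missense"),
    v9 = list(consequence = "missense"), v10 = list(consequence = "missense")
  )
  rows <- lapply(seq_along(specs), function(i) {
    do.call(ann_row, c(list(chrom = "1", pos = 1000L + i, ref = "A",
                            alt = "G"), specs[[i]]))
  })
  ann <- read_annotation_table(write_tmp_annotations(rows))
  variants <- ann[, c("chrom", "pos", "ref", "alt", "key")]
  # model-inconsistent candidates (v7, v8): affected child homozygous
  dos <- lapply(seq_along(specs), function(i) {
    if (i %in% 7:8) c(fa = 1L, mo = 1L, ch = 2L) else c(fa = 1L, mo = 0L, ch = 1L)
  })
  names(dos) <- ann$key
  list(ped = ped, variants = variants, annotations = ann, genotypes = gmat(dos))
}

# score every cosegregating survivor of a simulated cohort (in-memory run)
score_cohort <- function(sim, t = hm_thresholds()) {
  casc <- run_cascade(sim$variants, sim$genotypes, sim$pedigrees,
                      sim$annotations, t)
  parts <- partition_by_segregation(casc$survivors, sim$genotypes,
                                    sim$pedigrees, t)
  ranked <- rank_candidates(score_candidates(parts$cosegregating,
                                             sim$gene_sets, t))
  list(cascade = casc, parts = parts, ranked = ranked)
}

# fraction of families whose spiked causal variant ranks first
causal_first_rate <- function(sim, ranked) {
  per_family <- split(ranked, ranked$family_id)
  firsts <- vapply(per_family, function(df) df$variant_key[1], character(1))
  mean(sim$truth$variant_key == firsts[sim$truth$family_id], na.rm = TRUE)
}
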