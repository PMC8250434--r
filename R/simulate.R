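# gene pools used by the simulator: established high-myopia genes (causal
# spikes draw from these) and a generic background symbol space
KNOWN_HM_GENE_POOL <- c("ZNF644", "SCO2", "SLC39A5", "P4HA2", "BSG", "CCDC111",
                        "LEPREL1", "LRPAP1", "CTSH", "CSMD1", "PARP8",
                        "ADAMTSL1", "FNDC3B")
MYP_LOCI <- paste0("MYP", c(1:3, 5:26))

#' Simulation parameters
#'
#' The stated world of the synthetic cohort: 27 families with an 18 AR / 9 AD
#' inheritance mix, pedigree templates cycling through trio, quartet and
#' three-generation structures, one spiked causal variant per family and 200
#' family-private background variants. Background database frequencies follow
#' a four-class mixture (novel / rare / low-frequency / common, equal weights
#' by default); each background variant is transmitted by gene drop at a
#' latent cohort founder frequency (log-uniform 0.005-0.05) independent of
#' its database class, so the cascade actually sees background candidates.
#' Causal spikes are missense, novel with probability `causal_novel_prob`
#' (else rare), multi-tool damaging at `causal_tool_damaging` per tool, and
#' land in established high-myopia genes carrying adult and embryonic ocular
#' expression evidence. Background gene-evidence bits are sprinkled sparsely
#' (`background_evidence_prob` each) so background occasionally mimics causal
#' evidence.
#'
#' @param n_families number of families.
#' @param n_ar,n_ad counts of recessive / dominant families
#'   (`n_ar + n_ad == n_families`).
#' @param templates pedigree templates cycled across families.
#' @param n_background family-private background variants per family.
#' @param freq_weights named mixture weights over
#'   `c(novel, rare, low, common)`; must sum to 1.
#' @param causal_tool_damaging per-tool damaging probability for causal
#'   spikes.
#' @param background_tool_damaging per-tool damaging probability for
#'   background variants.
#' @param causal_novel_prob probability a causal spike is novel (absent from
#'   all three databases) rather than rare.
#' @param background_evidence_prob per-bit probability for background gene
#'   evidence.
#' @param seed integer seed; all randomness flows from one stream seeded with
#'   this value.
#' @return object of class `hm_sim_params`.
#' @export
sim_params <- function(n_families = 27L, n_ar = 18L, n_ad = 9L,
                       templates = c("trio", "quartet", "three_generation"),
                       n_background = 200L,
                       freq_weights = c(novel = 0.25, rare = 0.25,
                                        low = 0.25, common = 0.25),
                       causal_tool_damaging = 0.9,
                       background_tool_damaging = 0.1,
                       causal_novel_prob = 0.7,
                       background_evidence_prob = 0.05,
                       seed = 42L) {
  if (n_ar + n_ad != n_families) stop("n_ar + n_ad must equal n_families")
  stopifnot(all(templates %in% c("trio", "quartet", "three_generation")))
  if (!isTRUE(all.equal(sum(freq_weights), 1)) ||
      !setequal(names(freq_weights), c("novel", "rare", "low", "common"))) {
    stop("freq_weights must be named novel/rare/low/common and sum to 1")
  }
  structure(
    list(n_families = as.integer(n_families), n_ar = as.integer(n_ar),
         n_ad = as.integer(n_ad), templates = templates,
         n_background = as.integer(n_background),
         freq_weights = freq_weights[c("novel", "rare", "low", "common")],
         causal_tool_damaging = causal_tool_damaging,
         background_tool_damaging = background_tool_damaging,
         causal_novel_prob = causal_novel_prob,
         background_evidence_prob = background_evidence_prob,
         seed = as.integer(seed)),
    class = "hm_sim_params"
  )
}

rtrunc_norm_upper <- function(n, mean, sd, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x <= upper) break
    }
    out[i] <- x
  }
  out
}

# affected eyes: person-level SE from a truncated normal (mean -10 D, sd 3,
# <= -6), per-eye jitter clipped back to the affected range; AL tracks SE
# (AL = 23.5 - 0.3 * SE + noise, sd 0.3 mm)
sim_phenotype <- function(affected) {
  if (affected) {
    base <- rtrunc_norm_upper(1, -10, 3, -6.5)
    se <- pmin(-6, base + stats::rnorm(2, 0, 0.25))
  } else {
    base <- max(-1.8, min(1.8, stats::rnorm(1, 0, 0.75)))
    se <- pmax(-1.99, pmin(1.99, base + stats::rnorm(2, 0, 0.2)))
  }
  al <- 23.5 - 0.3 * se + stats::rnorm(2, 0, 0.3)
  list(se_right = se[1], se_left = se[2], al_right = al[1], al_left = al[2])
}

#' Simulate one pedigree with phenotypes
#'
#' Builds a family under one of three templates. Dominant families show
#' vertical transmission (an affected parent — and in the three-generation
#' template an affected grandparent — above each affected child); recessive
#' families have only affected children below unaffected carrier parents.
#' Affected spherical equivalents come from a truncated normal (mean -10 D,
#' sd 3, at most -6 D) so every affected member satisfies the high-myopia
#' inclusion criterion; unaffected members sit strictly within +/-2 D. Draws
#' come from the current RNG stream (seed it before calling).
#'
#' @param family_id family identifier.
#' @param template `"trio"`, `"quartet"` or `"three_generation"`.
#' @param model `"AD"` or `"AR"`.
#' @return an `hm_pedigree` with phenotype columns and declared statuses set.
#' @export
simulate_pedigree <- function(family_id, template, model) {
  stopifnot(template %in% c("trio", "quartet", "three_generation"),
            model %in% c("AD", "AR"))
  p <- function(role) paste0(family_id, "_", role)
  child_sex <- function() sample(c("male", "female"), 1)
  if (template == "trio") {
    ids <- p(c("fa", "mo", "ch"))
    fathers <- c(NA, NA, ids[1]); mothers <- c(NA, NA, ids[2])
    sexes <- c("male", "female", child_sex())
    affected <- if (model == "AD") c(TRUE, FALSE, TRUE) else c(FALSE, FALSE, TRUE)
  } else if (template == "quartet") {
    ids <- p(c("fa", "mo", "c1", "c2"))
    fathers <- c(NA, NA, ids[1], ids[1]); mothers <- c(NA, NA, ids[2], ids[2])
    sexes <- c("male", "female", child_sex(), child_sex())
    affected <- if (model == "AD") {
      c(TRUE, FALSE, TRUE, FALSE)
    } else {
      c(FALSE, FALSE, TRUE, stats::runif(1) < 0.5)
    }
  } else {
    ids <- p(c("gfa", "gmo", "fa", "mo", "ch"))
    fathers <- c(NA, NA, ids[1], NA, ids[3])
    mothers <- c(NA, NA, ids[2], NA, ids[4])
    sexes <- c("male", "female", "male", "female", child_sex())
    affected <- if (model == "AD") {
      c(TRUE, FALSE, TRUE, FALSE, TRUE)
    } else {
      c(FALSE, FALSE, FALSE, FALSE, TRUE)
    }
  }
  phen <- lapply(affected, sim_phenotype)
  members <- data.frame(
    id = ids, father_id = fathers, mother_id = mothers, sex = sexes,
    declared_status = ifelse(affected, "affected", "unaffected"),
    se_right = vapply(phen, `[[`, 0, "se_right"),
    se_left = vapply(phen, `[[`, 0, "se_left"),
    al_right = vapply(phen, `[[`, 0, "al_right"),
    al_left = vapply(phen, `[[`, 0, "al_left"),
    stringsAsFactors = FALSE
  )
  pedigree(family_id, members)
}

#' Gene drop of one variant through a pedigree
#'
#' Founders draw genotypes from Hardy-Weinberg proportions at the given
#' allele frequency; each child allele is copied independently from a
#' uniformly chosen allele of the corresponding parent, in generation order.
#'
#' @param ped an `hm_pedigree`.
#' @param freq founder alternate-allele frequency in \[0,1\].
#' @return named integer dosage vector over family members.
#' @export
gene_drop <- function(ped, freq) {
  stopifnot(freq >= 0, freq <= 1)
  m <- ped$members
  dos <- stats::setNames(rep(NA_integer_, nrow(m)), m$id)
  todo <- seq_len(nrow(m))
  while (length(todo)) {
    progressed <- FALSE
    for (i in todo) {
      fa <- m$father_id[i]; mo <- m$mother_id[i]
      if (is.na(fa) && is.na(mo)) {
        dos[m$id[i]] <- stats::rbinom(1, 2, freq)
      } else {
        if ((!is.na(fa) && is.na(dos[fa])) || (!is.na(mo) && is.na(dos[mo]))) next
        transmit <- function(pid) {
          if (is.na(pid)) stats::rbinom(1, 1, freq) # unlisted parent: population allele
          else stats::rbinom(1, 1, dos[[pid]] / 2)
        }
        dos[m$id[i]] <- transmit(fa) + transmit(mo)
      }
      progressed <- TRUE
    }
    todo <- which(is.na(dos))
    if (!progressed && length(todo)) {
      stop("gene_drop: unresolvable parent order in family ", ped$family_id)
    }
  }
  dos
}

loguni <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

random_variant_site <- function(n) {
  data.frame(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

draw_tool_calls <- function(p_damaging) {
  calls <- ifelse(stats::runif(length(TOOL_CALL_COLS)) < p_damaging,
                  "damaging", "tolerated")
  dann <- if (stats::runif(1) < p_damaging) stats::runif(1, 0.9, 1)
          else stats::runif(1, 0, 0.9)
  c(stats::setNames(as.list(calls), TOOL_CALL_COLS), list(dann = dann))
}

#' Spike a causal variant into one family
#'
#' Constructs genotypes exactly matching the family's inheritance model:
#' under AD every affected member is heterozygous and every unaffected is
#' homozygous reference; under AR every affected member is homozygous
#' alternate, parents of affecteds are obligate heterozygous carriers, and
#' other relatives draw Mendelian-consistent non-affected genotypes. The
#' annotation row is missense, novel or rare, and damaging per the causal
#' tool-concordance. Draws come from the current RNG stream.
#'
#' @param ped an `hm_pedigree`.
#' @param model `"AD"` or `"AR"`.
#' @param params an [sim_params()] object.
#' @param gene gene symbol for the spike.
#' @param site one-row data.frame with chrom, pos, ref (a fresh site).
#' @return list with `variant` (one-row data.frame incl. annotation columns),
#'   `genotypes` (named dosage vector) and `truth` (one-row data.frame).
#' @export
spike_causal <- function(ped, model, params, gene, site = random_variant_site(1)) {
  m <- ped$members
  status <- stats::setNames(m$declared_status, m$id)
  dos <- stats::setNames(rep(0L, nrow(m)), m$id)
  if (model == "AD") {
    dos[status == "affected"] <- 1L
  } else {
    dos[status == "affected"] <- 2L
    for (i in which(status == "affected")) {
      for (pid in c(m$father_id[i], m$mother_id[i])) {
        if (!is.na(pid) && status[[pid]] != "affected") dos[pid] <- 1L
      }
    }
    # remaining unaffected members (e.g. AR quartet sibs): het or ref,
    # Mendelian-consistent under carrier parents
    rest <- names(dos)[dos == 0L & status == "unaffected"]
    for (id in rest) {
      i <- match(id, m$id)
      if (!is.na(m$father_id[i]) && dos[m$father_id[i]] >= 1L) {
        dos[id] <- stats::rbinom(1, 1, 2 / 3)
      }
    }
    # propagate carriership upward so no carrier is Mendelian-impossible
    # (e.g. the three-generation template's carrier parent needs a carrier
    # grandparent)
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(m))) {
        fa <- m$father_id[i]; mo <- m$mother_id[i]
        if (is.na(fa) || is.na(mo)) next
        if (dos[m$id[i]] >= 1L && dos[fa] == 0L && dos[mo] == 0L) {
          dos[fa] <- 1L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  alt <- sample(setdiff(c("A", "C", "G", "T"), site$ref), 1)
  novel <- stats::runif(1) < params$causal_novel_prob
  freqs <- if (novel) {
    list(maf_exac = NA_real_, maf_1000g = NA_real_, maf_gnomad = NA_real_)
  } else {
    present <- stats::runif(3) < 0.8
    if (!any(present)) present[sample.int(3, 1)] <- TRUE
    v <- ifelse(present, loguni(3, 1e-5, 9e-4), NA_real_)
    list(maf_exac = v[1], maf_1000g = v[2], maf_gnomad = v[3])
  }
  tools <- draw_tool_calls(params$causal_tool_damaging)
  variant <- data.frame(
    chrom = site$chrom, pos = site$pos, ref = site$ref, alt = alt,
    gene = gene, transcript = paste0("NM_", sample.int(999999, 1)),
    cdna_hgvs = NA_character_, consequence = "missense",
    maf_exac = freqs$maf_exac, maf_1000g = freqs$maf_1000g,
    maf_gnomad = freqs$maf_gnomad,
    popmax_filtering_af = if (novel) NA_real_ else loguni(1, 1e-5, 9e-4),
    stringsAsFactors = FALSE
  )
  for (nm in names(tools)) variant[[nm]] <- tools[[nm]]
  variant$key <- variant_key(variant$chrom, variant$pos, variant$ref, variant$alt)
  list(
    variant = variant,
    genotypes = dos,
    truth = data.frame(family_id = ped$family_id, variant_key = variant$key,
                       model = model, expected_to_survive = TRUE,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a whole cohort in memory
#'
#' Generates pedigrees (inheritance mix and templates per [sim_params()]),
#' one causal spike per family, family-private background variants with
#' database frequencies from the mixture model and genotypes from
#' [gene_drop()], the sparse background gene-evidence sets, and a clinical
#' summary table. A single RNG stream is seeded from `params$seed`, so equal
#' parameters give identical cohorts.
#'
#' @param params an [sim_params()] object.
#' @return list of class `hm_cohort`: `params`, `pedigrees`, `variants`,
#'   `genotypes` (dosage matrix), `annotations` (`hm_annotations`),
#'   `gene_sets`, `truth`, `clinical` (data.frame in clinical-table dialect).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "hm_sim_params"))
  set.seed(params$seed)
  fam_ids <- sprintf("F%03d", seq_len(params$n_families))
  models <- rep(c("AR", "AD"), c(params$n_ar, params$n_ad))
  templates <- rep_len(params$templates, params$n_families)

  pedigrees <- stats::setNames(vector("list", params$n_families), fam_ids)
  for (i in seq_len(params$n_families)) {
    pedigrees[[i]] <- simulate_pedigree(fam_ids[i], templates[i], models[i])
  }
  all_ids <- unlist(lapply(pedigrees, function(p) p$members$id), use.names = FALSE)

  # causal spikes: one per family, genes cycled from the known-HM pool
  causal_genes <- rep_len(sample(KNOWN_HM_GENE_POOL), params$n_families)
  spikes <- vector("list", params$n_families)
  for (i in seq_len(params$n_families)) {
    spikes[[i]] <- spike_causal(pedigrees[[i]], models[i], params,
                                causal_genes[i])
  }

  # background variants: family-private sites; db MAF class vs latent cohort
  # founder frequency are independent (see vignette)
  n_bg_total <- params$n_background * params$n_families
  bg_gene_pool <- sprintf("BG%04d", seq_len(max(200L, n_bg_total %/% 10L)))
  classes <- sample(names(params$freq_weights), n_bg_total, replace = TRUE,
                    prob = params$freq_weights)
  bg_sites <- random_variant_site(n_bg_total)
  one_or_none <- function(x) if (n_bg_total) x else x[0]
  bg <- data.frame(
    chrom = bg_sites$chrom, pos = bg_sites$pos, ref = bg_sites$ref,
    alt = vapply(bg_sites$ref,
                 function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                 character(1), USE.NAMES = FALSE),
    gene = sample(bg_gene_pool, n_bg_total, replace = TRUE),
    transcript = one_or_none(NA_character_),
    cdna_hgvs = one_or_none(NA_character_),
    consequence = sample(c("missense", "nonsense", "frameshift",
                           "inframe_indel", "splice_site", "synonymous",
                           "intronic", "utr", "intergenic", "other"),
                         n_bg_total, replace = TRUE,
                         prob = c(0.35, 0.04, 0.04, 0.02, 0.05, 0.15,
                                  0.20, 0.09, 0.04, 0.02)),
    stringsAsFactors = FALSE
  )
  draw_maf <- function(cls) {
    switch(cls,
           novel = rep(NA_real_, 3),
           rare = ifelse(stats::runif(3) < 0.8, loguni(3, 1e-5, 9e-4), NA_real_),
           low = ifelse(stats::runif(3) < 0.9, loguni(3, 1e-3, 9.9e-3), NA_real_),
           common = loguni(3, 1e-2, 0.5))
  }
  mafs <- t(vapply(classes, draw_maf, numeric(3), USE.NAMES = FALSE))
  # the rare/low classes guarantee at least one present value
  none <- rowSums(!is.na(mafs)) == 0L & classes != "novel"
  if (any(none)) {
    mafs[none, 1] <- ifelse(classes[none] == "rare",
                            loguni(sum(none), 1e-5, 9e-4),
                            loguni(sum(none), 1e-3, 9.9e-3))
  }
  bg$maf_exac <- mafs[, 1]; bg$maf_1000g <- mafs[, 2]; bg$maf_gnomad <- mafs[, 3]
  popmax <- suppressWarnings(
    vapply(seq_len(n_bg_total), function(i) max(mafs[i, ], na.rm = TRUE),
           numeric(1)))
  popmax[!is.finite(popmax)] <- NA_real_
  bg$popmax_filtering_af <- popmax
  bg_tools <- lapply(seq_len(n_bg_total),
                     function(i) draw_tool_calls(params$background_tool_damaging))
  for (nm in c(TOOL_CALL_COLS, "dann")) {
    bg[[nm]] <- vapply(bg_tools, function(x) x[[nm]],
                       if (nm == "dann") numeric(1) else character(1))
  }
  bg$key <- variant_key(bg$chrom, bg$pos, bg$ref, bg$alt)
  bg$family_id <- rep(fam_ids, each = params$n_background)
  bg$latent_freq <- loguni(n_bg_total, 0.005, 0.05)

  variants <- rbind(
    do.call(rbind, lapply(spikes, `[[`, "variant")),
    bg[, setdiff(names(bg), c("family_id", "latent_freq"))]
  )
  dup <- duplicated(variants$key)
  if (any(dup)) { # resolve rare site collisions deterministically
    variants$pos[dup] <- variants$pos[dup] + seq_len(sum(dup))
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
  }
  rownames(variants) <- NULL
  causal_keys <- variants$key[seq_len(params$n_families)]

  genotypes <- matrix(0L, nrow(variants), length(all_ids),
                      dimnames = list(variants$key, all_ids))
  for (i in seq_len(params$n_families)) {
    genotypes[causal_keys[i],
              names(spikes[[i]]$genotypes)] <- spikes[[i]]$genotypes
  }
  bg_keys <- variants$key[-seq_len(params$n_families)]
  for (j in seq_len(n_bg_total)) {
    ped <- pedigrees[[bg$family_id[j]]]
    genotypes[bg_keys[j], ped$members$id] <- gene_drop(ped, bg$latent_freq[j])
  }

  # gene evidence: causal genes are established HM genes with both expression
  # flags; background genes carry sparse random bits
  pe <- params$background_evidence_prob
  bg_bits <- function() bg_gene_pool[stats::runif(length(bg_gene_pool)) < pe]
  myp_genes <- bg_gene_pool[stats::runif(length(bg_gene_pool)) < pe / 2]
  gene_sets <- structure(list(
    known_hm = sort(unique(c(KNOWN_HM_GENE_POOL, bg_bits()))),
    hm_related = sort(bg_bits()),
    ocular_disease = sort(bg_bits()),
    adult_ocular = sort(unique(c(KNOWN_HM_GENE_POOL, bg_bits()))),
    embryonic_ocular = sort(unique(c(KNOWN_HM_GENE_POOL, bg_bits()))),
    myp_map = stats::setNames(sample(MYP_LOCI, length(myp_genes), replace = TRUE),
                              myp_genes)
  ), class = "hm_gene_sets")

  clinical <- do.call(rbind, lapply(seq_along(pedigrees), function(i) {
    fs <- family_summary(pedigrees[[i]])
    data.frame(
      family = fs$family_id,
      proband_age = sample(15:35, 1),
      affected = fs$affected_count,
      se_range = sprintf("%.2f/%.2f", fs$se_range[2], fs$se_range[1]),
      se_median = sprintf("%.2f", fs$se_median),
      al_range = sprintf("%.2f/%.2f", fs$al_range[1], fs$al_range[2]),
      al_median = sprintf("%.2f", fs$al_median),
      stringsAsFactors = FALSE
    )
  }))

  ann <- variants
  rownames(ann) <- ann$key
  class(ann) <- c("hm_annotations", "data.frame")
  truth <- do.call(rbind, lapply(spikes, `[[`, "truth"))
  truth$variant_key <- causal_keys # keys after site-collision resolution
  structure(
    list(params = params, pedigrees = pedigrees,
         variants = variants[, c("chrom", "pos", "ref", "alt", "key")],
         genotypes = genotypes, annotations = ann, gene_sets = gene_sets,
         truth = truth, clinical = clinical),
    class = "hm_cohort"
  )
}

#' Write a simulated cohort to disk
#'
#' Emits the cohort in the pipeline's input dialects: `cohort.vcf`
#' (multi-sample, GT only), `cohort.ped`, `annotations.tsv`, `clinical.tsv`,
#' `truth.tsv` and a `genesets/` directory (`known_hm.txt`, `hm_related.txt`,
#' `ocular_disease.txt`, `adult_ocular.txt`, `embryonic_ocular.txt`,
#' `myp_map.tsv`). Output is byte-identical for identical parameters
#' (including the seed).
#'
#' @param params an [sim_params()] object.
#' @param dir output directory (created if needed).
#' @return the `hm_cohort`, invisibly, with a `files` element added.
#' @export
emit_cohort <- function(params = sim_params(), dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  sim <- simulate_cohort(params)
  files <- list(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    annotations = file.path(dir, "annotations.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.tsv"),
    gene_sets = file.path(dir, "genesets")
  )
  write_vcf(sim$variants, sim$genotypes, files$vcf)
  write_ped(sim$pedigrees, files$ped)
  ann <- sim$annotations[, ANNOTATION_COLS]
  num_fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15,
                                                     scientific = FALSE,
                                                     trim = TRUE))
  for (cc in c(FREQ_COLS, "popmax_filtering_af", "dann")) {
    ann[[cc]] <- num_fmt(ann[[cc]])
  }
  utils::write.table(ann, files$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(sim$clinical, files$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, files$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dir.create(files$gene_sets, showWarnings = FALSE)
  for (nm in c("known_hm", "hm_related", "ocular_disease", "adult_ocular",
               "embryonic_ocular")) {
    writeLines(sim$gene_sets[[nm]], file.path(files$gene_sets,
                                              paste0(nm, ".txt")))
  }
  mm <- sim$gene_sets$myp_map
  utils::write.table(
    data.frame(gene = names(mm), locus = unname(mm)),
    file.path(files$gene_sets, "myp_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sim$files <- files
  invisible(sim)
}

#' Count Mendelian-impossible child genotypes
#'
#' Exhaustive consistency check of a genotype matrix against pedigree
#' structure: for every child with both parents genotyped, the child dosage
#' must lie between the minimum and maximum transmissible alternate-allele
#' count given the parental dosages.
#'
#' @param genotypes dosage matrix.
#' @param pedigrees list of `hm_pedigree` objects.
#' @return integer count of violations (0 for any gene-drop output).
#' @export
mendelian_violations <- function(genotypes, pedigrees) {
  total <- 0L
  for (ped in pedigrees) {
    m <- ped$members
    for (i in seq_len(nrow(m))) {
      fa <- m$father_id[i]; mo <- m$mother_id[i]
      if (is.na(fa) || is.na(mo)) next
      if (!all(c(m$id[i], fa, mo) %in% colnames(genotypes))) next
      child <- genotypes[, m$id[i]]
      pf <- genotypes[, fa]; pm <- genotypes[, mo]
      ok <- !is.na(child) & !is.na(pf) & !is.na(pm)
      mn <- (pf == 2L) + (pm == 2L)
      mx <- (pf >= 1L) + (pm >= 1L)
      total <- total + sum(ok & (child < mn | child > mx))
    }
  }
  total
}
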