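#' Consequence filter
#'
#' Keeps variants whose consequence class can affect the protein or splicing:
#' `missense`, `nonsense`, `frameshift`, `inframe_indel`, `splice_site`.
#' Removes `synonymous`, `intronic`, `utr`, `intergenic`, `other`. A
#' synonymous change that alters a splice region must be labelled
#' `splice_site` by the annotation producer (single-label scheme), so
#' splice-preserving synonymous variants are always removed.
#'
#' @param variants data.frame with a `consequence` column.
#' @return list with `kept` and `removed` data.frames (input order).
#' @export
filter_consequence <- function(variants) {
  cq <- variants$consequence
  bad <- is.na(cq) | !cq %in% CONSEQUENCE_LEVELS
  if (any(bad)) {
    stop("unknown consequence label: ",
         paste(unique(cq[bad]), collapse = ", "))
  }
  keep <- cq %in% PROTEIN_ALTERING | cq == "splice_site"
  list(kept = variants[keep, , drop = FALSE],
       removed = variants[!keep, , drop = FALSE])
}

#' Population-frequency exclusion
#'
#' A variant is removed when its minor allele frequency is at or above
#' `maf_exclusion` (default 0.01, boundary inclusive) in any of the three
#' population databases (ExAC, 1000G, gnomAD). Absent frequencies never
#' trigger removal: a variant unreported everywhere is kept as novel.
#'
#' @param freqs one-row data.frame/list with `maf_exac`, `maf_1000g`,
#'   `maf_gnomad` (`NA` = absent).
#' @param t an [hm_thresholds()] object.
#' @return `TRUE` to keep, `FALSE` to remove.
#' @export
filter_frequency <- function(freqs, t = hm_thresholds()) {
  mafs <- c(freqs$maf_exac, freqs$maf_1000g, freqs$maf_gnomad)
  !any(!is.na(mafs) & mafs >= t$maf_exclusion)
}

# vectorized form over an annotation-joined candidate table
keep_frequency <- function(df, t) {
  m <- cbind(df$maf_exac, df$maf_1000g, df$maf_gnomad)
  rowSums(!is.na(m) & m >= t$maf_exclusion) == 0L
}

#' Assign a family's inheritance model
#'
#' Autosomal dominant when at least one affected member has an affected
#' parent (vertical transmission); autosomal recessive otherwise — including
#' the single-affected-child and affected-sibs-with-unaffected-parents
#' configurations. Affection status is resolved via declared status with
#' phenotype fallback. An explicit per-family override wins. X-linked models
#' are out of scope.
#'
#' @param ped an `hm_pedigree`.
#' @param t an [hm_thresholds()] object.
#' @param override `"AD"`, `"AR"` or `NULL`.
#' @return `"AD"` or `"AR"`.
#' @export
assign_inheritance_model <- function(ped, t = hm_thresholds(), override = NULL) {
  if (!is.null(override)) {
    stopifnot(override %in% c("AD", "AR"))
    return(override)
  }
  status <- resolve_statuses(ped, t)
  affected <- names(status)[status == "affected"]
  if (length(affected) == 0L) {
    stop("family ", ped$family_id, ": no affected members, cannot assign model")
  }
  m <- ped$members
  for (id in affected) {
    row <- m[m$id == id, ]
    parents <- c(row$father_id, row$mother_id)
    parents <- parents[!is.na(parents)]
    if (any(status[parents] == "affected")) return("AD")
  }
  "AR"
}

#' Genotype-model filter for one variant in one family
#'
#' Under AD the variant is kept iff every genotyped affected member is
#' heterozygous; under AR iff every genotyped affected member is homozygous
#' for the alternate allele. Missing genotypes do not veto (the rule is
#' evaluated over genotyped members only). A family with no genotyped
#' affected member removes the variant with reason `"untyped"`.
#'
#' @param key canonical variant key.
#' @param genotypes dosage matrix.
#' @param ped an `hm_pedigree`.
#' @param model `"AD"` or `"AR"`.
#' @param t an [hm_thresholds()] object.
#' @return list with `keep` (logical) and `reason` (`NA` when kept).
#' @export
filter_genotype_model <- function(key, genotypes, ped, model,
                                  t = hm_thresholds()) {
  stopifnot(model %in% c("AD", "AR"))
  status <- resolve_statuses(ped, t)
  affected <- intersect(names(status)[status == "affected"], colnames(genotypes))
  d <- if (key %in% rownames(genotypes)) genotypes[key, affected] else
    rep(NA_integer_, length(affected))
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(list(keep = FALSE, reason = "untyped"))
  want <- if (model == "AD") 1L else 2L
  if (all(d == want)) {
    list(keep = TRUE, reason = NA_character_)
  } else {
    list(keep = FALSE,
         reason = if (model == "AD") "not heterozygous in all affected"
                  else "not homozygous in all affected")
  }
}

#' De novo detection for one variant in one family
#'
#' `TRUE` iff some affected non-founder carries the alternate allele (het or
#' hom-alt) while both parents are genotyped and homozygous reference. A
#' missing parental genotype is conservative: de novo cannot be asserted.
#' De novo variants are excluded from the cascade.
#'
#' @inheritParams filter_genotype_model
#' @return logical scalar.
#' @export
detect_de_novo <- function(key, genotypes, ped, t = hm_thresholds()) {
  if (!key %in% rownames(genotypes)) return(FALSE)
  status <- resolve_statuses(ped, t)
  m <- ped$members
  gmem <- colnames(genotypes)
  for (i in seq_len(nrow(m))) {
    id <- m$id[i]
    if (status[[id]] != "affected") next
    fa <- m$father_id[i]; mo <- m$mother_id[i]
    if (is.na(fa) || is.na(mo)) next
    if (!all(c(id, fa, mo) %in% gmem)) next
    child <- genotypes[key, id]
    pf <- genotypes[key, fa]; pm <- genotypes[key, mo]
    if (anyNA(c(child, pf, pm))) next
    if (child >= 1L && pf == 0L && pm == 0L) return(TRUE)
  }
  FALSE
}

CASCADE_STAGES <- c("exonic", "synonymous", "frequency", "genotype_model",
                    "de_novo")

#' Run the full filter cascade
#'
#' Applies, in order: (1) exclusion of variants outside exonic/splice classes
#' (`intronic`, `utr`, `intergenic`, `other`); (2) exclusion of synonymous
#' variants; (3) population-frequency exclusion at `maf_exclusion`; (4) the
#' per-family inheritance-model genotype filter; then de novo exclusion. The
#' unit of the cascade is the (family, variant) candidate: a variant enters a
#' family's funnel when at least one genotyped member carries its alternate
#' allele. Inheritance models are assigned per family, then candidates are
#' pooled. Every removed candidate records its single earliest removal stage.
#'
#' Variants without an annotation row keep absent frequencies and an
#' all-missing prediction profile but carry consequence `other`, so they are
#' counted into the funnel and removed at the exonic stage (their class
#' cannot be evaluated).
#'
#' @param variants data.frame of variants from [read_vcf()].
#' @param genotypes dosage matrix from [read_vcf()].
#' @param pedigrees named list of `hm_pedigree` objects.
#' @param annotations `hm_annotations` table (or `NULL`).
#' @param t an [hm_thresholds()] object.
#' @param model_overrides optional named character vector of per-family
#'   model overrides.
#' @return list of class `hm_cascade`: `candidates` (all candidates with
#'   `kept` flag, `removed_stage`, `removal_reason`), `survivors` (kept
#'   candidates with annotation columns joined), `funnel` (data.frame stage,
#'   input, kept, removed) and `models` (per-family assignment).
#' @export
run_cascade <- function(variants, genotypes, pedigrees, annotations = NULL,
                        t = hm_thresholds(), model_overrides = NULL) {
  stopifnot(is.matrix(genotypes))
  pedigrees <- stats::setNames(pedigrees,
                               vapply(pedigrees, `[[`, "", "family_id"))
  ann_cols <- c("gene", "transcript", "cdna_hgvs", "consequence", FREQ_COLS,
                "popmax_filtering_af", TOOL_CALL_COLS, "dann")
  v <- variants[, c("key", "chrom", "pos", "ref", "alt"), drop = FALSE]
  if (!is.null(annotations)) {
    idx <- match(v$key, annotations$key)
    for (cc in ann_cols) v[[cc]] <- annotations[[cc]][idx]
  } else {
    for (cc in ann_cols) {
      v[[cc]] <- if (cc %in% c(FREQ_COLS, "popmax_filtering_af", "dann"))
        NA_real_ else NA_character_
    }
  }
  v$consequence[is.na(v$consequence)] <- "other"

  models <- vapply(pedigrees, function(p) {
    assign_inheritance_model(p, t, override = model_overrides[[p$family_id]])
  }, character(1))

  # candidate set: (family, variant) pairs with >= 1 carried alt allele
  cand <- list()
  for (fam in names(pedigrees)) {
    mem <- intersect(pedigrees[[fam]]$members$id, colnames(genotypes))
    if (length(mem) == 0L) next
    carried <- rowSums(genotypes[, mem, drop = FALSE] >= 1L, na.rm = TRUE) > 0L
    keys <- rownames(genotypes)[carried]
    if (length(keys) == 0L) next
    block <- v[match(keys, v$key), , drop = FALSE]
    block$family_id <- fam
    block$model <- unname(models[fam])
    cand[[fam]] <- block
  }
  cand <- if (length(cand)) do.call(rbind, c(cand, list(make.row.names = FALSE)))
          else {
            out <- v[0, , drop = FALSE]
            out$family_id <- character(0)
            out$model <- character(0)
            out
          }

  n <- nrow(cand)
  alive <- rep(TRUE, n)
  removed_stage <- rep(NA_character_, n)
  removal_reason <- rep(NA_character_, n)
  funnel <- data.frame(stage = CASCADE_STAGES, input = NA_integer_,
                       kept = NA_integer_, removed = NA_integer_)
  mark <- function(stage, fail_idx, reasons) {
    removed_stage[fail_idx] <<- stage
    removal_reason[fail_idx] <<- reasons
    alive[fail_idx] <<- FALSE
  }
  record <- function(stage, input_n) {
    i <- match(stage, funnel$stage)
    funnel$input[i] <<- input_n
    funnel$kept[i] <<- sum(alive)
    funnel$removed[i] <<- input_n - sum(alive)
  }

  # stage 1: exonic / splice classes only
  bad_cq <- !cand$consequence %in% CONSEQUENCE_LEVELS
  if (any(bad_cq)) stop("unknown consequence label: ",
                        unique(cand$consequence[bad_cq])[1])
  fail <- which(alive & cand$consequence %in%
                  c("intronic", "utr", "intergenic", "other"))
  mark("exonic", fail, paste0("non-exonic consequence (",
                              cand$consequence[fail], ")"))
  record("exonic", n)

  # stage 2: synonymous exclusion
  fail <- which(alive & cand$consequence == "synonymous")
  mark("synonymous", fail, "synonymous")
  record("synonymous", funnel$kept[1])

  # stage 3: frequency exclusion
  fail <- which(alive & !keep_frequency(cand, t))
  mark("frequency", fail, paste0("MAF >= ", t$maf_exclusion))
  record("frequency", funnel$kept[2])

  # stage 4: per-family genotype model
  idx_alive <- which(alive)
  for (i in idx_alive) {
    res <- filter_genotype_model(cand$key[i], genotypes,
                                 pedigrees[[cand$family_id[i]]],
                                 cand$model[i], t)
    if (!res$keep) mark("genotype_model", i, res$reason)
  }
  record("genotype_model", funnel$kept[3])

  # de novo exclusion (after the model filter, per the published order)
  idx_alive <- which(alive)
  for (i in idx_alive) {
    if (detect_de_novo(cand$key[i], genotypes,
                       pedigrees[[cand$family_id[i]]], t)) {
      mark("de_novo", i, "de novo")
    }
  }
  record("de_novo", funnel$kept[4])

  cand$kept <- alive
  cand$removed_stage <- removed_stage
  cand$removal_reason <- removal_reason
  structure(
    list(candidates = cand,
         survivors = cand[alive, setdiff(names(cand), c("kept", "removed_stage",
                                                        "removal_reason")),
                          drop = FALSE],
         funnel = funnel,
         models = models),
    class = "hm_cascade"
  )
}

#' @export
print.hm_cascade <- function(x, ...) {
  cat("hmexome filter cascade:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-15s input %5d  kept %5d  removed %5d\n",
                x$funnel$stage[i], x$funnel$input[i], x$funnel$kept[i],
                x$funnel$removed[i]))
  }
  invisible(x)
}
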