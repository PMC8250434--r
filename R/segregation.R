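#' Phenotype-based affection status
#'
#' Resolves a family member's status from eye measurements. Affected when the
#' worse eye's spherical equivalent is at or below `hm_se_max` or the longer
#' eye's axial length exceeds `hm_al_min` (either eye qualifying suffices —
#' worst-eye rule, so an anisometropic member with one qualifying eye is
#' affected). Unaffected when both eyes' SE are measured and strictly within
#' `unaffected_se_max_abs` in absolute value. Anything in between — e.g. a
#' young sib at -3 D — is `unknown` and stays segregation-neutral. A declared
#' status of `affected`/`unaffected`, when present, overrides the
#' measurements.
#'
#' @param ind one-row data.frame (or list) with `declared_status`,
#'   `se_right`, `se_left`, `al_right`, `al_left`.
#' @param t an [hm_thresholds()] object.
#' @return one of `"affected"`, `"unaffected"`, `"unknown"`.
#' @export
phenotype_status <- function(ind, t = hm_thresholds()) {
  declared <- ind$declared_status
  if (!is.null(declared) && !is.na(declared) && declared != "unknown") {
    return(declared)
  }
  se <- c(ind$se_right, ind$se_left)
  al <- c(ind$al_right, ind$al_left)
  se_worst <- if (all(is.na(se))) NA_real_ else min(se, na.rm = TRUE)
  al_longest <- if (all(is.na(al))) NA_real_ else max(al, na.rm = TRUE)
  if ((!is.na(se_worst) && se_worst <= t$hm_se_max) ||
      (!is.na(al_longest) && al_longest > t$hm_al_min)) {
    return("affected")
  }
  if (sum(!is.na(se)) == 2L && all(abs(se) < t$unaffected_se_max_abs)) {
    return("unaffected")
  }
  "unknown"
}

# resolved status for every member of a pedigree, named by id
resolve_statuses <- function(ped, t = hm_thresholds()) {
  m <- ped$members
  stats::setNames(
    vapply(seq_len(nrow(m)),
           function(i) phenotype_status(m[i, , drop = FALSE], t),
           character(1)),
    m$id
  )
}

#' Cosegregation test for one candidate variant
#'
#' Checks concordance between genotypes and affection status across all
#' genotyped family members under the family's inheritance model. Autosomal
#' dominant: every genotyped affected must be heterozygous and no genotyped
#' unaffected may carry the alternate allele. Autosomal recessive: every
#' genotyped affected must be homozygous alternate and no genotyped
#' unaffected may be homozygous alternate — heterozygous unaffected carriers
#' are permitted, since the parents of a recessive proband are obligate
#' carriers. Members with missing genotypes or `unknown` status never veto.
#'
#' @param key canonical variant key (row of `genotypes`).
#' @param genotypes dosage matrix from [read_vcf()].
#' @param ped an `hm_pedigree`.
#' @param model `"AD"` or `"AR"`.
#' @param t an [hm_thresholds()] object.
#' @return list of class `hm_segregation`: `cosegregates` (logical) and
#'   `violating_members` (data.frame id, reason; empty iff cosegregating).
#' @export
cosegregates <- function(key, genotypes, ped, model, t = hm_thresholds()) {
  stopifnot(model %in% c("AD", "AR"))
  status <- resolve_statuses(ped, t)
  ids <- intersect(names(status), colnames(genotypes))
  viol <- list()
  add <- function(id, reason) viol[[length(viol) + 1L]] <<- data.frame(
    id = id, reason = reason, stringsAsFactors = FALSE)
  for (id in ids) {
    d <- if (key %in% rownames(genotypes)) genotypes[key, id] else NA_integer_
    if (is.na(d)) next
    st <- status[[id]]
    if (st == "affected") {
      if (model == "AD" && d != 1L) add(id, "affected not heterozygous")
      if (model == "AR" && d != 2L) add(id, "affected not homozygous")
    } else if (st == "unaffected") {
      if (model == "AD" && d > 0L) add(id, "unaffected carrier")
      if (model == "AR" && d == 2L) add(id, "unaffected homozygous")
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(id = character(0), reason = character(0))
  structure(list(cosegregates = nrow(viol) == 0L, violating_members = viol),
            class = "hm_segregation")
}

#' Partition candidates by cosegregation
#'
#' Runs [cosegregates()] for each surviving candidate in its own family and
#' splits the list into cosegregating and non-cosegregating subsets, both in
#' input order.
#'
#' @param candidates data.frame of cascade survivors (columns `family_id`,
#'   `key`, `model`, ...).
#' @param genotypes dosage matrix.
#' @param pedigrees named list of `hm_pedigree` objects.
#' @param t an [hm_thresholds()] object.
#' @return list with `cosegregating` and `non_cosegregating` data.frames; the
#'   latter gains a `violations` column summarizing the failed conditions.
#' @export
partition_by_segregation <- function(candidates, genotypes, pedigrees,
                                     t = hm_thresholds()) {
  if (nrow(candidates) == 0L) {
    empty <- candidates
    empty$violations <- character(0)
    return(list(cosegregating = candidates, non_cosegregating = empty))
  }
  ok <- logical(nrow(candidates))
  why <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    seg <- cosegregates(candidates$key[i], genotypes,
                        pedigrees[[candidates$family_id[i]]],
                        candidates$model[i], t)
    ok[i] <- seg$cosegregates
    why[i] <- paste(sprintf("%s: %s", seg$violating_members$id,
                            seg$violating_members$reason), collapse = "; ")
  }
  non <- candidates[!ok, , drop = FALSE]
  non$violations <- why[!ok]
  list(cosegregating = candidates[ok, , drop = FALSE], non_cosegregating = non)
}
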