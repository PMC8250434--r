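#' Count damaging tool calls
#'
#' Counts prediction tools calling a variant damaging across the 10-tool
#' panel: nine categorical callers (SIFT, PolyPhen-2 HDIV, PolyPhen-2 HVAR,
#' MutationTaster, LRT, MutationAssessor, FATHMM, RadialSVM, LR) plus DANN,
#' which counts as damaging when its score is at or above `dann_damaging`.
#' With `collapse_polyphen` on (the default used for scoring), the two
#' PolyPhen-2 submodels count as a single tool that is damaging if either is,
#' matching the convention of reporting "PolyPhen-2" once; both columns are
#' always retained in the data.
#'
#' @param profile one-row data.frame/list with the nine call fields (values
#'   `damaging`/`tolerated`/`NA`) and `dann` in \[0,1\] or `NA`.
#' @param t an [hm_thresholds()] object.
#' @param collapse_polyphen logical.
#' @return integer count (0 for an all-missing profile).
#' @export
damaging_call_count <- function(profile, t = hm_thresholds(),
                                collapse_polyphen = TRUE) {
  calls <- vapply(TOOL_CALL_COLS, function(cc) {
    v <- profile[[cc]]
    !is.null(v) && !is.na(v) && v == "damaging"
  }, logical(1))
  n <- if (collapse_polyphen) {
    sum(calls[setdiff(TOOL_CALL_COLS, c("polyphen2_hdiv", "polyphen2_hvar"))]) +
      as.integer(calls["polyphen2_hdiv"] || calls["polyphen2_hvar"])
  } else {
    sum(calls)
  }
  dann <- profile$dann
  if (!is.null(dann) && !is.na(dann) && dann >= t$dann_damaging) n <- n + 1L
  as.integer(n)
}

#' Population-frequency class
#'
#' For variants already past the exclusion filter: `novel` when all three
#' database frequencies are absent; `rare` when at least one is present and
#' every present frequency is strictly below `rare_maf` (less than 1 in
#' 1,000 alleles in any population); `low_frequency` otherwise.
#'
#' @param freqs one-row data.frame/list with `maf_exac`, `maf_1000g`,
#'   `maf_gnomad`.
#' @param t an [hm_thresholds()] object.
#' @return one of `"novel"`, `"rare"`, `"low_frequency"`.
#' @export
frequency_class <- function(freqs, t = hm_thresholds()) {
  mafs <- c(freqs$maf_exac, freqs$maf_1000g, freqs$maf_gnomad)
  present <- mafs[!is.na(mafs)]
  if (length(present) == 0L) return("novel")
  if (max(present) < t$rare_maf) return("rare")
  "low_frequency"
}

#' Eleven-category evidence matrix for one candidate
#'
#' Computes the evidence bits used for ranking, grouped as: filter condition
#' (known HM gene, HM-related gene, ocular disease gene, at a mapped MYP
#' locus), pathogenicity (more than two tools damaging), annotation (exonic
#' protein-altering vs non-protein-altering — mutually exclusive, exactly one
#' true), expression (adult / embryonic human ocular tissue) and frequency
#' (novel vs rare — mutually exclusive, both false for low-frequency
#' variants). The weighted total is the dot product of the bits with the
#' weight vector.
#'
#' @param candidate one-row data.frame with `consequence` and the frequency
#'   and tool columns (an annotation-joined cascade survivor).
#' @param gene_ev one-row data.frame from [gene_evidence()].
#' @param t an [hm_thresholds()] object.
#' @param weights weight vector from [hm_weights()].
#' @param collapse_polyphen passed to [damaging_call_count()].
#' @return named list: the eleven logical bits, `weighted_total`,
#'   `frequency_class`, `damaging_tools`.
#' @export
evidence_matrix <- function(candidate, gene_ev, t = hm_thresholds(),
                            weights = hm_weights(), collapse_polyphen = TRUE) {
  n_damaging <- damaging_call_count(candidate, t, collapse_polyphen)
  fclass <- frequency_class(candidate, t)
  exonic <- candidate$consequence %in% PROTEIN_ALTERING
  bits <- c(
    known_hm_gene = isTRUE(gene_ev$is_known_hm_gene),
    hm_related_gene = isTRUE(gene_ev$is_hm_related),
    ocular_disease_gene = isTRUE(gene_ev$is_ocular_disease_gene),
    at_myp_locus = !is.na(gene_ev$myp_locus),
    multi_tool_damaging = n_damaging >= t$min_damaging_tools,
    exonic_protein_altering = exonic,
    non_protein_altering = !exonic,
    expressed_adult_ocular = isTRUE(gene_ev$expressed_adult_ocular),
    expressed_embryonic_ocular = isTRUE(gene_ev$expressed_embryonic_ocular),
    freq_novel = fclass == "novel",
    freq_rare = fclass == "rare"
  )
  stopifnot(identical(names(bits), EVIDENCE_CATEGORIES))
  c(as.list(bits),
    list(weighted_total = sum(bits * weights[EVIDENCE_CATEGORIES]),
         frequency_class = fclass,
         damaging_tools = n_damaging))
}

# highest present database MAF, absent treated as -1 (sorts novel first)
max_present_maf <- function(df) {
  m <- cbind(df$maf_exac, df$maf_1000g, df$maf_gnomad)
  out <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  out[!is.finite(out)] <- -1
  out
}

#' Rank scored candidates
#'
#' Orders candidates by descending weighted total; ties break by ascending
#' maximum present database MAF (absent = -1, so novel precedes rare), then
#' ascending gene symbol, then ascending variant key. The order is a pure
#' function of the candidates' evidence: permuting the input never changes
#' the output.
#'
#' @param scored data.frame of scored candidates (needs `weighted_total`,
#'   the three MAF columns, `gene`, `key`).
#' @return the same data.frame, reordered.
#' @export
rank_candidates <- function(scored) {
  if (nrow(scored) == 0L) return(scored)
  ord <- order(-scored$weighted_total, max_present_maf(scored),
               scored$gene, scored$key, method = "radix")
  out <- scored[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ACMG-style evidence tags
#'
#' Minimal three-tag subset of the ACMG/AMP evidence codes: `PM2` (absent or
#' very rare in population databases — frequency class novel or rare), `PP1`
#' (cosegregation with disease in the family) and `PP3` (multiple
#' computational tools support a deleterious effect). A fuller rule engine is
#' deliberately out of scope.
#'
#' @param freq_class from [frequency_class()].
#' @param cosegregating logical.
#' @param multi_tool_damaging logical.
#' @return character vector of tags (possibly empty).
#' @export
acmg_evidence <- function(freq_class, cosegregating, multi_tool_damaging) {
  tags <- character(0)
  if (freq_class %in% c("novel", "rare")) tags <- c(tags, "PM2")
  if (isTRUE(cosegregating)) tags <- c(tags, "PP1")
  if (isTRUE(multi_tool_damaging)) tags <- c(tags, "PP3")
  tags
}

#' Combine ACMG tags into a classification
#'
#' With only one moderate (PM2) and two supporting (PP1, PP3) criteria
#' available, the published combining rules cannot reach likely pathogenic
#' (which needs, at minimum, one moderate plus four supporting), so any
#' non-empty tag set maps to `uncertain_significance` and an empty set to
#' `likely_benign`. The mapping is overridable: `map` is a named list keyed
#' by the `+`-joined sorted tag set (e.g. `"PM2+PP1+PP3"`).
#'
#' @param tags character vector from [acmg_evidence()].
#' @param map optional named list of overrides.
#' @return one of `"likely_pathogenic"`, `"uncertain_significance"`,
#'   `"likely_benign"`.
#' @export
acmg_classify <- function(tags, map = NULL) {
  valid <- c("likely_pathogenic", "uncertain_significance", "likely_benign")
  key <- paste(sort(tags), collapse = "+")
  if (!is.null(map) && key %in% names(map)) {
    cls <- map[[key]]
    if (!cls %in% valid) stop("invalid classification in acmg map: ", cls)
    return(cls)
  }
  if (length(tags) == 0L) "likely_benign" else "uncertain_significance"
}

#' Score a set of cosegregating candidates
#'
#' Applies [evidence_matrix()], [acmg_evidence()] and [acmg_classify()] to
#' each candidate (all assumed cosegregating within their family, i.e. PP1
#' holds) and returns the scored table, unranked.
#'
#' @param candidates data.frame of annotation-joined candidates.
#' @param sets an `hm_gene_sets` object.
#' @param t an [hm_thresholds()] object.
#' @param weights weight vector from [hm_weights()].
#' @param collapse_polyphen passed to [damaging_call_count()].
#' @param cosegregating logical scalar or vector: PP1 state per candidate.
#' @param acmg_map optional classification override map.
#' @return data.frame: input columns plus the eleven bits, `weighted_total`,
#'   `frequency_class`, `acmg_tags`, `acmg_class` and `variant_key`.
#' @export
score_candidates <- function(candidates, sets, t = hm_thresholds(),
                             weights = hm_weights(), collapse_polyphen = TRUE,
                             cosegregating = TRUE, acmg_map = NULL) {
  n <- nrow(candidates)
  if (n == 0L) {
    empty <- candidates
    for (cc in EVIDENCE_CATEGORIES) empty[[cc]] <- logical(0)
    empty$weighted_total <- numeric(0)
    empty$frequency_class <- character(0)
    empty$damaging_tools <- integer(0)
    empty$acmg_tags <- character(0)
    empty$acmg_class <- character(0)
    empty$variant_key <- character(0)
    return(empty)
  }
  cosegregating <- rep_len(cosegregating, n)
  ge <- gene_evidence(candidates$gene, sets)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- evidence_matrix(candidates[i, , drop = FALSE],
                          ge[i, , drop = FALSE], t, weights, collapse_polyphen)
    tags <- acmg_evidence(ev$frequency_class, cosegregating[i],
                          ev$multi_tool_damaging)
    rows[[i]] <- data.frame(
      c(ev[EVIDENCE_CATEGORIES],
        list(weighted_total = ev$weighted_total,
             frequency_class = ev$frequency_class,
             damaging_tools = ev$damaging_tools,
             acmg_tags = paste(tags, collapse = "+"),
             acmg_class = acmg_classify(tags, acmg_map))),
      stringsAsFactors = FALSE)
  }
  scored <- cbind(candidates,
                  do.call(rbind, c(rows, list(make.row.names = FALSE))))
  scored$variant_key <- scored$key
  scored
}
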