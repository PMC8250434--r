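#' Analysis thresholds
#'
#' Bundles every numeric cutoff the pipeline uses, with the cohort study's
#' stated defaults. All boundaries keep their published semantics:
#' `maf_exclusion` is inclusive (a variant at exactly 0.01 in any database is
#' excluded), `hm_se_max` is inclusive (spherical equivalent of exactly
#' -6.00 D is high myopia) and `hm_al_min` is exclusive (axial length must
#' exceed 26.00 mm).
#'
#' @param maf_exclusion variants with MAF >= this in any of ExAC/1000G/gnomAD
#'   are excluded from the cascade.
#' @param rare_maf frequency class boundary: present MAFs all strictly below
#'   this are "rare" (1 in 1,000 alleles).
#' @param dann_damaging DANN score at or above which DANN counts as a
#'   damaging call.
#' @param min_damaging_tools number of damaging tool calls required for the
#'   multi-tool pathogenicity evidence bit ("more than two" => 3).
#' @param unaffected_se_max_abs both eyes strictly below this absolute
#'   spherical equivalent (diopters) classify a member unaffected.
#' @param hm_se_max spherical equivalent (diopters) at or below which an eye
#'   qualifies as high myopia.
#' @param hm_al_min axial length (mm) strictly above which an eye qualifies.
#' @return an object of class `hm_thresholds`.
#' @export
hm_thresholds <- function(maf_exclusion = 0.01,
                          rare_maf = 0.001,
                          dann_damaging = 0.90,
                          min_damaging_tools = 3L,
                          unaffected_se_max_abs = 2.00,
                          hm_se_max = -6.00,
                          hm_al_min = 26.00) {
  if (!(rare_maf > 0 && rare_maf < maf_exclusion && maf_exclusion <= 1)) {
    stop("thresholds must satisfy 0 < rare_maf < maf_exclusion <= 1")
  }
  if (min_damaging_tools < 1) stop("min_damaging_tools must be >= 1")
  structure(
    list(maf_exclusion = maf_exclusion,
         rare_maf = rare_maf,
         dann_damaging = dann_damaging,
         min_damaging_tools = as.integer(min_damaging_tools),
         unaffected_se_max_abs = unaffected_se_max_abs,
         hm_se_max = hm_se_max,
         hm_al_min = hm_al_min),
    class = "hm_thresholds"
  )
}

#' @export
print.hm_thresholds <- function(x, ...) {
  cat("hmexome thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Fixed category order of the evidence matrix (report column order):
# filter condition (4), pathogenicity (1), annotation (2), expression (2),
# frequency (2).
EVIDENCE_CATEGORIES <- c(
  "known_hm_gene", "hm_related_gene", "ocular_disease_gene", "at_myp_locus",
  "multi_tool_damaging",
  "exonic_protein_altering", "non_protein_altering",
  "expressed_adult_ocular", "expressed_embryonic_ocular",
  "freq_novel", "freq_rare"
)

#' Evidence category weights
#'
#' Default weight vector for the eleven evidence categories. The source study
#' publishes no numeric scale, so weights are configuration: every bit weighs
#' 1 except `non_protein_altering` (0, the annotation pair is exclusive and
#' only protein-altering status is credited) and `freq_rare` (0.5, rare is
#' weaker evidence than novel). Two bit pairs are mutually exclusive, so the
#' maximum attainable total under defaults is 9.
#'
#' @param ... named overrides for individual category weights.
#' @return named numeric vector over the eleven categories, in report order.
#' @export
hm_weights <- function(...) {
  w <- stats::setNames(rep(1, length(EVIDENCE_CATEGORIES)), EVIDENCE_CATEGORIES)
  w["non_protein_altering"] <- 0
  w["freq_rare"] <- 0.5
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), EVIDENCE_CATEGORIES)
    if (length(bad)) stop("unknown evidence categories: ", paste(bad, collapse = ", "))
    if (any(unlist(over) < 0)) stop("weights must be nonnegative")
    w[names(over)] <- unlist(over)
  }
  w
}

#' Read a pipeline configuration file
#'
#' JSON file with optional top-level entries `thresholds` (any subset of the
#' [hm_thresholds()] fields), `weights` (any subset of the eleven evidence
#' categories), `collapse_polyphen`, `top_k` and `acmg_map` (named list
#' mapping "+"-joined sorted tag sets to classifications). Unspecified values
#' fall back to package defaults; precedence is caller argument > config file
#' > built-in default.
#'
#' @param path path to a JSON config file, or `NULL` for all defaults.
#' @return list with elements `thresholds`, `weights`, `collapse_polyphen`,
#'   `top_k`, `acmg_map`.
#' @export
read_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  thr <- do.call(hm_thresholds, as.list(cfg$thresholds))
  wts <- do.call(hm_weights, as.list(cfg$weights))
  list(
    thresholds = thr,
    weights = wts,
    collapse_polyphen = if (is.null(cfg$collapse_polyphen)) TRUE else isTRUE(cfg$collapse_polyphen),
    top_k = if (is.null(cfg$top_k)) 20L else as.integer(cfg$top_k),
    acmg_map = if (is.null(cfg$acmg_map)) NULL else as.list(cfg$acmg_map)
  )
}
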