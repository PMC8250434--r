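#' High-myopia inclusion predicate
#'
#' An individual qualifies as high myopia when the worse eye's spherical
#' equivalent is at or below `hm_se_max` (default -6.00 D, boundary
#' inclusive: "worse than or equal to") and/or the longer eye's axial length
#' strictly exceeds `hm_al_min` (default 26.00 mm, boundary exclusive). A
#' missing measurement never qualifies on its own; both missing is an error.
#'
#' @param se_worst worse-eye spherical equivalent in diopters (`NA` allowed).
#' @param al_longest longer-eye axial length in mm (`NA` allowed).
#' @param t an [hm_thresholds()] object.
#' @return logical scalar.
#' @export
is_high_myopia <- function(se_worst, al_longest, t = hm_thresholds()) {
  if (is.na(se_worst) && is.na(al_longest)) {
    stop("is_high_myopia: both SE and AL are missing")
  }
  (!is.na(se_worst) && se_worst <= t$hm_se_max) ||
    (!is.na(al_longest) && al_longest > t$hm_al_min)
}

parse_clinical_range <- function(x, what, row_label) {
  x <- gsub("−", "-", as.character(x)) # unicode minus
  parts <- strsplit(x, "/", fixed = TRUE)
  t(vapply(seq_along(parts), function(i) {
    p <- trimws(parts[[i]])
    v <- suppressWarnings(as.numeric(p))
    if (length(v) != 2L || any(is.na(v))) {
      stop("non-numeric ", what, " range at ", row_label[i], ": ", x[i])
    }
    sort(v)
  }, numeric(2)))
}

#' Read the per-family clinical table
#'
#' Tab-delimited with header, one row per family, columns `family`,
#' `proband_age`, `affected`, `se_range`, `se_median`, `al_range`,
#' `al_median`. Ranges are encoded `a/b` and parsed to ordered numeric
#' (low, high) pairs; spherical equivalents are negative for myopia; a
#' degenerate range `x/x` is accepted. Unicode minus signs are normalized.
#'
#' @param path path to the TSV.
#' @return data.frame with columns family, proband_age, affected_count,
#'   se_low, se_high, se_median, al_low, al_high, al_median.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("family", "proband_age", "affected", "se_range", "se_median",
            "al_range", "al_median")
  if (!all(need %in% names(df))) {
    stop("clinical table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  lab <- paste0("family ", df$family)
  se <- parse_clinical_range(df$se_range, "SE", lab)
  al <- parse_clinical_range(df$al_range, "AL", lab)
  num <- function(col, what) {
    v <- gsub("−", "-", df[[col]])
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out))) stop("non-numeric ", what, " at ", lab[which(is.na(out))[1]])
    out
  }
  data.frame(
    family = df$family,
    proband_age = num("proband_age", "proband age"),
    affected_count = as.integer(num("affected", "affected count")),
    se_low = se[, 1], se_high = se[, 2], se_median = num("se_median", "SE median"),
    al_low = al[, 1], al_high = al[, 2], al_median = num("al_median", "AL median"),
    stringsAsFactors = FALSE
  )
}

#' Count families meeting the high-myopia inclusion criterion
#'
#' Applies [is_high_myopia()] to each family's (SE median, AL median) pair.
#'
#' @param clinical data.frame from [read_clinical_table()].
#' @param t an [hm_thresholds()] object.
#' @return integer count.
#' @export
count_hm_families <- function(clinical, t = hm_thresholds()) {
  if (nrow(clinical) == 0L) return(0L)
  sum(vapply(seq_len(nrow(clinical)), function(i) {
    is_high_myopia(clinical$se_median[i], clinical$al_median[i], t)
  }, logical(1)))
}

#' Internal-consistency check of a clinical table
#'
#' Flags rows whose printed median falls outside the printed range (a data
#' defect, not a parse error).
#'
#' @param clinical data.frame from [read_clinical_table()].
#' @return data.frame with columns family, field (`se`/`al`) for each
#'   violation; zero rows if fully consistent.
#' @export
check_clinical_consistency <- function(clinical) {
  eps <- 1e-9
  out <- list()
  for (field in c("se", "al")) {
    lo <- clinical[[paste0(field, "_low")]]
    hi <- clinical[[paste0(field, "_high")]]
    med <- clinical[[paste0(field, "_median")]]
    bad <- med < lo - eps | med > hi + eps
    if (any(bad)) {
      out[[field]] <- data.frame(family = clinical$family[bad], field = field,
                                 stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(family = character(0), field = character(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-family clinical summary
#'
#' Summarizes the affected members of one family the way the cohort's
#' clinical table does: ranges are (min, max) and medians are computed over
#' the pooled per-eye values of all affected members (each eye contributes
#' one value; an even count takes the mean of the two middle values).
#' Affection status is resolved by declared status with phenotype-rule
#' fallback ([phenotype_status()]).
#'
#' @param ped an `hm_pedigree` (phenotype columns populated).
#' @param t an [hm_thresholds()] object.
#' @return list of class `hm_family_summary`: family_id, affected_count,
#'   se_range, se_median, al_range, al_median.
#' @export
family_summary <- function(ped, t = hm_thresholds()) {
  m <- ped$members
  status <- resolve_statuses(ped, t)
  aff <- m[status == "affected", , drop = FALSE]
  if (nrow(aff) == 0L) stop("family ", ped$family_id, ": no affected members")
  se <- c(aff$se_right, aff$se_left)
  al <- c(aff$al_right, aff$al_left)
  se <- se[!is.na(se)]
  al <- al[!is.na(al)]
  if (!length(se) && !length(al)) {
    stop("family ", ped$family_id, ": no measured affected eyes")
  }
  rng <- function(x) if (length(x)) c(min(x), max(x)) else c(NA_real_, NA_real_)
  med <- function(x) if (length(x)) stats::median(x) else NA_real_
  structure(
    list(family_id = ped$family_id, affected_count = nrow(aff),
         se_range = rng(se), se_median = med(se),
         al_range = rng(al), al_median = med(al)),
    class = "hm_family_summary"
  )
}
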