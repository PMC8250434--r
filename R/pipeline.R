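#' Run the end-to-end prioritization pipeline
#'
#' Orchestrates cascade, cosegregation, scoring and ranking: reads the
#' multi-sample VCF, PED, annotation table and gene sets; runs the four-step
#' filter cascade with de novo exclusion; partitions cascade survivors by
#' cosegregation; scores cosegregating candidates on the eleven-category
#' evidence matrix; ranks them; and (when `out_dir` is given) writes
#' `funnel.tsv`, `non_cosegregating.tsv` and `ranked_report.tsv`.
#'
#' VCF samples absent from every pedigree are ignored with a warning;
#' pedigree members absent from the VCF are simply ungenotyped (they never
#' veto any rule).
#'
#' @param vcf path to the multi-sample VCF.
#' @param ped path to the PED file.
#' @param annotations path to the annotation TSV (or `NULL`).
#' @param gene_sets an `hm_gene_sets` object, a directory for
#'   [read_gene_sets_dir()], or `NULL` for empty sets.
#' @param config path to a JSON config file, a list from [read_config()], or
#'   `NULL` for defaults.
#' @param out_dir optional output directory for the report TSVs.
#' @param top_k rows shown by [funnel_report()] (default 20); overrides the
#'   config value.
#' @return object of class `hm_run`: `config`, `inputs`, `funnel`,
#'   `candidates`, `models`, `n_cosegregating`, `n_non_cosegregating`,
#'   `non_cosegregating`, `ranked`, `warnings`, `files`.
#' @export
run_pipeline <- function(vcf, ped, annotations = NULL, gene_sets = NULL,
                         config = NULL, out_dir = NULL, top_k = NULL) {
  cfg <- if (is.null(config)) read_config()
         else if (is.character(config)) read_config(config)
         else config
  if (!is.null(top_k)) cfg$top_k <- as.integer(top_k)
  t <- cfg$thresholds

  warnings <- character(0)
  vc <- read_vcf(vcf)
  pedigrees <- read_ped(ped)
  names(pedigrees) <- vapply(pedigrees, `[[`, "", "family_id")
  ann <- if (is.null(annotations)) NULL
         else if (is.character(annotations)) read_annotation_table(annotations)
         else annotations
  sets <- if (is.null(gene_sets)) read_gene_sets()
          else if (is.character(gene_sets)) read_gene_sets_dir(gene_sets)
          else gene_sets

  ped_ids <- unlist(lapply(pedigrees, function(p) p$members$id), use.names = FALSE)
  stray <- setdiff(colnames(vc$genotypes), ped_ids)
  if (length(stray)) {
    msg <- paste0("VCF samples absent from all pedigrees (ignored): ",
                  paste(stray, collapse = ", "))
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
    vc$genotypes <- vc$genotypes[, setdiff(colnames(vc$genotypes), stray),
                                 drop = FALSE]
  }

  cascade <- run_cascade(vc$variants, vc$genotypes, pedigrees, ann, t)
  parts <- partition_by_segregation(cascade$survivors, vc$genotypes,
                                    pedigrees, t)
  scored <- score_candidates(parts$cosegregating, sets, t, cfg$weights,
                             cfg$collapse_polyphen, cosegregating = TRUE,
                             acmg_map = cfg$acmg_map)
  ranked <- rank_candidates(scored)

  files <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
      stop("cannot create output directory: ", out_dir)
    }
    files$funnel <- file.path(out_dir, "funnel.tsv")
    utils::write.table(cascade$funnel, files$funnel, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files$non_cosegregating <- file.path(out_dir, "non_cosegregating.tsv")
    utils::write.table(
      parts$non_cosegregating[, c("family_id", "key", "gene", "model",
                                  "violations")],
      files$non_cosegregating, sep = "\t", quote = FALSE, row.names = FALSE,
      na = ".")
    files$ranked_report <- file.path(out_dir, "ranked_report.tsv")
    write_ranked_table(files$ranked_report, ranked)
  }

  structure(
    list(config = cfg,
         inputs = list(vcf = vcf, ped = ped, annotations = annotations,
                       gene_sets = gene_sets),
         funnel = cascade$funnel,
         candidates = cascade$candidates,
         models = cascade$models,
         n_cosegregating = nrow(parts$cosegregating),
         n_non_cosegregating = nrow(parts$non_cosegregating),
         non_cosegregating = parts$non_cosegregating,
         ranked = ranked,
         warnings = warnings,
         files = files),
    class = "hm_run"
  )
}

#' Human-readable funnel and ranking summary
#'
#' One line per cascade stage (input / kept / removed), the cosegregation
#' partition, and the top-k ranked candidates.
#'
#' @param run an `hm_run` from [run_pipeline()].
#' @param top_k rows of the ranked table to print (default from the run's
#'   config; never padded beyond the candidate count).
#' @param file connection passed to [cat()] (default stdout).
#' @return `run`, invisibly.
#' @export
funnel_report <- function(run, top_k = run$config$top_k, file = "") {
  f <- run$funnel
  cat("Filter cascade:\n", file = file)
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-15s input %6d  kept %6d  removed %6d\n",
                f$stage[i], f$input[i], f$kept[i], f$removed[i]),
        file = file, append = TRUE)
  }
  cat(sprintf("Cosegregating: %d   non-cosegregating: %d\n",
              run$n_cosegregating, run$n_non_cosegregating),
      file = file, append = TRUE)
  k <- min(top_k, nrow(run$ranked))
  cat(sprintf("Top %d ranked candidates:\n", k), file = file, append = TRUE)
  if (k > 0L) {
    top <- run$ranked[seq_len(k), ]
    for (i in seq_len(k)) {
      cat(sprintf("  %2d. %-6s %-10s %-22s score %5.2f  %-13s %s\n",
                  i, top$family_id[i], top$gene[i], top$variant_key[i],
                  top$weighted_total[i], top$frequency_class[i],
                  top$acmg_class[i]),
          file = file, append = TRUE)
    }
  }
  invisible(run)
}

#' @export
print.hm_run <- function(x, ...) {
  funnel_report(x)
  invisible(x)
}
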