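CONSEQUENCE_LEVELS <- c("missense", "nonsense", "frameshift", "inframe_indel",
                        "splice_site", "synonymous", "intronic", "utr",
                        "intergenic", "other")

PROTEIN_ALTERING <- c("missense", "nonsense", "frameshift", "inframe_indel")

# annotation table tool-call columns, fixed 10-tool panel
TOOL_CALL_COLS <- c("sift", "polyphen2_hdiv", "polyphen2_hvar",
                    "mutation_taster", "lrt", "mutation_assessor",
                    "fathmm", "radialsvm", "lr")
FREQ_COLS <- c("maf_exac", "maf_1000g", "maf_gnomad")
ANNOTATION_COLS <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
                     "cdna_hgvs", "consequence", FREQ_COLS,
                     "popmax_filtering_af", TOOL_CALL_COLS, "dann")

#' Canonical variant key
#'
#' Deterministic `chrom:pos:ref:alt` string identifying one biallelic change.
#' A leading `chr` is stripped so `chr8` and `8` yield the same key; X/Y are
#' kept as letters. Vectorized over all arguments.
#'
#' @param chrom chromosome label(s).
#' @param pos 1-based position(s).
#' @param ref,alt allele strings.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom))
  paste(chrom, as.integer(pos), toupper(ref), toupper(alt), sep = ":")
}

# genotype dosage (0/1/2/NA) of each sample for alt allele index `alt_idx`
# within one record's GT strings; any missing allele => NA; other alt alleles
# at the site count as reference for the focal alt.
gt_dosage <- function(gt, alt_idx) {
  u <- unique(gt)
  du <- vapply(u, function(s) {
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) == 0L || any(al == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (any(is.na(ai))) return(NA_integer_)
    sum(ai == alt_idx)
  }, integer(1))
  unname(du[match(gt, u)])
}

#' Read a multi-sample VCF
#'
#' Parses a VCF 4.x file (GT format field required) via
#' \pkg{VariantAnnotation} and decomposes every multi-allelic record into one
#' biallelic variant per alternate allele. For a decomposed record a sample's
#' genotype counts only the focal alternate allele: a `1/2` call is
#' heterozygous for each of the two decomposed variants, and an allele call
#' for a different alternate counts as reference. Any missing allele in a GT
#' makes the genotype missing.
#'
#' @param path path to a VCF file.
#' @return list with `variants` (data.frame: chrom, pos, ref, alt, key; gene,
#'   transcript, cdna_hgvs, consequence all `NA`, to be joined from the
#'   annotation table) and `genotypes` (integer matrix of alt-allele dosages,
#'   rows = variant keys, columns = sample ids, `NA` = missing).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("malformed VCF '", path, "': no GT genotype field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  samples <- colnames(gt)

  rows <- vector("list", length(alt_list))
  dosages <- vector("list", length(alt_list))
  for (i in seq_along(alt_list)) {
    alts <- as.character(alt_list[[i]])
    n_alt <- length(alts)
    sub <- data.frame(chrom = rep(chrom[i], n_alt), pos = rep(pos[i], n_alt),
                      ref = rep(ref[i], n_alt), alt = alts,
                      stringsAsFactors = FALSE)
    rows[[i]] <- sub
    dosages[[i]] <- t(vapply(seq_len(n_alt),
                             function(a) gt_dosage(gt[i, ], a),
                             integer(length(samples))))
  }
  variants <- do.call(rbind, rows)
  bad <- variants$ref == variants$alt | variants$pos < 1
  if (any(bad)) stop("malformed VCF '", path, "': invalid alleles at record ",
                     which(bad)[1])
  variants$gene <- NA_character_
  variants$transcript <- NA_character_
  variants$cdna_hgvs <- NA_character_
  variants$consequence <- NA_character_
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (anyDuplicated(variants$key)) {
    stop("malformed VCF '", path, "': duplicate variant after decomposition: ",
         variants$key[duplicated(variants$key)][1])
  }
  g <- do.call(rbind, dosages)
  dimnames(g) <- list(variants$key, samples)
  list(variants = variants, genotypes = g)
}

#' Write a multi-sample VCF
#'
#' Minimal VCF 4.2 writer (GT field only) for simulator output; biallelic
#' records only. The inverse of [read_vcf()] for dosage-coded genotypes.
#'
#' @param variants data.frame with chrom, pos, ref, alt (one row per
#'   biallelic variant).
#' @param genotypes integer dosage matrix, rows matching `variants` order,
#'   columns named by sample id.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  stopifnot(nrow(variants) == nrow(genotypes))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(variants)), function(i) {
    d <- genotypes[i, ]
    gts <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hmexome",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

numeric_or_na <- function(x, what, row_label, lo = NULL, hi = NULL) {
  x <- as.character(x)
  x[!nzchar(x) | x == "."] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop("non-numeric ", what, " at ", row_label[which(bad)[1]])
  if (!is.null(lo)) {
    oob <- !is.na(out) & (out < lo | out > hi)
    if (any(oob)) {
      stop(what, " out of [", lo, ",", hi, "] at ", row_label[which(oob)[1]],
           ": ", out[which(oob)[1]])
    }
  }
  out
}

#' Read the per-variant annotation table
#'
#' Tab-delimited, with header, one row per biallelic variant. Required
#' columns, in any order: `chrom, pos, ref, alt, gene, transcript, cdna_hgvs,
#' consequence`, the three population frequencies `maf_exac, maf_1000g,
#' maf_gnomad`, `popmax_filtering_af`, the nine categorical tool calls
#' (`sift, polyphen2_hdiv, polyphen2_hvar, mutation_taster, lrt,
#' mutation_assessor, fathmm, radialsvm, lr`; values `damaging`, `tolerated`
#' or empty) and the numeric `dann` score in \[0,1\]. Empty cells and `.`
#' mean absent. Columns outside this schema are rejected. Producers must
#' label a synonymous change that alters a splice region as `splice_site`
#' (the consequence scheme is single-label).
#'
#' @param path path to the TSV.
#' @return data.frame of class `hm_annotations`, keyed by canonical variant
#'   key (column `key`).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  unknown <- setdiff(names(df), ANNOTATION_COLS)
  if (length(unknown)) {
    stop("unknown annotation columns rejected: ", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(ANNOTATION_COLS, names(df))
  if (length(missing_cols)) {
    stop("annotation table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  lab <- paste0(path, " row ", seq_len(nrow(df)) + 1L)
  df$pos <- as.integer(numeric_or_na(df$pos, "position", lab))
  for (cc in c(FREQ_COLS, "popmax_filtering_af")) {
    df[[cc]] <- numeric_or_na(df[[cc]], cc, lab, lo = 0, hi = 1)
  }
  df$dann <- numeric_or_na(df$dann, "dann", lab, lo = 0, hi = 1)
  for (cc in c("gene", "transcript", "cdna_hgvs")) {
    df[[cc]][!nzchar(df[[cc]]) | df[[cc]] == "."] <- NA_character_
  }
  for (cc in TOOL_CALL_COLS) {
    v <- df[[cc]]
    v[!nzchar(v) | v == "."] <- NA_character_
    bad <- !is.na(v) & !v %in% c("damaging", "tolerated")
    if (any(bad)) {
      stop("invalid ", cc, " call at ", lab[which(bad)[1]], ": ", v[which(bad)[1]])
    }
    df[[cc]] <- v
  }
  bad <- !df$consequence %in% CONSEQUENCE_LEVELS
  if (any(bad)) {
    stop("unknown consequence at ", lab[which(bad)[1]], ": ",
         df$consequence[which(bad)[1]])
  }
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df$key)) {
    stop("duplicate variant key in annotation table: ",
         df$key[duplicated(df$key)][1])
  }
  rownames(df) <- df$key
  class(df) <- c("hm_annotations", "data.frame")
  df
}

read_symbol_list <- function(path, set_name) {
  if (is.null(path)) return(character(0))
  if (!file.exists(path)) stop("cannot read gene set '", set_name, "': ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read gene-set evidence files
#'
#' Takes named file paths for any subset of the evidence sets:
#' `known_hm` (established high-myopia genes), `hm_related`,
#' `ocular_disease`, `adult_ocular` and `embryonic_ocular` (expression
#' flags), each one gene symbol per line; and `myp_map`, a two-column
#' tab-delimited file (gene, MYP locus label) with no header. Unsupplied sets
#' are empty; genes absent from every set get an all-false evidence row from
#' [gene_evidence()].
#'
#' @param paths named list/vector of file paths (any subset of the six names).
#' @return object of class `hm_gene_sets`.
#' @export
read_gene_sets <- function(paths = list()) {
  paths <- as.list(paths)
  allowed <- c("known_hm", "hm_related", "ocular_disease",
               "adult_ocular", "embryonic_ocular", "myp_map")
  bad <- setdiff(names(paths), allowed)
  if (length(bad)) stop("unknown gene-set names: ", paste(bad, collapse = ", "))
  sets <- lapply(setdiff(allowed, "myp_map"),
                 function(nm) read_symbol_list(paths[[nm]], nm))
  names(sets) <- setdiff(allowed, "myp_map")
  myp <- character(0)
  if (!is.null(paths$myp_map)) {
    if (!file.exists(paths$myp_map)) {
      stop("cannot read gene set 'myp_map': ", paths$myp_map)
    }
    mm <- utils::read.delim(paths$myp_map, header = FALSE, sep = "\t",
                            colClasses = "character")
    if (ncol(mm) < 2L) stop("myp_map must have two columns (gene, locus)")
    myp <- stats::setNames(trimws(mm[[2]]), trimws(mm[[1]]))
    myp <- myp[nzchar(names(myp))]
  }
  structure(c(sets, list(myp_map = myp)), class = "hm_gene_sets")
}

#' Read gene sets from a directory
#'
#' Directory convention used by the simulator and CLI: files `known_hm.txt`,
#' `hm_related.txt`, `ocular_disease.txt`, `adult_ocular.txt`,
#' `embryonic_ocular.txt` and `myp_map.tsv`; missing files mean empty sets.
#'
#' @param dir directory path.
#' @return object of class `hm_gene_sets`.
#' @export
read_gene_sets_dir <- function(dir) {
  files <- c(known_hm = "known_hm.txt", hm_related = "hm_related.txt",
             ocular_disease = "ocular_disease.txt",
             adult_ocular = "adult_ocular.txt",
             embryonic_ocular = "embryonic_ocular.txt",
             myp_map = "myp_map.tsv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  read_gene_sets(as.list(paths[file.exists(paths)]))
}

#' Gene evidence lookup
#'
#' @param genes character vector of gene symbols (`NA` allowed).
#' @param sets an `hm_gene_sets` object.
#' @return data.frame with one row per input gene: the five boolean evidence
#'   bits and `myp_locus` (`NA` if unmapped). Genes in no set are all-false.
#' @export
gene_evidence <- function(genes, sets = read_gene_sets()) {
  stopifnot(inherits(sets, "hm_gene_sets"))
  genes <- as.character(genes)
  data.frame(
    gene = genes,
    is_known_hm_gene = !is.na(genes) & genes %in% sets$known_hm,
    is_hm_related = !is.na(genes) & genes %in% sets$hm_related,
    is_ocular_disease_gene = !is.na(genes) & genes %in% sets$ocular_disease,
    myp_locus = ifelse(!is.na(genes) & genes %in% names(sets$myp_map),
                       unname(sets$myp_map[genes]), NA_character_),
    expressed_adult_ocular = !is.na(genes) & genes %in% sets$adult_ocular,
    expressed_embryonic_ocular = !is.na(genes) & genes %in% sets$embryonic_ocular,
    stringsAsFactors = FALSE
  )
}

RANKED_TABLE_COLS <- c("family_id", "gene", "variant_key", "cdna_hgvs",
                       EVIDENCE_CATEGORIES, "weighted_total",
                       "frequency_class", "acmg_class")

#' Write the ranked candidate report
#'
#' Tab-delimited report of ranked candidates, one row per candidate in the
#' given (already ranked) order. Fixed column order: `family_id`, `gene`,
#' `variant_key`, `cdna_hgvs`, the eleven evidence categories as 0/1 in
#' report order (filter condition, pathogenicity, annotation, expression,
#' frequency), `weighted_total`, `frequency_class`, `acmg_class`.
#'
#' @param path output path.
#' @param ranked data.frame of scored candidates (as produced by
#'   [rank_candidates()] / [run_pipeline()]); an empty data.frame writes a
#'   header-only file.
#' @return `path`, invisibly.
#' @export
write_ranked_table <- function(path, ranked) {
  out <- if (nrow(ranked) == 0L) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(RANKED_TABLE_COLS)),
                                  RANKED_TABLE_COLS))
  } else {
    df <- ranked
    for (cc in EVIDENCE_CATEGORIES) df[[cc]] <- as.integer(df[[cc]])
    df[, RANKED_TABLE_COLS]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read back a ranked candidate report
#'
#' Inverse of [write_ranked_table()]; evidence categories come back as
#' logicals.
#'
#' @param path path to a ranked report TSV.
#' @return data.frame in report column order.
#' @export
read_ranked_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = ".")
  if (!identical(names(df), RANKED_TABLE_COLS)) {
    stop("not a ranked report (unexpected columns): ", path)
  }
  for (cc in EVIDENCE_CATEGORIES) df[[cc]] <- as.integer(df[[cc]]) == 1L
  df$weighted_total <- as.numeric(df$weighted_total)
  df
}
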