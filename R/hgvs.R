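#' Parse an HGVS coding-DNA substitution
#'
#' Accepts the standard substitution form `c.904C>T` and the transposed
#' letter-position-letter form `c.G848A` that appears in some clinical
#' reports; both normalize to the same representation. Only single-nucleotide
#' substitutions are supported; any other HGVS form (dup/del/ins/fs, genomic
#' g., intronic offsets) raises an "unsupported notation" error rather than
#' guessing.
#'
#' @param text HGVS c. string.
#' @return list of class `hm_cdna` with fields `position` (1-based cDNA
#'   coordinate), `ref_base`, `alt_base`.
#' @examples
#' parse_cdna("c.904C>T")
#' parse_cdna("c.G848A")
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  s <- gsub("\\s", "", text)
  m <- regmatches(s, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", s))[[1]]
  if (length(m) == 4L) {
    pos <- as.integer(m[2]); ref <- m[3]; alt <- m[4]
  } else {
    m <- regmatches(s, regexec("^c\\.([ACGT])([0-9]+)([ACGT])$", s))[[1]]
    if (length(m) != 4L) stop("unsupported notation: ", text)
    pos <- as.integer(m[3]); ref <- m[2]; alt <- m[4]
  }
  if (is.na(pos) || pos < 1L) stop("cDNA position must be >= 1: ", text)
  if (ref == alt) stop("reference and alternate bases are identical: ", text)
  structure(list(position = pos, ref_base = ref, alt_base = alt),
            class = "hm_cdna")
}

#' Parse an HGVS protein substitution
#'
#' One-letter amino-acid form, e.g. `p.R302C`; a space after `p.` (as printed
#' in some reports, `p. A253E`) and surrounding parentheses are tolerated.
#'
#' @param text HGVS p. string.
#' @return list of class `hm_protein` with fields `residue`, `ref_aa`,
#'   `alt_aa`.
#' @export
parse_protein <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  s <- gsub("[\\s()]", "", text, perl = TRUE)
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  pat <- sprintf("^p\\.([%s])([0-9]+)([%s])$", aa, aa)
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (length(m) != 4L) stop("unsupported notation: ", text)
  res <- as.integer(m[3])
  if (is.na(res) || res < 1L) stop("residue index must be >= 1: ", text)
  if (m[2] == m[4]) stop("reference and alternate residues are identical: ", text)
  structure(list(residue = res, ref_aa = m[2], alt_aa = m[4]),
            class = "hm_protein")
}

#' Codon index of a cDNA position
#'
#' Maps a 1-based coding-DNA coordinate to the 1-based index of the codon
#' (residue) it belongs to: `floor((position - 1) / 3) + 1`. Positions 1-3 are
#' codon 1, 4-6 codon 2, and so on.
#'
#' @param cdna_position 1-based coding position(s); vectorized.
#' @return integer residue index/indices.
#' @examples
#' codon_index(904) # 302
#' @export
codon_index <- function(cdna_position) {
  if (any(is.na(cdna_position)) || any(cdna_position < 1)) {
    stop("cDNA position must be >= 1")
  }
  as.integer((cdna_position - 1) %/% 3 + 1)
}

#' Check codon consistency of a c./p. pair
#'
#' `TRUE` iff the codon index of the coding position equals the protein
#' residue index. This is pure codon arithmetic; amino-acid identity is not
#' verified (that would require transcript sequences, which the package does
#' not ship).
#'
#' @param cdna a parsed [parse_cdna()] object or an HGVS c. string.
#' @param protein a parsed [parse_protein()] object or an HGVS p. string.
#' @return logical scalar.
#' @export
check_protein_consistency <- function(cdna, protein) {
  if (is.character(cdna)) cdna <- parse_cdna(cdna)
  if (is.character(protein)) protein <- parse_protein(protein)
  stopifnot(inherits(cdna, "hm_cdna"), inherits(protein, "hm_protein"))
  codon_index(cdna$position) == protein$residue
}
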