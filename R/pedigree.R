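#' Construct a pedigree
#'
#' @param family_id family identifier.
#' @param members data.frame with columns `id`, `father_id`, `mother_id`
#'   (`NA` for founders), `sex` (`male`/`female`/`unknown`), `declared_status`
#'   (`affected`/`unaffected`/`unknown`) and optional per-eye phenotype
#'   columns `se_right`, `se_left` (spherical equivalent, diopters; negative
#'   is myopic) and `al_right`, `al_left` (axial length, mm). Missing
#'   phenotype columns are filled with `NA`.
#' @return object of class `hm_pedigree`. Validates id uniqueness, that
#'   parent links point inside the family, and acyclicity of the parent
#'   graph.
#' @export
pedigree <- function(family_id, members) {
  stopifnot(is.data.frame(members),
            all(c("id", "father_id", "mother_id") %in% names(members)))
  defaults <- list(sex = "unknown", declared_status = "unknown",
                   se_right = NA_real_, se_left = NA_real_,
                   al_right = NA_real_, al_left = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(members[[nm]])) members[[nm]] <- defaults[[nm]]
  }
  members$id <- as.character(members$id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  if (anyDuplicated(members$id)) {
    stop("duplicate individual id in family ", family_id, ": ",
         members$id[duplicated(members$id)][1])
  }
  for (side in c("father_id", "mother_id")) {
    p <- members[[side]]
    present <- !is.na(p)
    missing_parent <- present & !p %in% members$id
    if (any(missing_parent)) {
      stop("family ", family_id, ": ", side, " '", p[missing_parent][1],
           "' of '", members$id[missing_parent][1], "' is not a family member")
    }
  }
  check_acyclic(members, family_id)
  bad_status <- !members$declared_status %in% c("affected", "unaffected", "unknown")
  if (any(bad_status)) stop("family ", family_id, ": invalid declared_status")
  structure(list(family_id = as.character(family_id), members = members),
            class = "hm_pedigree")
}

# error if any individual is its own ancestor; iterative ancestor closure so
# deep pedigrees cannot overflow the call stack
check_acyclic <- function(members, family_id) {
  ids <- members$id
  parent_idx <- cbind(match(members$father_id, ids), match(members$mother_id, ids))
  for (i in seq_along(ids)) {
    seen <- logical(length(ids))
    frontier <- parent_idx[i, ]
    frontier <- frontier[!is.na(frontier)]
    while (length(frontier)) {
      if (i %in% frontier) {
        stop("family ", family_id, ": individual '", ids[i],
             "' is its own ancestor (cyclic parentage)")
      }
      seen[frontier] <- TRUE
      nxt <- unique(as.vector(parent_idx[frontier, , drop = FALSE]))
      nxt <- nxt[!is.na(nxt) & !seen[nxt]]
      frontier <- nxt
    }
  }
  invisible(TRUE)
}

#' @export
print.hm_pedigree <- function(x, ...) {
  st <- table(factor(x$members$declared_status,
                     c("affected", "unaffected", "unknown")))
  cat(sprintf("hm_pedigree %s: %d members (%d affected, %d unaffected, %d unknown)\n",
              x$family_id, nrow(x$members), st[1], st[2], st[3]))
  invisible(x)
}

#' Founders of a pedigree
#'
#' @param ped an `hm_pedigree`.
#' @return character vector of member ids with neither parent in the family.
#' @export
founders <- function(ped) {
  m <- ped$members
  m$id[is.na(m$father_id) & is.na(m$mother_id)]
}

#' Read a PED pedigree file
#'
#' Six-column whitespace-delimited PED dialect: family id, individual id,
#' father id, mother id, sex (1 = male, 2 = female, other = unknown),
#' affection status (2 = affected, 1 = unaffected, 0/other = unknown). A
#' parent id of `0` encodes a founder. Duplicate (family, id) pairs, parent
#' ids outside the family, self-parentage and cyclic parentage are validation
#' errors.
#'
#' @param path path to the PED file.
#' @return named list of [pedigree()] objects, one per family, in file order.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "status"))
  if (anyDuplicated(raw[, c("family", "id")])) {
    d <- raw[duplicated(raw[, c("family", "id")]), ]
    stop("duplicate (family, id) in PED: ", d$family[1], " / ", d$id[1])
  }
  sex_map <- c(`1` = "male", `2` = "female")
  status_map <- c(`1` = "unaffected", `2` = "affected")
  peds <- lapply(split(raw, factor(raw$family, unique(raw$family))), function(fam) {
    members <- data.frame(
      id = fam$id,
      father_id = ifelse(fam$father == "0", NA_character_, fam$father),
      mother_id = ifelse(fam$mother == "0", NA_character_, fam$mother),
      sex = ifelse(fam$sex %in% names(sex_map), sex_map[fam$sex], "unknown"),
      declared_status = ifelse(fam$status %in% names(status_map),
                               status_map[fam$status], "unknown"),
      stringsAsFactors = FALSE
    )
    self <- !is.na(members$father_id) & members$father_id == members$id |
      !is.na(members$mother_id) & members$mother_id == members$id
    if (any(self)) {
      stop("family ", fam$family[1], ": individual '", members$id[self][1],
           "' listed as its own parent")
    }
    pedigree(fam$family[1], members)
  })
  peds[unique(raw$family)]
}

#' Write pedigrees to a PED file
#'
#' @param pedigrees list of `hm_pedigree` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(pedigrees, path) {
  rows <- lapply(pedigrees, function(p) {
    m <- p$members
    data.frame(
      family = p$family_id, id = m$id,
      father = ifelse(is.na(m$father_id), "0", m$father_id),
      mother = ifelse(is.na(m$mother_id), "0", m$mother_id),
      sex = c(male = "1", female = "2", unknown = "0")[m$sex],
      status = c(affected = "2", unaffected = "1", unknown = "0")[m$declared_status],
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
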