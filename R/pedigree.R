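#' Read a pedigree file
#'
#' Reads a 7-column whitespace-delimited pedigree file (family, individual,
#' father, mother, sex, phenotype, age of onset) into a tidy pedigree table.
#' Parent codes of `"0"` denote an absent parent and become `NA`. Sex is coded
#' `1` = male, `2` = female, anything else = unknown. Phenotype strings are
#' translated through `phenotype_map`; an input code missing from the map is a
#' parse error naming the offending row. The onset column accepts `"."`,
#' `"NA"` or `"0"` for a missing age of onset.
#'
#' @param path Path to the pedigree file.
#' @param phenotype_map Named character vector mapping input phenotype codes
#'   to the fixed vocabulary in [PHENOTYPES]. Defaults to
#'   [default_phenotype_map()].
#' @param sequenced Character vector of sequenced subject ids, or `NULL`
#'   (default) to mark every member sequenced.
#' @return A tibble with one row per individual and columns `family_id`, `id`,
#'   `father_id`, `mother_id`, `sex`, `phenotype`, `age_of_onset`,
#'   `sequenced`, `married_in`. Structural validity (acyclic parentage,
#'   parent sex consistency) is enforced via [validate_pedigree()].
#' @export
#' @examples
#' ped_file <- tempfile(fileext = ".ped")
#' writeLines(c(
#'   "F1 f1 0 0 1 unaffected .",
#'   "F1 m1 0 0 2 BD1 24",
#'   "F1 c1 f1 m1 2 BD1 23"
#' ), ped_file)
#' read_pedigree(ped_file)
read_pedigree <- function(path, phenotype_map = default_phenotype_map(),
                          sequenced = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_table(
    path,
    col_names = c("family_id", "id", "father_id", "mother_id", "sex",
                  "phenotype", "age_of_onset"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#"
  )
  if (nrow(raw) == 0) {
    rlang::abort("pedigree file is empty")
  }
  unknown <- !(raw$phenotype %in% names(phenotype_map))
  if (any(unknown)) {
    bad <- which(unknown)[1]
    rlang::abort(sprintf(
      "unknown phenotype code '%s' at row %d (individual '%s')",
      raw$phenotype[bad], bad, raw$id[bad]
    ), class = "famvar_parse_error")
  }
  ped <- tibble::tibble(
    family_id = raw$family_id,
    id = raw$id,
    father_id = dplyr::if_else(raw$father_id == "0", NA_character_, raw$father_id),
    mother_id = dplyr::if_else(raw$mother_id == "0", NA_character_, raw$mother_id),
    sex = dplyr::case_match(raw$sex, "1" ~ "male", "2" ~ "female",
                            .default = "unknown"),
    phenotype = unname(phenotype_map[raw$phenotype]),
    age_of_onset = suppressWarnings(dplyr::if_else(
      raw$age_of_onset %in% c(".", "NA", "0"), NA_real_,
      as.numeric(raw$age_of_onset)
    )),
    sequenced = if (is.null(sequenced)) TRUE else raw$id %in% sequenced
  )
  ped$married_in <- married_in_flag(ped)
  validate_pedigree(ped)
  ped
}

#' Default mapping from pedigree phenotype codes to the fixed vocabulary
#'
#' @return Named character vector suitable for the `phenotype_map` argument of
#'   [read_pedigree()].
#' @export
default_phenotype_map <- function() {
  c(
    BD1 = "BD1", "BD-I" = "BD1",
    BD2 = "BD2", "BD-II" = "BD2",
    SZMA = "SZMA",
    RUD = "RUD",
    UA = "unaffected", unaffected = "unaffected", "1" = "unaffected",
    UNK = "unknown", unknown = "unknown", u = "unknown", "-9" = "unknown"
  )
}

#' Write a pedigree table to PED format
#'
#' Inverse of [read_pedigree()] with the default phenotype map; absent parents
#' are written as `"0"`, missing onset as `"."`.
#'
#' @param ped Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    family_id = ped$family_id,
    id = ped$id,
    father_id = dplyr::coalesce(ped$father_id, "0"),
    mother_id = dplyr::coalesce(ped$mother_id, "0"),
    sex = dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2",
                            .default = "0"),
    phenotype = ped$phenotype,
    age_of_onset = dplyr::if_else(is.na(ped$age_of_onset), ".",
                                  format(ped$age_of_onset, trim = TRUE))
  )
  readr::write_delim(out, path, delim = " ", col_names = FALSE)
  invisible(path)
}

# married-in: no parents inside the pedigree, but co-parents children with a
# member who does have in-pedigree parents (or is ancestral via children)
married_in_flag <- function(ped) {
  has_parents <- !is.na(ped$father_id) | !is.na(ped$mother_id)
  flag <- logical(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    if (has_parents[i]) next
    kids <- ped$father_id %in% ped$id[i] | ped$mother_id %in% ped$id[i]
    if (!any(kids)) next
    mates <- unique(c(ped$father_id[kids], ped$mother_id[kids]))
    mates <- setdiff(mates[!is.na(mates)], ped$id[i])
    mate_rows <- match(mates, ped$id)
    mate_rows <- mate_rows[!is.na(mate_rows)]
    if (length(mate_rows) > 0 && any(has_parents[mate_rows])) flag[i] <- TRUE
  }
  flag
}

#' Validate structural invariants of a pedigree table
#'
#' Checks that parent references resolve within the same family (or are
#' absent), that referenced fathers are male and mothers female, that the
#' parentage graph is acyclic, and that phenotypes use the fixed vocabulary.
#'
#' @param ped Pedigree tibble as returned by [read_pedigree()].
#' @return `ped`, invisibly. Errors of class `famvar_structural_error` are
#'   raised on violation.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("family_id", "id", "father_id", "mother_id", "sex",
                  "phenotype") %in% names(ped)))
  if (anyDuplicated(ped$id) > 0) {
    rlang::abort("duplicate individual ids in pedigree",
                 class = "famvar_structural_error")
  }
  if (!all(ped$phenotype %in% PHENOTYPES)) {
    rlang::abort("phenotype outside the fixed vocabulary",
                 class = "famvar_structural_error")
  }
  for (fam in unique(ped$family_id)) {
    p <- ped[ped$family_id == fam, ]
    for (col in c("father_id", "mother_id")) {
      refs <- p[[col]][!is.na(p[[col]])]
      missing_refs <- setdiff(refs, p$id)
      if (length(missing_refs) > 0) {
        rlang::abort(sprintf(
          "family %s: parent id(s) %s do not resolve within the family",
          fam, paste(missing_refs, collapse = ", ")
        ), class = "famvar_structural_error")
      }
    }
    fa <- match(p$father_id, p$id)
    mo <- match(p$mother_id, p$id)
    if (any(p$sex[fa[!is.na(fa)]] == "female")) {
      rlang::abort(sprintf("family %s: female individual listed as father", fam),
                   class = "famvar_structural_error")
    }
    if (any(p$sex[mo[!is.na(mo)]] == "male")) {
      rlang::abort(sprintf("family %s: male individual listed as mother", fam),
                   class = "famvar_structural_error")
    }
    # cycle check: repeated parent-pointer contraction must terminate
    depth <- pedigree_depth(p)
    if (anyNA(depth)) {
      rlang::abort(sprintf("family %s: cyclic parentage", fam),
                   class = "famvar_structural_error")
    }
  }
  invisible(ped)
}

# generation depth per member (founders = 0); NA signals a cycle
pedigree_depth <- function(p) {
  n <- nrow(p)
  fa <- match(p$father_id, p$id)
  mo <- match(p$mother_id, p$id)
  depth <- ifelse(is.na(fa) & is.na(mo), 0L, NA_integer_)
  for (iter in seq_len(n + 1)) {
    todo <- which(is.na(depth))
    if (length(todo) == 0) return(depth)
    for (i in todo) {
      dp <- c(if (!is.na(fa[i])) depth[fa[i]], if (!is.na(mo[i])) depth[mo[i]])
      need <- sum(!is.na(fa[i]), !is.na(mo[i]))
      if (length(dp) == need && !anyNA(dp)) depth[i] <- max(dp) + 1L
    }
  }
  depth
}

# members sorted so that parents precede children
pedigree_order <- function(p) {
  order(pedigree_depth(p))
}

#' Affection scheme: which phenotypes count as affected / unaffected
#'
#' The `strict` scheme mirrors family ascertainment (affected = BD-I, BD-II,
#' SZMA); the `broad` scheme adds recurrent unipolar depression (RUD) to the
#' affected set, as used for the onset-burden analysis. In both schemes only
#' `"unaffected"` counts as unaffected; `"unknown"` (and `RUD` under
#' `strict`) is excluded from both sides.
#'
#' @param name `"strict"` or `"broad"`.
#' @return A list with character elements `affected` and `unaffected`.
#' @export
affection_scheme <- function(name = c("strict", "broad")) {
  name <- match.arg(name)
  affected <- c("BD1", "BD2", "SZMA")
  if (name == "broad") affected <- c(affected, "RUD")
  list(name = name, affected = affected, unaffected = "unaffected")
}

# affection status under a scheme: "affected", "unaffected" or NA (excluded)
affection_status <- function(phenotype, scheme) {
  dplyr::case_when(
    phenotype %in% scheme$affected ~ "affected",
    phenotype %in% scheme$unaffected ~ "unaffected",
    TRUE ~ NA_character_
  )
}
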