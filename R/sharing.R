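#' Sharing rule for classifying variants within a family
#'
#' A variant is a potentially etiologic variant (PEV) in a family when carried
#' by at least `min_affected` affected relatives and at most
#' `max_unaffected_pev` unaffected relatives; it is a likely neutral variant
#' (LNV) when carried by between `min_unaffected_lnv` and `max_unaffected_lnv`
#' unaffected relatives and at most `max_affected_lnv` affected relatives.
#' PEV takes precedence when both rules match.
#'
#' @param min_affected Minimum affected carriers for PEV, default 3.
#' @param max_unaffected_pev Maximum unaffected carriers for PEV, default 1.
#' @param min_unaffected_lnv,max_unaffected_lnv Unaffected-carrier range for
#'   LNV, defaults 1 and 3.
#' @param max_affected_lnv Maximum affected carriers for LNV, default 1.
#' @return A list of rule parameters.
#' @export
sharing_rule <- function(min_affected = 3, max_unaffected_pev = 1,
                         min_unaffected_lnv = 1, max_unaffected_lnv = 3,
                         max_affected_lnv = 1) {
  rule <- list(min_affected = min_affected,
               max_unaffected_pev = max_unaffected_pev,
               min_unaffected_lnv = min_unaffected_lnv,
               max_unaffected_lnv = max_unaffected_lnv,
               max_affected_lnv = max_affected_lnv)
  stopifnot(all(unlist(rule) >= 0))
  rule
}

#' Classify carrier counts into PEV / LNV / neither
#'
#' Vectorised core of the sharing classification, operating on affected and
#' unaffected carrier counts directly.
#'
#' @param n_affected,n_unaffected Integer vectors of carrier counts.
#' @param rule See [sharing_rule()].
#' @return Character vector with values `"PEV"`, `"LNV"` or `"neither"`.
#' @export
sharing_label <- function(n_affected, n_unaffected, rule = sharing_rule()) {
  pev <- n_affected >= rule$min_affected &
    n_unaffected <= rule$max_unaffected_pev
  lnv <- !pev &
    n_unaffected >= rule$min_unaffected_lnv &
    n_unaffected <= rule$max_unaffected_lnv &
    n_affected <= rule$max_affected_lnv
  dplyr::case_when(pev ~ "PEV", lnv ~ "LNV", TRUE ~ "neither")
}

#' Count affected and unaffected carriers of each variant in each family
#'
#' A carrier has genotype `het` or `hom_alt`. Missing genotypes are excluded
#' from both counts (a missing call is neither carrier nor non-carrier), as
#' are members whose phenotype falls outside both sides of the affection
#' scheme and members not sequenced. Carriers are counted per family: the same
#' variant observed in two families yields two independent rows.
#'
#' @param vc Variant-call table.
#' @param ped Pedigree tibble covering the subjects in `vc`.
#' @param scheme Affection scheme, see [affection_scheme()].
#' @return Tibble with `family_id`, `variant_id`, `n_affected`,
#'   `n_unaffected` and `carrier_ids` (list of carrier subject ids among
#'   scheme-classified members).
#' @export
count_carriers <- function(vc, ped, scheme = affection_scheme("strict")) {
  members <- ped[ped$sequenced, c("family_id", "id", "phenotype")]
  members$status <- affection_status(members$phenotype, scheme)
  calls <- dplyr::inner_join(
    vc[, c("variant_id", "subject_id", "gt")],
    members, by = c(subject_id = "id")
  )
  calls <- calls[!is.na(calls$status) & calls$gt != "missing", ]
  calls$carrier <- calls$gt %in% c("het", "hom_alt")
  out <- calls |>
    dplyr::group_by(.data$family_id, .data$variant_id) |>
    dplyr::summarise(
      n_affected = sum(.data$carrier & .data$status == "affected"),
      n_unaffected = sum(.data$carrier & .data$status == "unaffected"),
      carrier_ids = list(.data$subject_id[.data$carrier]),
      .groups = "drop"
    )
  out
}

#' Classify variant sharing within families
#'
#' Applies the PEV/LNV sharing rule to per-family carrier counts (see
#' [count_carriers()] and [sharing_label()]). The caller decides which
#' variants to classify; for the potentially etiologic pool this is the
#' pathogenic-candidate subset from [annotate_variants()].
#'
#' @inheritParams count_carriers
#' @param rule See [sharing_rule()].
#' @return Tibble of sharing calls: `family_id`, `variant_id`, `label`
#'   (`PEV`/`LNV`/`neither`), `n_affected`, `n_unaffected`, `carrier_ids`.
#' @export
classify_sharing <- function(vc, ped, scheme = affection_scheme("strict"),
                             rule = sharing_rule()) {
  counts <- count_carriers(vc, ped, scheme)
  counts$label <- sharing_label(counts$n_affected, counts$n_unaffected, rule)
  dplyr::relocate(counts, "family_id", "variant_id", "label")
}

#' Find compound heterozygotes within genes
#'
#' Flags subjects carrying two or more heterozygous variants in the same gene
#' and, where both parents are genotyped, resolves phase by parental origin:
#' a pair is `trans` when its two alternate alleles trace to different
#' parents, `cis` when they trace to the same parent, and `unknown` when
#' transmission is ambiguous or parents are unavailable.
#'
#' @param vc Variant-call table (typically restricted to candidate variants).
#' @param ped Pedigree tibble.
#' @return Tibble with `subject_id`, `gene`, `variant_id_1`, `variant_id_2`,
#'   `phase_status`.
#' @export
find_compound_hets <- function(vc, ped) {
  hets <- vc[vc$gt == "het" & !is.na(vc$gene), ]
  groups <- split(hets$variant_id,
                  list(subject = hets$subject_id, gene = hets$gene),
                  drop = TRUE, sep = "\r")
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) {
    return(tibble::tibble(subject_id = character(), gene = character(),
                          variant_id_1 = character(),
                          variant_id_2 = character(),
                          phase_status = character()))
  }
  out <- dplyr::bind_rows(purrr::imap(groups, function(vids, key) {
    pairs <- utils::combn(sort(vids), 2)
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    tibble::tibble(subject_id = parts[1], gene = parts[2],
                   variant_id_1 = pairs[1, ], variant_id_2 = pairs[2, ])
  }))
  gt_of <- function(variant, subject) {
    idx <- match(paste(variant, subject), paste(vc$variant_id, vc$subject_id))
    ifelse(is.na(idx), "missing", vc$gt[idx])
  }
  origin <- function(variant, subject) {
    # parent that must have transmitted the alt allele; NA when ambiguous
    row <- ped[ped$id == subject, ]
    if (nrow(row) == 0 || is.na(row$father_id) || is.na(row$mother_id)) {
      return(NA_character_)
    }
    fgt <- gt_of(variant, row$father_id)
    mgt <- gt_of(variant, row$mother_id)
    if (fgt == "missing" || mgt == "missing") return(NA_character_)
    f_can <- fgt %in% c("het", "hom_alt")
    m_can <- mgt %in% c("het", "hom_alt")
    if (f_can && !m_can) return("father")
    if (m_can && !f_can) return("mother")
    NA_character_
  }
  out$phase_status <- vapply(seq_len(nrow(out)), function(i) {
    o1 <- origin(out$variant_id_1[i], out$subject_id[i])
    o2 <- origin(out$variant_id_2[i], out$subject_id[i])
    if (is.na(o1) || is.na(o2)) return("unknown")
    if (o1 == o2) "cis" else "trans"
  }, character(1))
  tibble::as_tibble(out)
}

#' Multi-class gene convergence table
#'
#' Aggregates qualifying events per gene across variant classes: PEV sharing
#' calls (SNVs), segregating CNVs and de novo candidates. Genes with at least
#' two qualifying events are reported with the number of distinct families
#' contributing, a per-class event breakdown, and total affected / unaffected
#' carrier counts, sorted by gene symbol.
#'
#' @param sharing_calls Sharing-call table (only rows with `label == "PEV"`
#'   qualify); needs a `gene` column or is joined to `vc` sites via
#'   `variant_id`.
#' @param vc Variant-call table used to recover the gene of each SNV.
#' @param ped Pedigree tibble (for affection status of carriers).
#' @param scheme Affection scheme.
#' @param cnv_calls Optional CNV table with `family_id`, `gene`,
#'   `carrier_ids`.
#' @param denovo_calls Optional de novo candidate table with `subject_id`,
#'   `gene` (plus `family_id` if available).
#' @return Tibble with `gene`, `n_events`, `n_families`, `event_types`,
#'   `n_affected_total`, `n_unaffected_total`.
#' @export
convergence_table <- function(sharing_calls, vc, ped,
                              scheme = affection_scheme("strict"),
                              cnv_calls = NULL, denovo_calls = NULL) {
  sites <- variant_sites(vc)
  status <- setNames(affection_status(ped$phenotype, scheme), ped$id)
  fam <- setNames(ped$family_id, ped$id)

  ev_snv <- sharing_calls[sharing_calls$label == "PEV", ]
  ev_snv$gene <- sites$gene[match(ev_snv$variant_id, sites$variant_id)]
  events <- tibble::tibble(
    gene = ev_snv$gene, family_id = ev_snv$family_id, type = "SNV",
    carriers = ev_snv$carrier_ids
  )
  if (!is.null(denovo_calls) && nrow(denovo_calls) > 0) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      gene = denovo_calls$gene,
      family_id = unname(fam[denovo_calls$subject_id]),
      type = "de novo",
      carriers = as.list(denovo_calls$subject_id)
    ))
  }
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0 && "gene" %in% names(cnv_calls)) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      gene = cnv_calls$gene, family_id = cnv_calls$family_id, type = "CNV",
      carriers = cnv_calls$carrier_ids
    ))
  }
  events <- events[!is.na(events$gene), ]
  if (nrow(events) == 0) {
    return(tibble::tibble(gene = character(), n_events = integer(),
                          n_families = integer(), event_types = character(),
                          n_affected_total = integer(),
                          n_unaffected_total = integer()))
  }
  events |>
    dplyr::group_by(.data$gene) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      n_families = dplyr::n_distinct(.data$family_id),
      event_types = paste(vapply(
        split(.data$type, .data$type),
        function(x) paste(length(x), x[1]), character(1)
      ), collapse = "; "),
      n_affected_total = {
        ids <- unique(unlist(.data$carriers))
        sum(status[ids] == "affected", na.rm = TRUE)
      },
      n_unaffected_total = {
        ids <- unique(unlist(.data$carriers))
        sum(status[ids] == "unaffected", na.rm = TRUE)
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene)
}
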