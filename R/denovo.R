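#' Mendelian-error check for a genotype trio
#'
#' `TRUE` when the child's diploid genotype is impossible given one
#' transmitted allele from each parent (for a biallelic site), e.g. a
#' heterozygous child of two homozygous-reference parents, or a
#' homozygous-alternate child of a homozygous-reference parent. Any missing
#' genotype makes the trio non-evaluable and returns `NA`, distinct from
#' `FALSE`.
#'
#' @param child_gt,father_gt,mother_gt Character vectors of genotype states
#'   (`hom_ref`, `het`, `hom_alt`, `missing`), recycled to a common length.
#' @return Logical vector (`NA` = not evaluable).
#' @export
mendelian_error <- function(child_gt, father_gt, mother_gt) {
  n <- max(length(child_gt), length(father_gt), length(mother_gt))
  child_gt <- rep_len(child_gt, n)
  father_gt <- rep_len(father_gt, n)
  mother_gt <- rep_len(mother_gt, n)
  # transmissible allele sets per genotype: hom_ref {0}, het {0,1}, hom_alt {1}
  can_give <- list(hom_ref = 0L, het = 0:1, hom_alt = 1L)
  child_sets <- list(hom_ref = c(0L, 0L), het = c(0L, 1L), hom_alt = c(1L, 1L))
  vapply(seq_len(n), function(i) {
    if (child_gt[i] == "missing" || father_gt[i] == "missing" ||
        mother_gt[i] == "missing") {
      return(NA)
    }
    cs <- child_sets[[child_gt[i]]]
    fa <- can_give[[father_gt[i]]]
    mo <- can_give[[mother_gt[i]]]
    possible <- any(vapply(fa, function(a) any(
      (a == cs[1] & mo == cs[2]) | (a == cs[2] & mo == cs[1])
    ), logical(1)))
    !possible
  }, logical(1))
}

#' Detect de novo variant candidates in sequenced trios
#'
#' Screens every offspring with both parents sequenced for sites at which the
#' offspring shows a Mendelian error against two homozygous-reference parents,
#' then applies read-level gates standing in for manual read inspection:
#' total depth strictly above `depth_min` in all three trio members, at least
#' `min_alt_reads` alternate reads in the offspring, and at most
#' `max_parent_alt_reads` alternate reads in each parent. Optionally a
#' candidate is disqualified when any additional relative in the family
#' carries the allele (the variant is then inherited or a site-level
#' artifact). Failing sites are retained with the first failing gate recorded.
#'
#' @param vc Variant-call table.
#' @param ped Pedigree tibble.
#' @param depth_min Total-depth gate (strict `>`), default 20. Interpreted as
#'   total read depth in all three members; set `gate_on = "alt"` to gate the
#'   offspring's alternate-allele depth instead.
#' @param min_alt_reads Minimum offspring alternate reads, default 5.
#' @param max_parent_alt_reads Maximum parental alternate reads, default 1.
#' @param disqualify_other_carriers Logical, default `TRUE`.
#' @param gate_on `"total"` (default) or `"alt"`.
#' @return Tibble of class-agnostic de novo calls: `subject_id`, `family_id`,
#'   `variant_id`, `gene`, `consequence`, `dp_father`, `dp_mother`, `dp_child`,
#'   `ad_ref`, `ad_alt`, `status` (`candidate` or `filtered`), `reason`.
#' @export
detect_de_novo <- function(vc, ped, depth_min = 20, min_alt_reads = 5,
                           max_parent_alt_reads = 1,
                           disqualify_other_carriers = TRUE,
                           gate_on = c("total", "alt")) {
  gate_on <- match.arg(gate_on)
  trios <- trio_table(ped)
  if (nrow(trios) == 0) {
    return(empty_denovo())
  }
  calls <- vc[, c("variant_id", "subject_id", "gt", "ad_ref", "ad_alt", "dp")]
  key <- function(v, s) paste(v, s, sep = "\r")
  lut <- setNames(seq_len(nrow(calls)), key(calls$variant_id, calls$subject_id))
  sites <- variant_sites(vc)

  out <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    tr <- trios[i, ]
    ci <- lut[key(sites$variant_id, tr$id)]
    fi <- lut[key(sites$variant_id, tr$father_id)]
    mi <- lut[key(sites$variant_id, tr$mother_id)]
    ok <- !is.na(ci) & !is.na(fi) & !is.na(mi)
    if (!any(ok)) next
    cgt <- calls$gt[ci[ok]]; fgt <- calls$gt[fi[ok]]; mgt <- calls$gt[mi[ok]]
    merr <- mendelian_error(cgt, fgt, mgt)
    hit <- which(!is.na(merr) & merr & fgt == "hom_ref" & mgt == "hom_ref")
    if (length(hit) == 0) next
    sub <- which(ok)[hit]
    d <- tibble::tibble(
      subject_id = tr$id,
      family_id = tr$family_id,
      variant_id = sites$variant_id[sub],
      gene = sites$gene[sub],
      consequence = sites$consequence[sub],
      dp_father = calls$dp[fi[sub]],
      dp_mother = calls$dp[mi[sub]],
      dp_child = calls$dp[ci[sub]],
      ad_ref = calls$ad_ref[ci[sub]],
      ad_alt = calls$ad_alt[ci[sub]],
      parent_alt_max = pmax(calls$ad_alt[fi[sub]], calls$ad_alt[mi[sub]])
    )
    depth_val <- if (gate_on == "total") {
      pmin(d$dp_father, d$dp_mother, d$dp_child)
    } else {
      d$ad_alt
    }
    reason <- rep(NA_character_, nrow(d))
    reason[is.na(depth_val) | depth_val <= depth_min] <- "depth"
    reason[is.na(reason) &
             (is.na(d$ad_alt) | d$ad_alt < min_alt_reads)] <- "offspring_alt_reads"
    reason[is.na(reason) & !is.na(d$parent_alt_max) &
             d$parent_alt_max > max_parent_alt_reads] <- "parent_alt_reads"
    if (disqualify_other_carriers) {
      fam_ids <- ped$id[ped$family_id == tr$family_id & ped$sequenced]
      others <- setdiff(fam_ids, c(tr$id, tr$father_id, tr$mother_id))
      if (length(others) > 0) {
        for (j in which(is.na(reason))) {
          oi <- lut[key(d$variant_id[j], others)]
          ogt <- calls$gt[oi[!is.na(oi)]]
          if (any(ogt %in% c("het", "hom_alt"))) reason[j] <- "carried_by_relative"
        }
      }
    }
    d$status <- ifelse(is.na(reason), "candidate", "filtered")
    d$reason <- reason
    out[[i]] <- d
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty_denovo() else dplyr::select(res, -"parent_alt_max")
}

empty_denovo <- function() {
  tibble::tibble(
    subject_id = character(), family_id = character(), variant_id = character(),
    gene = character(), consequence = character(),
    dp_father = integer(), dp_mother = integer(), dp_child = integer(),
    ad_ref = integer(), ad_alt = integer(),
    status = character(), reason = character()
  )
}

# offspring with both parents present and sequenced
trio_table <- function(ped) {
  tr <- ped[!is.na(ped$father_id) & !is.na(ped$mother_id) & ped$sequenced, ]
  seqd <- ped$id[ped$sequenced]
  tr[tr$father_id %in% seqd & tr$mother_id %in% seqd,
     c("family_id", "id", "father_id", "mother_id", "phenotype")]
}

#' Compare de novo rates between affected and unaffected offspring
#'
#' Counts de novo candidates per trio offspring (offspring without any
#' candidate count as zero), optionally restricted to coding consequence
#' classes, and compares the two groups with the self-contained rank-sum test.
#'
#' @param denovo_calls Output of [detect_de_novo()].
#' @param ped Pedigree tibble.
#' @param scheme Affection scheme for grouping offspring.
#' @param coding_only Restrict to coding classes (everything except `other`),
#'   default `FALSE` (the simulator emits coding sites only, making this a
#'   pass-through flag).
#' @return Tibble with one row: `mean_affected`, `mean_unaffected`,
#'   `n_affected`, `n_unaffected`, `u`, `p_value`.
#' @export
de_novo_rate_comparison <- function(denovo_calls, ped,
                                    scheme = affection_scheme("strict"),
                                    coding_only = FALSE) {
  trios <- trio_table(ped)
  cand <- denovo_calls[denovo_calls$status == "candidate", ]
  if (coding_only) cand <- cand[!cand$consequence %in% "other", ]
  counts <- table(factor(cand$subject_id, levels = trios$id))
  status <- affection_status(trios$phenotype, scheme)
  a <- as.integer(counts[!is.na(status) & status == "affected"])
  u <- as.integer(counts[!is.na(status) & status == "unaffected"])
  if (length(a) == 0 || length(u) == 0) {
    rlang::abort("both offspring groups must be non-empty")
  }
  test <- mann_whitney_u(a, u)
  tibble::tibble(
    mean_affected = mean(a), mean_unaffected = mean(u),
    n_affected = length(a), n_unaffected = length(u),
    u = test$u, p_value = test$p_value
  )
}
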