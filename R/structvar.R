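#' Detect deletion candidates from runs of Mendelian inconsistency
#'
#' Scans each family chromosome by chromosome, in position order, for sites at
#' which some parent-offspring pair shows a Mendelian inconsistency consistent
#' with hemizygosity: the child apparently homozygous for an allele a
#' genotyped parent cannot have contributed (opposite homozygotes in
#' particular). Successive supporting sites separated by at most `max_gap_bp`
#' are merged; a run of at least `min_run` supporting sites becomes one
#' deletion call spanning the first to last supporting site. The initial
#' carrier set contains the members of inconsistent pairs whose calls are
#' hemizygosity-consistent (never heterozygous) across the run.
#'
#' @param vc Variant-call table.
#' @param ped Pedigree tibble.
#' @param min_run Minimum supporting sites per call, default 3.
#' @param max_gap_bp Maximum distance between successive supporting sites,
#'   default 1e6.
#' @return Tibble of CNV calls: `family_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `type` (`"deletion"`), `n_supporting_sites`,
#'   `carrier_ids` (list), `variant_ids` (list of supporting sites),
#'   `source` (`"wes_inconsistency"`).
#' @export
detect_deletion_runs <- function(vc, ped, min_run = 3, max_gap_bp = 1e6) {
  out <- list()
  for (fam in unique(ped$family_id)) {
    p <- ped[ped$family_id == fam & ped$sequenced, ]
    pairs <- parent_offspring_pairs(p)
    if (nrow(pairs) == 0) next
    calls <- vc[vc$subject_id %in% p$id, ]
    gtw <- tidyr::pivot_wider(
      calls[, c("variant_id", "chrom", "pos", "subject_id", "gt")],
      names_from = "subject_id", values_from = "gt"
    )
    gtw <- gtw[order(gtw$chrom, gtw$pos), ]
    # per site: which pairs are hemizygosity-consistent inconsistencies
    supp <- matrix(FALSE, nrow(gtw), nrow(pairs))
    for (j in seq_len(nrow(pairs))) {
      cg <- gtw[[pairs$child[j]]]
      pg <- gtw[[pairs$parent[j]]]
      if (is.null(cg) || is.null(pg)) next
      supp[, j] <- hemizygous_inconsistency(cg, pg)
    }
    support <- rowSums(supp) > 0
    if (!any(support)) next
    for (ch in unique(gtw$chrom[support])) {
      ii <- which(support & gtw$chrom == ch)
      runs <- split(ii, cumsum(c(1, diff(gtw$pos[ii]) > max_gap_bp)))
      for (run in runs) {
        if (length(run) < min_run) next
        members <- unique(c(pairs$child[colSums(supp[run, , drop = FALSE]) > 0],
                            pairs$parent[colSums(supp[run, , drop = FALSE]) > 0]))
        # carriers must never be heterozygous across the run
        carriers <- members[vapply(members, function(id) {
          g <- gtw[[id]][run]
          !any(g == "het", na.rm = TRUE)
        }, logical(1))]
        out[[length(out) + 1]] <- tibble::tibble(
          family_id = fam, chrom = ch,
          start = as.integer(gtw$pos[run[1]]),
          end = as.integer(gtw$pos[run[length(run)]]),
          type = "deletion",
          n_supporting_sites = length(run),
          carrier_ids = list(sort(carriers)),
          variant_ids = list(gtw$variant_id[run]),
          source = "wes_inconsistency"
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      family_id = character(), chrom = character(), start = integer(),
      end = integer(), type = character(), n_supporting_sites = integer(),
      carrier_ids = list(), variant_ids = list(), source = character()
    ))
  }
  dplyr::bind_rows(out)
}

# genotyped parent-offspring pairs within one family
parent_offspring_pairs <- function(p) {
  rows <- list()
  for (i in seq_len(nrow(p))) {
    for (par in c(p$father_id[i], p$mother_id[i])) {
      if (!is.na(par) && par %in% p$id) {
        rows[[length(rows) + 1]] <- tibble::tibble(child = p$id[i], parent = par)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(child = character(), parent = character()))
  }
  dplyr::bind_rows(rows)
}

# inconsistency patterns a hemizygous deletion produces in a duo:
# opposite homozygotes (either member may be the hemizygous one)
hemizygous_inconsistency <- function(child_gt, parent_gt) {
  (child_gt == "hom_ref" & parent_gt == "hom_alt") |
    (child_gt == "hom_alt" & parent_gt == "hom_ref")
}

#' Phase genotypes by transmission within nuclear families
#'
#' Assigns parental origin of each allele wherever Mendelian logic is
#' decisive given both parents' genotypes (e.g. a heterozygous child of a
#' homozygous-reference father and homozygous-alternate mother). Ambiguous
#' sites (e.g. all three members heterozygous) and Mendelian-inconsistent
#' sites yield `NA` phase; the assignment never contradicts the observed
#' genotypes.
#'
#' @param vc Variant-call table.
#' @param ped Pedigree tibble; only offspring with both parents sequenced are
#'   phased.
#' @return Tibble with `subject_id`, `variant_id`, `paternal_allele`,
#'   `maternal_allele` (`"ref"`, `"alt"` or `NA`).
#' @export
phase_by_transmission <- function(vc, ped) {
  trios <- trio_table(ped)
  if (nrow(trios) == 0) {
    return(tibble::tibble(subject_id = character(), variant_id = character(),
                          paternal_allele = character(),
                          maternal_allele = character()))
  }
  calls <- vc[, c("variant_id", "subject_id", "gt")]
  gtw <- tidyr::pivot_wider(calls, names_from = "subject_id",
                            values_from = "gt")
  out <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    tr <- trios[i, ]
    ph <- phase_trio(gtw[[tr$id]], gtw[[tr$father_id]], gtw[[tr$mother_id]])
    out[[i]] <- tibble::tibble(
      subject_id = tr$id, variant_id = gtw$variant_id,
      paternal_allele = ph$pat, maternal_allele = ph$mat
    )
  }
  dplyr::bind_rows(out)
}

# decisive-transmission phasing for one trio, vectorised over sites
phase_trio <- function(cg, fg, mg) {
  n <- length(cg)
  pat <- rep(NA_character_, n)
  mat <- rep(NA_character_, n)
  give <- list(hom_ref = list(0L), het = list(0L, 1L), hom_alt = list(1L),
               missing = list(0L, 1L))
  child_pairs <- list(hom_ref = list(c(0L, 0L)),
                      het = list(c(0L, 1L), c(1L, 0L)),
                      hom_alt = list(c(1L, 1L)))
  for (i in seq_len(n)) {
    if (is.na(cg[i]) || cg[i] == "missing" || is.na(fg[i]) || is.na(mg[i])) next
    cps <- child_pairs[[cg[i]]]
    fa <- unlist(give[[fg[i]]])
    mo <- unlist(give[[mg[i]]])
    valid <- Filter(function(p) p[1] %in% fa && p[2] %in% mo, cps)
    if (length(valid) == 1) {
      pat[i] <- c("ref", "alt")[valid[[1]][1] + 1L]
      mat[i] <- c("ref", "alt")[valid[[1]][2] + 1L]
    }
  }
  list(pat = pat, mat = mat)
}

#' Infer CNV segregation across the pedigree
#'
#' Extends a deletion call's carrier set to all relatives using
#' genotype-pattern constraint propagation within the interval: a member
#' heterozygous at any interval site is a definite non-carrier (both
#' haplotypes present); a member implicated in a hemizygosity-consistent
#' inconsistency at an interval site is a carrier; everyone else is unknown.
#' On clean data this never labels a true non-carrier as carrier. When two
#' confirmed carriers are definite non-carriers of each other's evidence —
#' both parents of a confirmed carrier excluded, for example — the carrier
#' evidence is contradictory and segregation is aborted with a conflict flag.
#'
#' @param cnv One row of [detect_deletion_runs()] output.
#' @param vc Variant-call table.
#' @param ped Pedigree tibble.
#' @return Tibble with `subject_id`, `status`
#'   (`carrier`/`non_carrier`/`unknown`) for every sequenced family member,
#'   with attribute `conflict` (logical).
#' @export
infer_cnv_segregation <- function(cnv, vc, ped) {
  stopifnot(nrow(cnv) == 1)
  p <- ped[ped$family_id == cnv$family_id & ped$sequenced, ]
  site_ids <- cnv$variant_ids[[1]]
  calls <- vc[vc$variant_id %in% site_ids & vc$subject_id %in% p$id, ]
  gtw <- tidyr::pivot_wider(
    calls[, c("variant_id", "subject_id", "gt")],
    names_from = "subject_id", values_from = "gt"
  )
  pairs <- parent_offspring_pairs(p)
  carriers <- character(0)
  for (j in seq_len(nrow(pairs))) {
    cg <- gtw[[pairs$child[j]]]; pg <- gtw[[pairs$parent[j]]]
    if (is.null(cg) || is.null(pg)) next
    if (any(hemizygous_inconsistency(cg, pg))) {
      carriers <- union(carriers, c(pairs$child[j], pairs$parent[j]))
    }
  }
  status <- vapply(p$id, function(id) {
    g <- gtw[[id]]
    if (is.null(g)) return("unknown")
    if (any(g == "het", na.rm = TRUE)) return("non_carrier")
    if (id %in% carriers) return("carrier")
    "unknown"
  }, character(1))
  # carriers that are simultaneously excluded are contradictory evidence
  conflict <- any(status[carriers] == "non_carrier")
  if (conflict) {
    status[] <- "unknown"
  }
  res <- tibble::tibble(subject_id = p$id, status = unname(status))
  attr(res, "conflict") <- conflict
  res
}

#' Filter CNV calls on frequency, span and support
#'
#' Retains calls with population frequency below `maf_max` (missing frequency
#' passes). Array-sourced calls (`source == "external_array"`) must span at
#' least `min_span_bp` and be supported by at least `min_sites` probes;
#' genotype-inconsistency calls instead require `min_run` supporting variant
#' sites, since exonic variant density is far below array probe density.
#'
#' @param calls CNV call table; optional columns `pop_freq`, `n_probes`.
#' @param maf_max Frequency cut, default 0.05 (strict `<`).
#' @param min_span_bp Minimum span for array calls, default 25000.
#' @param min_sites Minimum probes for array calls, default 25.
#' @param min_run Minimum supporting sites for genotype-derived calls,
#'   default 3.
#' @return The retained rows.
#' @export
filter_cnvs <- function(calls, maf_max = 0.05, min_span_bp = 25000,
                        min_sites = 25, min_run = 3) {
  if (nrow(calls) == 0) return(calls)
  freq_ok <- if ("pop_freq" %in% names(calls)) {
    is.na(calls$pop_freq) | calls$pop_freq < maf_max
  } else {
    rep(TRUE, nrow(calls))
  }
  span <- calls$end - calls$start + 1
  probes <- if ("n_probes" %in% names(calls)) calls$n_probes else
    calls$n_supporting_sites
  array_ok <- span >= min_span_bp & probes >= min_sites
  wes_ok <- calls$n_supporting_sites >= min_run
  keep <- freq_ok & ifelse(calls$source == "external_array", array_ok, wes_ok)
  calls[keep, ]
}

#' Export CNV calls to BED
#'
#' Converts the 1-based inclusive intervals to BED's 0-based half-open
#' convention.
#'
#' @param calls CNV call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(calls, path) {
  bed <- data.frame(
    chrom = calls$chrom,
    start = calls$start - 1L,
    end = calls$end,
    name = paste(calls$family_id, calls$type, sep = "_"),
    score = calls$n_supporting_sites,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Pairwise identity-by-descent estimation (method of moments)
#'
#' Estimates the probabilities `Z0`, `Z1`, `Z2` of sharing 0, 1 or 2 alleles
#' identical by descent for subject pairs from identity-by-state counts at
#' (approximately) independent biallelic sites with known allele frequencies,
#' then projects onto the probability simplex; `pi_hat = Z1/2 + Z2`. Sites
#' are greedily pruned to a minimum pairwise distance of `prune_bp` as an
#' independence proxy, and sites with missing or monomorphic frequency are
#' dropped.
#'
#' @param vc Variant-call table (genotypes for the subjects of interest).
#' @param allele_freqs Named numeric vector of alternate-allele frequencies
#'   by `variant_id`; defaults to frequencies estimated from `vc` itself.
#' @param pairs Two-column data frame of subject id pairs, or `NULL` for all
#'   pairs of subjects present in `vc`.
#' @param min_sites Minimum informative sites required, default 200.
#' @param prune_bp Minimum distance between retained sites, default 1e5.
#' @return Tibble with `id1`, `id2`, `n_sites`, `Z0`, `Z1`, `Z2`, `pi_hat`.
#' @export
pairwise_ibd <- function(vc, allele_freqs = NULL, pairs = NULL,
                         min_sites = 200, prune_bp = 1e5) {
  sites <- variant_sites(vc)
  sites <- sites[order(sites$chrom, sites$pos), ]
  keep <- prune_sites(sites$chrom, sites$pos, prune_bp)
  sites <- sites[keep, ]
  if (is.null(allele_freqs)) {
    allele_freqs <- vc |>
      dplyr::filter(.data$gt != "missing") |>
      dplyr::group_by(.data$variant_id) |>
      dplyr::summarise(af = mean(c(hom_ref = 0, het = 1, hom_alt = 2)[.data$gt]) / 2,
                       .groups = "drop") |>
      (\(d) setNames(d$af, d$variant_id))()
  }
  q <- allele_freqs[sites$variant_id]
  poly <- !is.na(q) & q > 0 & q < 1
  sites <- sites[poly, ]; q <- q[poly]
  if (nrow(sites) == 0) {
    rlang::abort("no polymorphic sites available for IBD estimation")
  }
  if (nrow(sites) < min_sites) {
    rlang::warn(sprintf("only %d informative sites (requested >= %d)",
                        nrow(sites), min_sites))
  }
  gtw <- tidyr::pivot_wider(
    vc[vc$variant_id %in% sites$variant_id,
       c("variant_id", "subject_id", "gt")],
    names_from = "subject_id", values_from = "gt"
  )
  gtw <- gtw[match(sites$variant_id, gtw$variant_id), ]
  dose <- function(id) c(hom_ref = 0, het = 1, hom_alt = 2,
                         missing = NA_integer_)[gtw[[id]]]
  subjects <- setdiff(names(gtw), "variant_id")
  if (is.null(pairs)) {
    pairs <- as.data.frame(t(utils::combn(subjects, 2)),
                           stringsAsFactors = FALSE)
  }
  names(pairs) <- c("id1", "id2")
  p <- 1 - q  # reference-allele frequency
  # expected IBS-state probabilities per site given IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- 1 - e0_ibd0 - e1_ibd0
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- 1 - e1_ibd1
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- dose(pairs$id1[i]); g2 <- dose(pairs$id2[i])
    ok <- !is.na(g1) & !is.na(g2)
    if (!any(ok)) rlang::abort("no overlapping genotypes for a pair")
    ibs <- 2L - abs(g1[ok] - g2[ok])
    ibs[g1[ok] == 1 & g2[ok] == 1] <- 2L  # het/het is IBS 2
    n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
    E0_0 <- sum(e0_ibd0[ok]); E1_0 <- sum(e1_ibd0[ok]); E2_0 <- sum(e2_ibd0[ok])
    E1_1 <- sum(e1_ibd1[ok]); E2_1 <- sum(e2_ibd1[ok])
    z0 <- n0 / E0_0
    z1 <- (n1 - z0 * E1_0) / E1_1
    z2 <- (n2 - z0 * E2_0 - z1 * E2_1) / sum(ok)
    z <- simplex_project(c(z0, z1, z2))
    out[[i]] <- tibble::tibble(
      id1 = pairs$id1[i], id2 = pairs$id2[i], n_sites = sum(ok),
      Z0 = z[1], Z1 = z[2], Z2 = z[3], pi_hat = z[2] / 2 + z[3]
    )
  }
  dplyr::bind_rows(out)
}

# greedy pruning to a minimum pairwise distance within chromosome
prune_sites <- function(chrom, pos, min_bp) {
  keep <- logical(length(pos))
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    last <- -Inf
    for (i in ii) {
      if (pos[i] - last >= min_bp) {
        keep[i] <- TRUE
        last <- pos[i]
      }
    }
  }
  keep
}

# Euclidean projection of a length-3 vector onto the probability simplex
simplex_project <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}
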