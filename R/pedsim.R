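#' Configuration for the synthetic pedigree-exome generator
#'
#' Defaults describe the study design the analyses assume: multiplex
#' two-to-four-generation families ascertained for at least four affected
#' relatives, rare founder variants gene-dropped through each pedigree, about
#' one coding de novo event per offspring exome, very high mean read depth
#' (112-fold), and an age of onset optionally coupled to the brain-expressed
#' disruptive-variant burden.
#'
#' @param n_families Number of families, default 15.
#' @param pedigree_template `"three_generation"` or `"nuclear"`.
#' @param n_rare_sites Number of shared rare exonic sites, default 400.
#' @param rare_af_range Founder allele-frequency range for rare sites.
#' @param n_common_sites Number of common marker sites (used by deletion
#'   detection and identity-by-descent estimation), default 300.
#' @param common_af_range Allele-frequency range for common markers.
#' @param n_genes Number of genes in the synthetic feature table, default 1200.
#' @param n_pev_spikes Etiologic variants spiked per family, default 1.
#' @param pev_penetrance In `[0, 1]`; at 1 a spiked etiologic variant admits
#'   no unaffected carrier, below 1 it admits one.
#' @param pev_target_frac Probability that a spiked etiologic variant lands in
#'   the designated target gene set, default 0.8.
#' @param de_novo_rate Mean de novo events per trio offspring exome,
#'   default 0.97.
#' @param n_deletion_spikes Hemizygous deletions spiked study-wide, default 2.
#' @param deletion_marker_span Consecutive variant sites a spiked deletion
#'   covers, default 10.
#' @param depth_mean Mean read depth, default 112.
#' @param genotype_error_rate Probability a call is perturbed to an adjacent
#'   genotype state, default 0 (apply with [apply_noise()]).
#' @param onset_model `list(type = "independent")` or
#'   `list(type = "burden_coupled", beta0 = 45, beta1 = 1.5, sigma = 5)`:
#'   onset (years) is `beta0 - beta1 * burden + Normal(0, sigma)` truncated to
#'   the 15–50-year typical-onset window.
#' @param seed Integer seed; every stage derives its own stream from it.
#' @return A list of class `fv_sim_config`.
#' @export
sim_config <- function(n_families = 15,
                       pedigree_template = c("three_generation", "nuclear"),
                       n_rare_sites = 400,
                       rare_af_range = c(0.0005, 0.005),
                       n_common_sites = 300,
                       common_af_range = c(0.35, 0.5),
                       n_genes = 1200,
                       n_pev_spikes = 1,
                       pev_penetrance = 0.8,
                       pev_target_frac = 0.8,
                       de_novo_rate = 0.97,
                       n_deletion_spikes = 2,
                       deletion_marker_span = 10,
                       depth_mean = 112,
                       genotype_error_rate = 0,
                       onset_model = list(type = "burden_coupled",
                                          beta0 = 45, beta1 = 1.5, sigma = 5),
                       seed = 1) {
  pedigree_template <- match.arg(pedigree_template)
  stopifnot(
    n_families >= 1, n_rare_sites >= 0, n_common_sites >= 0,
    all(rare_af_range > 0), all(rare_af_range < 1),
    all(common_af_range > 0), all(common_af_range < 1),
    pev_penetrance >= 0, pev_penetrance <= 1,
    de_novo_rate >= 0, deletion_marker_span >= 1,
    genotype_error_rate >= 0, genotype_error_rate < 1,
    depth_mean > 0
  )
  structure(as.list(environment()), class = "fv_sim_config")
}

#' Simulate one multiplex pedigree
#'
#' The `three_generation` template builds a founder couple, four of their
#' children (three with married-in spouses), and two to three grandchildren
#' per couple — at least ten members. Descendant members are affected with
#' probability 0.45 (diagnoses BD-I 55%, BD-II 20%, SZMA 15%, RUD 10%);
#' married-in parents are unaffected. Families are rejection-sampled until at
#' least four sequenced members are affected under the strict scheme,
#' mirroring ascertainment for high density of illness. The `nuclear` template
#' is a founder couple with `n_offspring` children, no ascertainment
#' constraint. Affected members receive a provisional onset uniform in 15–50
#' years (see [assign_phenotypes()] for burden-coupled onsets).
#'
#' @param template `"three_generation"` or `"nuclear"`.
#' @param family_id Family identifier string.
#' @param seed Integer seed or `NULL`.
#' @param n_offspring Offspring count for the nuclear template, default 4.
#' @return A pedigree tibble (see [read_pedigree()]) with parents ordered
#'   before children.
#' @export
simulate_pedigree <- function(template = c("three_generation", "nuclear"),
                              family_id = "F1", seed = NULL, n_offspring = 4) {
  template <- match.arg(template)
  local_seed(seed)
  if (template == "nuclear") {
    ped <- new_ped_rows(
      family_id,
      id = c("p1", "p2", paste0("c", seq_len(n_offspring))),
      father_id = c(NA, NA, rep("p1", n_offspring)),
      mother_id = c(NA, NA, rep("p2", n_offspring)),
      sex = c("male", "female", sample(c("male", "female"), n_offspring,
                                       replace = TRUE))
    )
    ped <- assign_sim_phenotypes(ped)
    return(finish_ped(ped))
  }
  for (attempt in 1:200) {
    ids <- c("gf", "gm")
    father <- c(NA, NA); mother <- c(NA, NA)
    sex <- c("male", "female")
    n_children <- 4
    for (i in seq_len(n_children)) {
      cid <- paste0("c", i)
      csex <- sample(c("male", "female"), 1)
      ids <- c(ids, cid); father <- c(father, "gf"); mother <- c(mother, "gm")
      sex <- c(sex, csex)
      if (i <= 3) {
        sid <- paste0("s", i)
        ids <- c(ids, sid); father <- c(father, NA); mother <- c(mother, NA)
        sex <- c(sex, if (csex == "male") "female" else "male")
        for (j in seq_len(sample(2:3, 1))) {
          gid <- paste0("g", i, j)
          ids <- c(ids, gid)
          father <- c(father, if (csex == "male") cid else sid)
          mother <- c(mother, if (csex == "male") sid else cid)
          sex <- c(sex, sample(c("male", "female"), 1))
        }
      }
    }
    ped <- new_ped_rows(family_id, ids, father, mother, sex)
    ped <- assign_sim_phenotypes(ped)
    n_strict <- sum(ped$phenotype %in% affection_scheme("strict")$affected)
    if (n_strict >= 4) return(finish_ped(ped))
  }
  rlang::abort("could not satisfy >=4 affected after 200 attempts")
}

new_ped_rows <- function(family_id, id, father_id, mother_id, sex) {
  tibble::tibble(
    family_id = family_id, id = paste(family_id, id, sep = "_"),
    father_id = ifelse(is.na(father_id), NA,
                       paste(family_id, father_id, sep = "_")),
    mother_id = ifelse(is.na(mother_id), NA,
                       paste(family_id, mother_id, sep = "_")),
    sex = sex,
    phenotype = "unknown", age_of_onset = NA_real_, sequenced = TRUE
  )
}

assign_sim_phenotypes <- function(ped) {
  married <- married_in_flag(ped)
  for (i in seq_len(nrow(ped))) {
    if (married[i]) {
      ped$phenotype[i] <- "unaffected"
    } else if (runif(1) < 0.45) {
      ped$phenotype[i] <- sample(c("BD1", "BD2", "SZMA", "RUD"), 1,
                                 prob = c(0.55, 0.2, 0.15, 0.1))
      ped$age_of_onset[i] <- round(runif(1, 15, 50), 1)
    } else {
      ped$phenotype[i] <- sample(c("unaffected", "unknown"), 1,
                                 prob = c(0.9, 0.1))
    }
  }
  ped
}

finish_ped <- function(ped) {
  ped$married_in <- married_in_flag(ped)
  validate_pedigree(ped)
  ped
}

#' Gene-drop founder alleles through a pedigree
#'
#' Founder haplotypes are drawn independently as Bernoulli(`af`) per site;
#' each transmission passes one parental haplotype chosen uniformly and
#' independently per site (no linkage outside spiked deletion intervals).
#' Phase is recorded exactly. Allele frequencies must lie in `[0, 1)`; at 0
#' every call is homozygous reference.
#'
#' @param ped Pedigree tibble for one family.
#' @param sites Site table with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `af` (founder allele frequency) and any annotation columns.
#' @param seed Integer seed or `NULL`.
#' @return A simulation state (`fv_sim_state`): the pedigree, site table,
#'   true haplotypes, hemizygosity masks, de novo overlay and accumulated
#'   ground truth. Materialise calls with [as_variant_calls()] and phase with
#'   [true_phase()].
#' @export
gene_drop <- function(ped, sites, seed = NULL) {
  if (any(sites$af < 0 | sites$af >= 1)) {
    rlang::abort("founder allele frequencies must lie in [0, 1)")
  }
  local_seed(seed)
  ped <- ped[pedigree_order(ped), ]
  n <- nrow(ped); m <- nrow(sites)
  H_pat <- matrix(0L, n, m, dimnames = list(ped$id, sites$variant_id))
  H_mat <- H_pat
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      H_pat[i, ] <- rbinom(m, 1, sites$af)
    } else {
      pick <- runif(m) < 0.5
      H_pat[i, ] <- ifelse(pick, H_pat[fa[i], ], H_mat[fa[i], ])
    }
    if (is.na(mo[i])) {
      H_mat[i, ] <- rbinom(m, 1, sites$af)
    } else {
      pick <- runif(m) < 0.5
      H_mat[i, ] <- ifelse(pick, H_pat[mo[i], ], H_mat[mo[i], ])
    }
  }
  structure(list(
    ped = ped, sites = sites, H_pat = H_pat, H_mat = H_mat,
    hemi_pat = matrix(FALSE, n, m, dimnames = dimnames(H_pat)),
    hemi_mat = matrix(FALSE, n, m, dimnames = dimnames(H_pat)),
    overlay = tibble::tibble(id = character(), variant_id = character()),
    truth = list(
      pev_sites = tibble::tibble(family_id = character(),
                                 variant_id = character(),
                                 carrier_ids = list()),
      denovo_events = tibble::tibble(family_id = character(),
                                     subject_id = character(),
                                     variant_id = character()),
      deletions = tibble::tibble(family_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 variant_ids = list(), carrier_ids = list())
    )
  ), class = "fv_sim_state")
}

# append one new site to a state; alleles given as founder haplotype settings
add_site <- function(state, site_row, pat = NULL, mat = NULL) {
  n <- nrow(state$ped)
  state$sites <- dplyr::bind_rows(state$sites, site_row)
  zero <- matrix(0L, n, 1, dimnames = list(state$ped$id, site_row$variant_id))
  state$H_pat <- cbind(state$H_pat, if (is.null(pat)) zero else pat)
  state$H_mat <- cbind(state$H_mat, if (is.null(mat)) zero else mat)
  state$hemi_pat <- cbind(state$hemi_pat, matrix(FALSE, n, 1,
    dimnames = list(state$ped$id, site_row$variant_id)))
  state$hemi_mat <- cbind(state$hemi_mat, matrix(FALSE, n, 1,
    dimnames = list(state$ped$id, site_row$variant_id)))
  state
}

# ids of all descendants of one individual
descendant_ids <- function(ped, id) {
  out <- character(0)
  frontier <- id
  while (length(frontier) > 0) {
    kids <- ped$id[ped$father_id %in% frontier | ped$mother_id %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# drop a single founder allele through the pedigree; returns 0/1 matrices
drop_single_allele <- function(ped, founder_row, side = c("pat", "mat")) {
  side <- match.arg(side)
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  pat <- integer(n); mat <- integer(n)
  if (side == "pat") pat[founder_row] <- 1L else mat[founder_row] <- 1L
  for (i in seq_len(n)) {
    if (!is.na(fa[i])) {
      pat[i] <- if (runif(1) < 0.5) pat[fa[i]] else mat[fa[i]]
    } else if (i != founder_row || side != "pat") {
      if (i != founder_row) pat[i] <- 0L
    }
    if (!is.na(mo[i])) {
      mat[i] <- if (runif(1) < 0.5) pat[mo[i]] else mat[mo[i]]
    } else if (i != founder_row) {
      mat[i] <- 0L
    }
  }
  list(pat = pat, mat = mat)
}

#' Spike a potentially etiologic founder variant into a family
#'
#' Inserts a new rare, predicted-pathogenic founder variant and resamples its
#' transmission until the carrier set contains at least three affected and at
#' most one unaffected sequenced member (no unaffected carrier when
#' `penetrance` is 1), guaranteeing that the sharing classifier has true
#' positives to find. Fails after bounded retries when the pedigree cannot
#' satisfy the constraint.
#'
#' @param state Simulation state from [gene_drop()].
#' @param penetrance In `[0, 1]`; see above.
#' @param gene Gene symbol for the spiked variant.
#' @param scheme Affection scheme used for the carrier constraint.
#' @param consequence Consequence class; the default missense is paired with
#'   maximally damaging PolyPhen-2/SIFT scores so the variant passes the
#'   pathogenicity filter.
#' @param pos Coordinate for the spiked site; default derives from the
#'   current site count.
#' @param seed Integer seed or `NULL`.
#' @param max_retries Bound on transmission resampling, default 500.
#' @return Updated state; the spiked site is recorded in
#'   `state$truth$pev_sites`.
#' @export
spike_pev <- function(state, penetrance = 1, gene = "GENE1",
                      scheme = affection_scheme("strict"),
                      consequence = "missense", pos = NULL, seed = NULL,
                      max_retries = 2000) {
  local_seed(seed)
  ped <- state$ped
  status <- affection_status(ped$phenotype, scheme)
  affected <- ped$id[ped$sequenced & !is.na(status) & status == "affected"]
  unaffected <- ped$id[ped$sequenced & !is.na(status) & status == "unaffected"]
  if (length(affected) < 3) {
    rlang::abort("spike_pev() needs >= 3 affected sequenced members")
  }
  max_unaff <- if (penetrance >= 1) 0L else 1L
  founders <- which(is.na(ped$father_id) & is.na(ped$mother_id))
  # only founders whose descendant closure holds enough affected members
  n_aff_desc <- vapply(founders, function(f) {
    desc <- descendant_ids(ped, ped$id[f])
    sum(c(ped$id[f], desc) %in% affected)
  }, integer(1))
  founders <- founders[n_aff_desc >= 3]
  if (length(founders) == 0) {
    rlang::abort("no founder has >= 3 affected descendants")
  }
  for (r in seq_len(max_retries)) {
    f <- if (length(founders) == 1) founders else sample(founders, 1)
    side <- sample(c("pat", "mat"), 1)
    drop <- drop_single_allele(ped, f, side)
    carrier <- (drop$pat + drop$mat) > 0
    ids <- ped$id[carrier]
    if (sum(ids %in% affected) >= 3 && sum(ids %in% unaffected) <= max_unaff) {
      at <- if (is.null(pos)) 5000000L + nrow(state$sites) else as.integer(pos)
      vid <- sprintf("chr20:%d:G:A", at)
      site <- tibble::tibble(
        variant_id = vid, chrom = "chr20", pos = at,
        ref = "G", alt = "A", gene = gene, consequence = consequence,
        polyphen2 = if (consequence == "missense") 1.0 else NA_real_,
        sift = if (consequence == "missense") 0.0 else NA_real_,
        af = 0, af_evs = NA_real_, af_kg = NA_real_, kind = "pev_spike"
      )
      state <- add_site(state, site,
                        pat = matrix(drop$pat, ncol = 1,
                                     dimnames = list(ped$id, vid)),
                        mat = matrix(drop$mat, ncol = 1,
                                     dimnames = list(ped$id, vid)))
      state$truth$pev_sites <- dplyr::bind_rows(
        state$truth$pev_sites,
        tibble::tibble(family_id = ped$family_id[1], variant_id = vid,
                       carrier_ids = list(ids))
      )
      return(state)
    }
  }
  rlang::abort(sprintf("spike_pev(): constraint unsatisfied after %d retries",
                       max_retries))
}

#' Spike de novo variants into trio offspring
#'
#' Every offspring whose two parents are in the pedigree and sequenced
#' receives `Poisson(rate)` new heterozygous sites at which all other members
#' (both parents in particular) are homozygous reference. Spiked events are
#' not transmitted onward, so each produces exactly one Mendelian-error
#' signature.
#'
#' @param state Simulation state.
#' @param rate Mean events per offspring exome.
#' @param pos_base Base coordinate for spiked sites (events are placed at
#'   consecutive positions above it); default 8000000.
#' @param seed Integer seed or `NULL`.
#' @return Updated state; events recorded in `state$truth$denovo_events`.
#' @export
spike_de_novo <- function(state, rate = 0.97, pos_base = NULL, seed = NULL) {
  local_seed(seed)
  ped <- state$ped
  seqd <- ped$id[ped$sequenced]
  offspring <- ped$id[!is.na(ped$father_id) & !is.na(ped$mother_id) &
                        ped$sequenced &
                        ped$father_id %in% seqd & ped$mother_id %in% seqd]
  if (is.null(pos_base)) pos_base <- 8000000L
  counter <- 0L
  for (o in offspring) {
    k <- rpois(1, rate)
    if (k == 0) next
    for (j in seq_len(k)) {
      counter <- counter + 1L
      pos <- as.integer(pos_base) + counter
      vid <- sprintf("chr21:%d:C:T", pos)
      site <- tibble::tibble(
        variant_id = vid, chrom = "chr21", pos = pos, ref = "C", alt = "T",
        gene = sample(unique(state$sites$gene), 1),
        consequence = sample(c("missense", "synonymous", "nonsense"), 1,
                             prob = c(0.7, 0.2, 0.1)),
        polyphen2 = NA_real_, sift = NA_real_,
        af = 0, af_evs = NA_real_, af_kg = NA_real_, kind = "denovo_spike"
      )
      state <- add_site(state, site)
      state$overlay <- dplyr::bind_rows(
        state$overlay, tibble::tibble(id = o, variant_id = vid)
      )
      state$truth$denovo_events <- dplyr::bind_rows(
        state$truth$denovo_events,
        tibble::tibble(family_id = ped$family_id[1], subject_id = o,
                       variant_id = vid)
      )
    }
  }
  state
}

#' Spike a hemizygous deletion over consecutive variant sites
#'
#' Chooses an interval of `span` consecutive sites on one chromosome and a
#' founder haplotype, re-drops the interval through the pedigree as a fully
#' linked block while tracking descent, and marks the chosen founder
#' haplotype as deleted. Carriers of the deleted haplotype are hemizygous
#' across the interval: their calls are re-emitted as homozygous for the
#' surviving allele, which creates Mendelian inconsistencies wherever the
#' surviving allele conflicts with naive diploid expectation. Transmission is
#' resampled until at least one carrier is an offspring with both parents in
#' the pedigree (otherwise no inconsistency can surface).
#'
#' @param state Simulation state.
#' @param span Number of consecutive sites the deletion covers.
#' @param chrom Chromosome to place the deletion on; default any chromosome
#'   with an eligible window.
#' @param site_pool `"common"` (default when the site table has a `kind`
#'   column) restricts the window to runs of consecutive common marker sites,
#'   where carrier hemizygosity is detectable; `"any"` allows any window.
#' @param seed Integer seed or `NULL`.
#' @param max_retries Bound on transmission resampling, default 200.
#' @return Updated state; the interval and carrier set are recorded in
#'   `state$truth$deletions`.
#' @export
spike_deletion <- function(state, span = 10, chrom = NULL,
                           site_pool = NULL, seed = NULL,
                           max_retries = 200) {
  stopifnot(span >= 1)
  local_seed(seed)
  ped <- state$ped
  n <- nrow(ped)
  if (is.null(site_pool)) {
    site_pool <- if ("kind" %in% names(state$sites)) "common" else "any"
  }
  site_ord <- order(state$sites$chrom, state$sites$pos)
  if (site_pool == "common") {
    # maximal runs of consecutive common marker sites per chromosome
    is_common <- state$sites$kind[site_ord] == "common"
    grp <- paste(state$sites$chrom[site_ord],
                 cumsum(c(1L, as.integer(diff(is_common) != 0))))
    by_chrom <- split(site_ord, grp)
    by_chrom <- by_chrom[vapply(by_chrom, function(ii) {
      all(state$sites$kind[ii] == "common")
    }, logical(1))]
    names(by_chrom) <- vapply(by_chrom, function(ii) {
      state$sites$chrom[ii[1]]
    }, character(1))
  } else {
    by_chrom <- split(site_ord, state$sites$chrom[site_ord])
  }
  by_chrom <- by_chrom[lengths(by_chrom) >= span]
  if (!is.null(chrom)) by_chrom <- by_chrom[names(by_chrom) %in% chrom]
  if (length(by_chrom) == 0) {
    rlang::abort(sprintf("no chromosome has %d consecutive eligible sites",
                         span))
  }
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  founders <- which(is.na(fa) & is.na(mo))
  for (r in seq_len(max_retries)) {
    csites <- by_chrom[[sample(length(by_chrom), 1)]]
    start <- sample(length(csites) - span + 1, 1)
    win <- csites[start:(start + span - 1)]
    f <- sample(founders, 1)
    target_side <- sample(c("pat", "mat"), 1)
    # linked re-drop of the window with lineage labels
    lin_pat <- character(n); lin_mat <- character(n)
    Hp <- state$H_pat; Hm <- state$H_mat
    for (i in seq_len(n)) {
      if (is.na(fa[i])) {
        lin_pat[i] <- paste0(ped$id[i], ":pat")
      } else {
        if (runif(1) < 0.5) {
          Hp[i, win] <- Hp[fa[i], win]; lin_pat[i] <- lin_pat[fa[i]]
        } else {
          Hp[i, win] <- Hm[fa[i], win]; lin_pat[i] <- lin_mat[fa[i]]
        }
      }
      if (is.na(mo[i])) {
        lin_mat[i] <- paste0(ped$id[i], ":mat")
      } else {
        if (runif(1) < 0.5) {
          Hm[i, win] <- Hp[mo[i], win]; lin_mat[i] <- lin_pat[mo[i]]
        } else {
          Hm[i, win] <- Hm[mo[i], win]; lin_mat[i] <- lin_mat[mo[i]]
        }
      }
    }
    target <- paste0(ped$id[f], ":", target_side)
    carrier_pat <- lin_pat == target
    carrier_mat <- lin_mat == target
    carriers <- carrier_pat | carrier_mat
    informative <- carriers & !is.na(fa) & !is.na(mo)
    if (!any(informative)) next
    state$H_pat <- Hp; state$H_mat <- Hm
    state$hemi_pat[, win] <- state$hemi_pat[, win] | carrier_pat
    state$hemi_mat[, win] <- state$hemi_mat[, win] | carrier_mat
    state$truth$deletions <- dplyr::bind_rows(
      state$truth$deletions,
      tibble::tibble(
        family_id = ped$family_id[1],
        chrom = state$sites$chrom[win[1]],
        start = as.integer(state$sites$pos[win[1]]),
        end = as.integer(state$sites$pos[win[span]]),
        variant_ids = list(state$sites$variant_id[win]),
        carrier_ids = list(ped$id[carriers])
      )
    )
    return(state)
  }
  rlang::abort(sprintf(
    "spike_deletion(): no informative transmission after %d retries",
    max_retries))
}

#' Materialise tidy variant calls from a simulation state
#'
#' Genotypes derive from the true haplotypes; hemizygous (deleted) calls are
#' emitted as homozygous for the surviving allele; de novo overlay events are
#' emitted heterozygous. Clean calls carry constant depth `depth_mean` with
#' allele depths split by dosage — add sampling noise with [apply_noise()].
#'
#' @param state Simulation state.
#' @param depth_mean Constant emitted depth, default 112.
#' @return A tidy variant-call table (see [read_variants()]), rows ordered by
#'   site then subject.
#' @export
as_variant_calls <- function(state, depth_mean = 112) {
  ped <- state$ped; sites <- state$sites
  n <- nrow(ped); m <- nrow(sites)
  dose <- state$H_pat + state$H_mat
  # hemizygous: survive on the non-deleted haplotype
  surv <- ifelse(state$hemi_pat, state$H_mat,
                 ifelse(state$hemi_mat, state$H_pat, NA))
  hemi <- state$hemi_pat | state$hemi_mat
  dose[hemi] <- 2L * surv[hemi]
  if (nrow(state$overlay) > 0) {
    oi <- cbind(match(state$overlay$id, ped$id),
                match(state$overlay$variant_id, sites$variant_id))
    dose[oi] <- 1L
  }
  dp <- as.integer(round(depth_mean))
  gt_levels <- c("hom_ref", "het", "hom_alt")
  site_idx <- rep(seq_len(m), each = n)
  site_cols <- intersect(
    c("variant_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
      "polyphen2", "sift", grep("^af_", names(sites), value = TRUE)),
    names(sites)
  )
  vc <- tibble::as_tibble(lapply(sites[, site_cols], function(col) col[site_idx]))
  for (col in setdiff(c("gene", "consequence", "polyphen2", "sift"), names(vc))) {
    vc[[col]] <- if (col %in% c("polyphen2", "sift")) NA_real_ else NA_character_
  }
  vc$subject_id <- rep(ped$id, m)
  vc$gt <- gt_levels[as.vector(dose) + 1L]
  vc$ad_alt <- as.integer(round(dp * as.vector(dose) / 2))
  vc$dp <- dp
  vc$ad_ref <- dp - vc$ad_alt
  dplyr::relocate(vc, "ad_ref", .before = "ad_alt")
}

#' True phase of a simulation state
#'
#' @param state Simulation state.
#' @return Tibble with `subject_id`, `variant_id`, `paternal_allele`,
#'   `maternal_allele` (`"ref"`/`"alt"`, `NA` for a deleted haplotype).
#' @export
true_phase <- function(state) {
  ped <- state$ped; sites <- state$sites
  n <- nrow(ped); m <- nrow(sites)
  allele <- function(H, hemi) {
    out <- c("ref", "alt")[as.vector(H) + 1L]
    out[as.vector(hemi)] <- NA_character_
    out
  }
  tibble::tibble(
    subject_id = rep(ped$id, m),
    variant_id = rep(sites$variant_id, each = n),
    paternal_allele = allele(state$H_pat, state$hemi_pat),
    maternal_allele = allele(state$H_mat, state$hemi_mat)
  )
}

#' Overlay sequencing noise on a variant-call table
#'
#' Re-draws per-call depth as Poisson(`depth_mean`), perturbs each genotype
#' with probability `error_rate` to an adjacent state (`hom_ref` ↔ `het` ↔
#' `hom_alt`), and splits allele depths binomially given the emitted genotype
#' (alternate-read probability `read_error`, 0.5, `1 - read_error` for the
#' three states).
#'
#' @param vc Variant-call table.
#' @param error_rate Genotype perturbation probability in `[0, 1)`.
#' @param depth_mean Mean of the Poisson depth distribution.
#' @param read_error Per-read miscall probability, default 0.001.
#' @param seed Integer seed or `NULL`.
#' @return `vc` with `gt`, `ad_ref`, `ad_alt`, `dp` replaced by noisy values.
#' @export
apply_noise <- function(vc, error_rate = 0, depth_mean = 112,
                        read_error = 0.001, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1)
  local_seed(seed)
  n <- nrow(vc)
  gt <- vc$gt
  flip <- runif(n) < error_rate & gt != "missing"
  up <- runif(n) < 0.5
  gt[flip & gt == "hom_ref"] <- "het"
  gt[flip & gt == "hom_alt"] <- "het"
  gt[flip & vc$gt == "het"] <- ifelse(up[flip & vc$gt == "het"],
                                      "hom_alt", "hom_ref")
  dp <- rpois(n, depth_mean)
  p_alt <- c(hom_ref = read_error, het = 0.5, hom_alt = 1 - read_error,
             missing = 0)[gt]
  ad_alt <- rbinom(n, dp, p_alt)
  vc$gt <- gt
  vc$dp <- as.integer(dp)
  vc$ad_alt <- as.integer(ad_alt)
  vc$ad_ref <- as.integer(dp - ad_alt)
  vc
}

#' Assign ages of onset (optionally burden-coupled)
#'
#' Under the `burden_coupled` model each affected member's onset is
#' `beta0 - beta1 * burden + Normal(0, sigma)` years, truncated to the
#' 15–50-year typical-onset window; under `independent` onsets are uniform in
#' the window. Unaffected and unknown members keep a missing onset.
#'
#' @param ped Pedigree tibble.
#' @param onset_model See [sim_config()].
#' @param burden Named numeric vector of per-subject burdens (names = subject
#'   ids); required for `burden_coupled`.
#' @param scheme Members affected under this scheme receive an onset
#'   (default broad).
#' @param seed Integer seed or `NULL`.
#' @return `ped` with `age_of_onset` updated.
#' @export
assign_phenotypes <- function(ped, onset_model = list(type = "independent"),
                              burden = NULL,
                              scheme = affection_scheme("broad"),
                              seed = NULL) {
  local_seed(seed)
  affected <- !is.na(affection_status(ped$phenotype, scheme)) &
    affection_status(ped$phenotype, scheme) == "affected"
  k <- sum(affected)
  if (onset_model$type == "independent") {
    onset <- runif(k, 15, 50)
  } else if (onset_model$type == "burden_coupled") {
    if (is.null(onset_model$sigma) || onset_model$sigma <= 0) {
      rlang::abort("burden_coupled onset model requires sigma > 0")
    }
    if (is.null(burden)) {
      rlang::abort("burden_coupled onset model requires per-subject burdens")
    }
    b <- burden[ped$id[affected]]
    b[is.na(b)] <- 0
    onset <- onset_model$beta0 - onset_model$beta1 * b +
      rnorm(k, 0, onset_model$sigma)
    onset <- pmin(pmax(onset, 15), 50)
  } else {
    rlang::abort("unknown onset model type")
  }
  ped$age_of_onset[affected] <- round(onset, 1)
  ped$age_of_onset[!affected] <- NA_real_
  ped
}
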