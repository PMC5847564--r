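#' Simulate a complete multi-family exome study
#'
#' Generates the full set of inputs the analysis pipeline consumes: a
#' synthetic gene feature table, gene sets (including a designated target set
#' that spiked etiologic variants preferentially fall in), a shared site map
#' mixing rare exonic variants with common markers, per-family gene drops,
#' spiked etiologic variants, de novo events and hemizygous deletions, noise,
#' and burden-coupled ages of onset. All randomness derives deterministically
#' from `config$seed`.
#'
#' @param config See [sim_config()].
#' @return A list of class `fv_study` with elements `pedigree` (all
#'   families), `variant_calls` (tidy multi-sample call table), `features`,
#'   `gene_sets`, `truth` (spiked etiologic sites, de novo events, deletions,
#'   per-family simulation states) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  local_seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  features <- simulate_gene_features(genes)
  gene_sets <- simulate_gene_sets(genes)
  target_genes <- gene_sets$genes[[match("PSD", gene_sets$name)]]
  sites <- simulate_site_map(config, genes)

  fam_seeds <- sample.int(2^30, config$n_families * 4)
  fams <- vector("list", config$n_families)
  truth <- list(pev_sites = NULL, denovo_events = NULL, deletions = NULL)
  states <- vector("list", config$n_families)

  for (f in seq_len(config$n_families)) {
    fid <- sprintf("PED%02d", f)
    sd <- fam_seeds[(f - 1) * 4 + 1:4]
    # a drawn pedigree may admit no transmission satisfying the spike
    # constraints; redraw the family in that case
    for (attempt in 0:9) {
      ped_f <- simulate_pedigree(config$pedigree_template, family_id = fid,
                                 seed = sd[1] + attempt)
      state <- gene_drop(ped_f, sites, seed = sd[2] + attempt)
      state <- tryCatch(
        withr::with_seed(sd[3] + attempt, {
          for (k in seq_len(config$n_pev_spikes)) {
            g <- if (runif(1) < config$pev_target_frac) {
              sample(target_genes, 1)
            } else {
              sample(genes, 1)
            }
            csq <- sample(c("missense", "nonsense"), 1, prob = c(0.7, 0.3))
            state <- spike_pev(state, penetrance = config$pev_penetrance,
                               gene = g, consequence = csq,
                               pos = 5000000L + f * 1000L + k)
          }
          if (f <= config$n_deletion_spikes) {
            state <- spike_deletion(state, span = config$deletion_marker_span)
          }
          state
        }),
        error = function(e) NULL
      )
      if (!is.null(state)) break
    }
    if (is.null(state)) {
      rlang::abort(sprintf("family %s: could not place spikes in 10 attempts",
                           fid))
    }
    state <- spike_de_novo(state, rate = config$de_novo_rate,
                           pos_base = 8000000L + f * 100000L, seed = sd[4])
    states[[f]] <- state
    fams[[f]] <- ped_f
  }

  # union of sites: base map plus every family's spiked sites
  spiked <- dplyr::bind_rows(lapply(states, function(s) {
    s$sites[!s$sites$variant_id %in% sites$variant_id, ]
  }))
  all_sites <- dplyr::bind_rows(sites, spiked)

  vcs <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    vc_f <- as_variant_calls(states[[f]], depth_mean = config$depth_mean)
    foreign <- all_sites[!all_sites$variant_id %in% states[[f]]$sites$variant_id, ]
    if (nrow(foreign) > 0) {
      n_mem <- nrow(states[[f]]$ped)
      idx <- rep(seq_len(nrow(foreign)), each = n_mem)
      dp <- as.integer(round(config$depth_mean))
      extra <- tibble::as_tibble(lapply(
        foreign[, intersect(names(vc_f), names(foreign))],
        function(col) col[idx]
      ))
      extra$subject_id <- rep(states[[f]]$ped$id, nrow(foreign))
      extra$gt <- "hom_ref"
      extra$ad_ref <- dp
      extra$ad_alt <- 0L
      extra$dp <- dp
      vc_f <- dplyr::bind_rows(vc_f, extra[, names(vc_f)])
    }
    vcs[[f]] <- vc_f
  }
  vc <- dplyr::bind_rows(vcs)
  vc <- vc[order(vc$chrom, vc$pos, vc$alt, vc$subject_id), ]

  noise_seed <- sample.int(2^30, 1)
  vc <- apply_noise(vc, error_rate = config$genotype_error_rate,
                    depth_mean = config$depth_mean, seed = noise_seed)

  ped <- dplyr::bind_rows(fams)
  if (identical(config$onset_model$type, "burden_coupled")) {
    ann <- annotate_variants(vc, features)
    prof <- burden_per_subject(ann, ped)
    ped <- assign_phenotypes(
      ped, config$onset_model,
      burden = setNames(prof$n_lgd_brain, prof$subject_id),
      seed = sample.int(2^30, 1)
    )
  } else {
    ped <- assign_phenotypes(ped, config$onset_model,
                             seed = sample.int(2^30, 1))
  }

  truth <- list(
    pev_sites = dplyr::bind_rows(lapply(states, function(s) s$truth$pev_sites)),
    denovo_events = dplyr::bind_rows(lapply(states, function(s) s$truth$denovo_events)),
    deletions = dplyr::bind_rows(lapply(states, function(s) s$truth$deletions)),
    states = states
  )
  structure(list(pedigree = ped, variant_calls = vc, features = features,
                 gene_sets = gene_sets, truth = truth, config = config,
                 target_set = "PSD"),
            class = "fv_study")
}

simulate_gene_features <- function(genes) {
  n <- length(genes)
  lowcov <- runif(n) < 0.08
  coverage <- ifelse(lowcov, runif(n, 0, 10),
                     pmax(10.5, rnorm(n, 112, 30)))
  expressed <- runif(n) < 0.6
  rpkm <- ifelse(expressed, stats::rlnorm(n, log(8), 1), runif(n, 0, 1))
  tibble::tibble(
    gene = genes,
    cds_length = pmax(150, round(stats::rlnorm(n, log(1500), 0.7))),
    missense_z = round(rnorm(n, 0, 2), 3),
    mean_coverage = round(coverage, 1),
    brain_rpkm = round(rpkm, 3)
  )
}

simulate_gene_sets <- function(genes) {
  sizes <- c(PSD = 150, FMRP_targets = 84, DeNovo_PSY = 160, NMDAR = 12,
             ARC = 8, Mitochondrial = 110)
  tibble::tibble(
    name = names(sizes),
    description = paste("synthetic gene set", names(sizes)),
    genes = unname(lapply(sizes, function(k) sample(genes, k))),
    n_genes = as.integer(sizes)
  )
}

simulate_site_map <- function(config, genes) {
  # common markers sit in one contiguous block per chromosome (emulating the
  # clustered high-heterozygosity panels used for segregation inference),
  # followed by the rare exonic sites
  n_chrom <- max(1L, min(19L, config$n_common_sites %/% 20L))
  m <- config$n_rare_sites + config$n_common_sites
  chrom_common <- paste0("chr", rep_len(seq_len(n_chrom), config$n_common_sites))
  chrom_rare <- paste0("chr", rep_len(seq_len(n_chrom), config$n_rare_sites))
  chrom <- c(sort(chrom_common), sort(chrom_rare))
  kind <- c(rep("common", config$n_common_sites),
            rep("rare", config$n_rare_sites))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    ic <- which(chrom == ch & kind == "common")
    ir <- which(chrom == ch & kind == "rare")
    pos[ic] <- cumsum(round(runif(length(ic), 30000, 170000)))
    offset <- if (length(ic) > 0) max(pos[ic]) else 0
    pos[ir] <- offset + 500000 + cumsum(round(runif(length(ir), 30000, 170000)))
  }
  af <- ifelse(kind == "rare",
               runif(m, config$rare_af_range[1], config$rare_af_range[2]),
               runif(m, config$common_af_range[1], config$common_af_range[2]))
  consequence <- ifelse(
    kind == "rare",
    sample(c("missense", "synonymous", "nonsense", "frameshift_indel",
             "canonical_splice", "start_lost", "other"), m, replace = TRUE,
           prob = c(0.66, 0.15, 0.045, 0.045, 0.03, 0.01, 0.06)),
    sample(c("synonymous", "other", "missense"), m, replace = TRUE,
           prob = c(0.5, 0.3, 0.2))
  )
  is_mis <- consequence == "missense"
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  sites <- tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = sample(genes, m, replace = TRUE),
    consequence = consequence,
    polyphen2 = ifelse(is_mis, round(runif(m), 3), NA_real_),
    sift = ifelse(is_mis, round(runif(m), 3), NA_real_),
    af = af,
    af_evs = round(af, 5),
    af_kg = round(af, 5),
    kind = kind
  )
  sites$variant_id <- paste(sites$chrom, sites$pos, sites$ref, sites$alt,
                            sep = ":")
  sites <- sites[order(sites$chrom, sites$pos), ]
  dplyr::relocate(sites, "variant_id")
}

#' Write a simulated study to disk in the formats the readers consume
#'
#' Emits `calls.vcf`, `pedigree.ped`, `gene_features.tsv`, `gene_sets.gmt`
#' and `truth.json` under `dir`. Output is deterministic for a fixed study
#' object.
#'
#' @param study Study list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "calls.vcf"),
    ped = file.path(dir, "pedigree.ped"),
    features = file.path(dir, "gene_features.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(study$variant_calls, paths["vcf"])
  write_pedigree(study$pedigree, paths["ped"])
  write_gene_features(study$features, paths["features"])
  write_gene_sets(study$gene_sets, paths["gmt"])
  truth <- list(
    pev_sites = study$truth$pev_sites,
    denovo_events = study$truth$denovo_events,
    deletions = study$truth$deletions
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
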