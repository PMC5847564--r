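#' Configuration for an end-to-end analysis run
#'
#' Collects input paths, analysis parameters and per-stage seeds. Every
#' random stage has its own explicit seed derived deterministically from
#' `seed`, so stages can be re-run independently and the whole run is
#' byte-reproducible.
#'
#' @param vcf,ped,features,gmt Input file paths (VCF calls, pedigree, gene
#'   feature TSV, gene sets GMT).
#' @param out_dir Output directory.
#' @param scheme_name Affection scheme for the sharing stage, `"strict"` or
#'   `"broad"`.
#' @param thresholds See [annotation_thresholds()].
#' @param rule See [sharing_rule()].
#' @param n_draws Null draws for the enrichment stage.
#' @param match_covariates Covariates for null matching.
#' @param onset_window Typical-onset window for the burden stage.
#' @param depth_min,min_alt_reads,max_parent_alt_reads De novo gates.
#' @param min_run,max_gap_bp Deletion-run detection parameters.
#' @param ibd_min_sites,ibd_prune_bp Identity-by-descent parameters.
#' @param seed Master seed for the per-stage seeds.
#' @return A list of class `fv_run_config`.
#' @export
run_config <- function(vcf, ped, features, gmt, out_dir,
                       scheme_name = "strict",
                       thresholds = annotation_thresholds(),
                       rule = sharing_rule(),
                       n_draws = 2000,
                       match_covariates = c("cds_length", "missense_z"),
                       onset_window = c(15, 50),
                       depth_min = 20, min_alt_reads = 5,
                       max_parent_alt_reads = 1,
                       min_run = 3, max_gap_bp = 1e6,
                       ibd_min_sites = 100, ibd_prune_bp = 1e5,
                       seed = 1) {
  seeds <- withr::with_seed(as.integer(seed),
                            setNames(sample.int(2^30, 2),
                                     c("enrichment_pev", "enrichment_lnv")))
  structure(
    list(vcf = vcf, ped = ped, features = features, gmt = gmt,
         out_dir = out_dir, scheme_name = scheme_name,
         thresholds = thresholds, rule = rule, n_draws = n_draws,
         match_covariates = match_covariates, onset_window = onset_window,
         depth_min = depth_min, min_alt_reads = min_alt_reads,
         max_parent_alt_reads = max_parent_alt_reads,
         min_run = min_run, max_gap_bp = max_gap_bp,
         ibd_min_sites = ibd_min_sites, ibd_prune_bp = ibd_prune_bp,
         seed = seed, seeds = as.list(seeds)),
    class = "fv_run_config"
  )
}

#' Cross-check the inputs of a run for consistency
#'
#' Verifies that every VCF subject appears in the pedigree (fatal otherwise),
#' and reports — without mutating anything — genes in the VCF missing from
#' the feature table and pedigree phenotypes excluded from both sides of the
#' affection scheme.
#'
#' @param vc Variant-call table.
#' @param ped Pedigree tibble.
#' @param features Gene feature table.
#' @param scheme Affection scheme.
#' @return Tibble of issues (`severity`, `message`); empty for clean inputs.
#'   Subject-id mismatch raises an error.
#' @export
validate_inputs <- function(vc, ped, features,
                            scheme = affection_scheme("strict")) {
  issues <- list()
  missing_subjects <- setdiff(unique(vc$subject_id), ped$id)
  if (length(missing_subjects) > 0) {
    rlang::abort(sprintf("VCF subject(s) absent from pedigree: %s",
                         paste(missing_subjects, collapse = ", ")))
  }
  vcf_genes <- setdiff(unique(vc$gene), NA)
  miss_feat <- setdiff(vcf_genes, features$gene)
  if (length(miss_feat) > 0) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      severity = "warning",
      message = sprintf("%d gene(s) in VCF missing from feature table",
                        length(miss_feat))
    )
  }
  excluded <- is.na(affection_status(ped$phenotype, scheme))
  if (any(excluded)) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      severity = "note",
      message = sprintf("%d pedigree member(s) excluded from both sides of the affection scheme",
                        sum(excluded))
    )
  }
  if (length(issues) == 0) {
    return(tibble::tibble(severity = character(), message = character()))
  }
  dplyr::bind_rows(issues)
}

#' Run the full family rare-variant analysis
#'
#' Executes the pipeline stages in order — read and validate inputs, annotate,
#' classify sharing, matched-null enrichment for the potentially etiologic
#' and likely neutral gene pools, per-subject burden with the group and onset
#' analyses, trio de novo detection and rate comparison, deletion-run CNV
#' inference with segregation, within-family identity-by-descent checks, and
#' the multi-class gene convergence table — writing one TSV per stage plus a
#' machine-readable manifest (`manifest.json`) with inputs, seeds and
#' per-stage record counts. Outputs contain no timestamps: two runs with the
#' same config are byte-identical.
#'
#' @param config See [run_config()].
#' @return The manifest, invisibly.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  scheme <- affection_scheme(config$scheme_name)

  ped <- read_pedigree(config$ped)
  vc <- read_variants(config$vcf)
  features <- read_gene_features(config$features)
  gene_sets <- read_gene_sets(config$gmt)
  issues <- validate_inputs(vc, ped, features, scheme)
  readr::write_tsv(issues, out("validation.tsv"))

  # annotation
  ann <- annotate_variants(vc, features, config$thresholds)
  ann_sites <- variant_sites(ann)
  readr::write_tsv(
    dplyr::select(ann_sites, -dplyr::any_of(c("carrier_ids"))),
    out("annotated_sites.tsv")
  )

  # sharing classification on the pathogenic-candidate pool
  cand <- ann[ann$path_candidate, ]
  sharing <- classify_sharing(cand, ped, scheme, config$rule)
  readr::write_tsv(flatten_list_cols(sharing), out("sharing_calls.tsv"))
  comp_het <- find_compound_hets(cand, ped)
  readr::write_tsv(comp_het, out("compound_hets.tsv"))

  pev_genes <- gene_of_calls(sharing[sharing$label == "PEV", ], ann_sites)
  lnv_genes <- gene_of_calls(sharing[sharing$label == "LNV", ], ann_sites)

  # matched-null enrichment, both query pools
  spec <- null_spec(n_draws = config$n_draws,
                    match_covariates = config$match_covariates,
                    coverage_min = config$thresholds$coverage_min)
  background <- build_background(features, spec)
  m <- 2L * nrow(gene_sets)
  spec$seed <- config$seeds$enrichment_pev
  enr_pev <- enrich_gene_sets(pev_genes, gene_sets, background, spec, m = m)
  spec$seed <- config$seeds$enrichment_lnv
  enr_lnv <- enrich_gene_sets(lnv_genes, gene_sets, background, spec, m = m)
  enrichment <- dplyr::bind_rows(
    dplyr::mutate(enr_pev, query = "PEV", .before = 1),
    dplyr::mutate(enr_lnv, query = "LNV", .before = 1)
  )
  readr::write_tsv(enrichment, out("enrichment.tsv"))

  # burden
  profiles <- burden_per_subject(ann, ped)
  profiles$married_in <- ped$married_in[match(profiles$subject_id, ped$id)]
  readr::write_tsv(profiles, out("burden_profiles.tsv"))
  group_test <- burden_group_test(profiles, affection_scheme("strict"))
  onset <- tryCatch(
    onset_burden_analysis(profiles, affection_scheme("broad"),
                          config$onset_window),
    error = function(e) tibble::tibble(r_s = NA_real_, p_value = NA_real_,
                                       n = 0L)
  )
  burden_summary <- tibble::tibble(
    mean_affected = attr(group_test, "mean_affected"),
    mean_unaffected = attr(group_test, "mean_unaffected"),
    u = group_test$u, u_p_value = group_test$p_value,
    onset_r_s = onset$r_s, onset_p_value = onset$p_value, onset_n = onset$n
  )
  readr::write_tsv(burden_summary, out("burden_summary.tsv"))

  # de novo
  denovo <- detect_de_novo(vc, ped, depth_min = config$depth_min,
                           min_alt_reads = config$min_alt_reads,
                           max_parent_alt_reads = config$max_parent_alt_reads)
  readr::write_tsv(denovo, out("denovo_calls.tsv"))
  dn_rates <- tryCatch(
    de_novo_rate_comparison(denovo, ped, affection_scheme("strict")),
    error = function(e) tibble::tibble(mean_affected = NA_real_,
                                       mean_unaffected = NA_real_,
                                       n_affected = 0L, n_unaffected = 0L,
                                       u = NA_real_, p_value = NA_real_)
  )
  readr::write_tsv(dn_rates, out("denovo_rates.tsv"))

  # CNV deletions
  cnv <- detect_deletion_runs(vc, ped, min_run = config$min_run,
                              max_gap_bp = config$max_gap_bp)
  cnv <- filter_cnvs(cnv, min_run = config$min_run)
  if (nrow(cnv) > 0) {
    seg <- lapply(seq_len(nrow(cnv)), function(i) {
      s <- infer_cnv_segregation(cnv[i, ], vc, ped)
      s$cnv_index <- i
      s
    })
    readr::write_tsv(dplyr::bind_rows(seg), out("cnv_segregation.tsv"))
    write_cnv_bed(cnv, out("cnv_calls.bed"))
  }
  readr::write_tsv(flatten_list_cols(cnv), out("cnv_calls.tsv"))

  # identity-by-descent within families
  ibd <- dplyr::bind_rows(lapply(unique(ped$family_id), function(fam) {
    ids <- ped$id[ped$family_id == fam & ped$sequenced]
    if (length(ids) < 2) return(NULL)
    fam_vc <- vc[vc$subject_id %in% ids, ]
    af <- setNames(variant_sites(fam_vc)$af_evs,
                   variant_sites(fam_vc)$variant_id)
    res <- pairwise_ibd(fam_vc, allele_freqs = af,
                        min_sites = config$ibd_min_sites,
                        prune_bp = config$ibd_prune_bp)
    dplyr::mutate(res, family_id = fam, .before = 1)
  }))
  readr::write_tsv(ibd, out("ibd_estimates.tsv"))

  # convergence
  convergence <- convergence_table(
    sharing, ann, ped, scheme,
    cnv_calls = annotate_cnv_genes(cnv, ann_sites),
    denovo_calls = denovo[denovo$status == "candidate", ]
  )
  readr::write_tsv(convergence, out("convergence.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("famvar")),
    inputs = config[c("vcf", "ped", "features", "gmt")],
    seed = config$seed,
    seeds = config$seeds,
    scheme = config$scheme_name,
    counts = list(
      subjects = length(unique(vc$subject_id)),
      families = length(unique(ped$family_id)),
      variants = nrow(ann_sites),
      pathogenic_candidates = sum(variant_sites(ann)$path_candidate),
      sharing_calls = nrow(sharing),
      pev = sum(sharing$label == "PEV"),
      lnv = sum(sharing$label == "LNV"),
      compound_het_pairs = nrow(comp_het),
      enrichment_tests = nrow(enrichment),
      burden_subjects = nrow(profiles),
      denovo_candidates = sum(denovo$status == "candidate"),
      cnv_calls = nrow(cnv),
      ibd_pairs = nrow(ibd),
      convergence_genes = nrow(convergence)
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# genes of sharing calls, one per distinct (gene) across calls
gene_of_calls <- function(calls, sites) {
  unique(stats::na.omit(sites$gene[match(calls$variant_id, sites$variant_id)]))
}

# attach the gene most overlapped by each CNV (first supporting site's gene)
annotate_cnv_genes <- function(cnv, sites) {
  if (nrow(cnv) == 0) return(cnv)
  cnv$gene <- vapply(cnv$variant_ids, function(v) {
    g <- stats::na.omit(sites$gene[match(v, sites$variant_id)])
    if (length(g) == 0) NA_character_ else g[1]
  }, character(1))
  cnv
}

# stringify list columns for TSV output
flatten_list_cols <- function(df) {
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(x) paste(x, collapse = ","),
                          character(1))
    }
  }
  df
}
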