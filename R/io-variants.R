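#' Read annotated variant calls from a VCF file
#'
#' Parses a VCF 4.x file carrying per-sample `GT`, `AD` and `DP` FORMAT fields
#' and site annotations in INFO (`GENE`, `CSQCLASS`, `PP2`, `SIFT`, and one
#' `AF_<panel>` key per population reference panel) into a tidy table with one
#' row per alternate allele per subject. Multiallelic sites are decomposed
#' into one record per alternate allele, sharing `chrom`/`pos`; a genotype is
#' classified per allele (e.g. a `1/2` call is `het` for both decomposed
#' records). Missing annotation fields become `NA`, never zero.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param subjects Optional character vector of subject ids that must be
#'   present; an error lists any that are missing from the VCF header. When
#'   supplied, the returned table is restricted to these subjects.
#' @return A tibble with site columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, `polyphen2`, `sift`, one numeric
#'   `af_<panel>` column per panel seen in the file, and call columns
#'   `subject_id`, `gt` (`hom_ref`/`het`/`hom_alt`/`missing`), `ad_ref`,
#'   `ad_alt`, `dp`.
#' @seealso [write_vcf()], [variant_sites()]
#' @export
read_variants <- function(path, subjects = NULL) {
  stopifnot(file.exists(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(subjects)) {
    missing_ids <- setdiff(subjects, samples)
    if (length(missing_ids) > 0) {
      rlang::abort(sprintf("subject(s) absent from VCF header: %s",
                           paste(missing_ids, collapse = ", ")))
    }
    samples <- subjects
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- vcf@fix[, "INFO"]
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  ad_raw <- vcfR::extract.gt(vcf, element = "AD")
  dp_raw <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)

  af_keys <- sort(unique(unlist(
    stringr::str_extract_all(info, "AF_[A-Za-z0-9]+")
  )))

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    kv <- parse_info(info[i])
    gene <- kv[["GENE"]] %||% NA_character_
    csq <- split_per_alt(kv[["CSQCLASS"]], length(alts))
    pp2 <- as.numeric(split_per_alt(kv[["PP2"]], length(alts)))
    sift <- as.numeric(split_per_alt(kv[["SIFT"]], length(alts)))
    afs <- lapply(af_keys, function(k) {
      as.numeric(split_per_alt(kv[[k]], length(alts)))
    })
    ad_i <- strsplit(ad_raw[i, samples], ",", fixed = TRUE)
    gt_i <- gt_raw[i, samples]
    dp_i <- dp_raw[i, samples]
    per_alt <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      gt_k <- classify_gt(gt_i, k)
      ad_ref <- vapply(ad_i, function(x) {
        if (length(x) < 1 || is.na(x[1])) NA_integer_ else as.integer(x[1])
      }, integer(1))
      ad_alt <- vapply(ad_i, function(x) {
        if (length(x) < k + 1 || is.na(x[k + 1])) NA_integer_ else as.integer(x[k + 1])
      }, integer(1))
      row <- tibble::tibble(
        variant_id = paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"],
                           alts[k], sep = ":"),
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[k],
        gene = gene,
        consequence = csq[k],
        polyphen2 = pp2[k],
        sift = sift[k],
        subject_id = samples,
        gt = gt_k,
        ad_ref = unname(ad_ref),
        ad_alt = unname(ad_alt),
        dp = as.integer(unname(dp_i))
      )
      for (j in seq_along(af_keys)) {
        row[[tolower(af_keys[j])]] <- afs[[j]][k]
      }
      per_alt[[k]] <- row
    }
    rows[[i]] <- dplyr::bind_rows(per_alt)
  }
  out <- dplyr::bind_rows(rows)
  site_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                 "consequence", "polyphen2", "sift", tolower(af_keys))
  dplyr::relocate(out, dplyr::all_of(site_cols))
}

parse_info <- function(x) {
  if (is.na(x) || x == "." || x == "") return(list())
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1) p[2] else NA_character_)
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

split_per_alt <- function(x, n_alt) {
  if (is.null(x) || is.na(x)) return(rep(NA_character_, n_alt))
  vals <- strsplit(x, ",", fixed = TRUE)[[1]]
  vals[vals == "."] <- NA_character_
  if (length(vals) == 1) vals <- rep(vals, n_alt)
  length(vals) <- n_alt
  vals
}

# classify a VCF GT string with respect to alt allele index k
classify_gt <- function(gt, k) {
  alleles <- strsplit(gt, "[/|]")
  unname(vapply(alleles, function(a) {
    if (length(a) == 0 || anyNA(a) || any(a == ".")) return("missing")
    n_alt <- sum(a == as.character(k))
    c("hom_ref", "het", "hom_alt")[n_alt + 1]
  }, character(1)))
}

#' Write a variant-call table to VCF 4.2
#'
#' Inverse of [read_variants()] for biallelic records: annotations are emitted
#' as INFO keys `GENE`, `CSQCLASS`, `PP2`, `SIFT` and upper-cased `AF_<panel>`
#' keys; per-sample fields are `GT:AD:DP`. Output is deterministic (records
#' sorted by chromosome and position, samples in first-seen order).
#'
#' @param vc Variant-call table (see [read_variants()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vc, path) {
  af_cols <- grep("^af_", names(vc), value = TRUE)
  sites <- variant_sites(vc)
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), ]
  subjects <- unique(vc$subject_id)

  info_str <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    parts <- c(
      if (!is.na(s$gene)) paste0("GENE=", s$gene),
      if (!is.na(s$consequence)) paste0("CSQCLASS=", s$consequence),
      if (!is.na(s$polyphen2)) paste0("PP2=", format(s$polyphen2, trim = TRUE)),
      if (!is.na(s$sift)) paste0("SIFT=", format(s$sift, trim = TRUE))
    )
    for (a in af_cols) {
      if (!is.na(s[[a]])) {
        parts <- c(parts, paste0(toupper(a), "=", format(s[[a]], trim = TRUE)))
      }
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))

  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  calls <- vc[, c("variant_id", "subject_id", "gt", "ad_ref", "ad_alt", "dp")]
  calls$field <- paste0(
    gt_code[calls$gt], ":",
    dplyr::coalesce(as.character(calls$ad_ref), "."), ",",
    dplyr::coalesce(as.character(calls$ad_alt), "."), ":",
    dplyr::coalesce(as.character(calls$dp), ".")
  )
  wide <- tidyr::pivot_wider(calls[, c("variant_id", "subject_id", "field")],
                             names_from = "subject_id", values_from = "field")
  wide <- wide[match(sites$variant_id, wide$variant_id), , drop = FALSE]

  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQCLASS,Number=A,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=PP2,Number=A,Type=Float,Description=\"PolyPhen-2 score\">",
    "##INFO=<ID=SIFT,Number=A,Type=Float,Description=\"SIFT score\">",
    vapply(af_cols, function(a) sprintf(
      "##INFO=<ID=%s,Number=A,Type=Float,Description=\"Population allele frequency (%s)\">",
      toupper(a), sub("^af_", "", a)), character(1)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], sites$pos[i], sites$variant_id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", info_str[i], "GT:AD:DP",
            unlist(wide[i, subjects])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Collapse a variant-call table to one row per variant site
#'
#' @param vc Variant-call table.
#' @return Tibble of the site-level columns, one row per `variant_id`.
#' @export
variant_sites <- function(vc) {
  call_cols <- c("subject_id", "gt", "ad_ref", "ad_alt", "dp")
  dplyr::distinct(vc[, setdiff(names(vc), call_cols)])
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then gene symbols. Duplicate genes within a line are deduplicated and empty
#' lines skipped; a non-empty line with fewer than three fields is a parse
#' error reporting the line number.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns `name`, `description`, `genes` (list of
#'   character vectors) and `n_genes`.
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) {
    rlang::abort(sprintf("GMT line %d has fewer than 3 fields",
                         which(keep)[which(short)[1]]),
                 class = "famvar_parse_error")
  }
  tibble::tibble(
    name = vapply(fields, `[`, character(1), 1),
    description = vapply(fields, `[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)])),
  ) |>
    dplyr::mutate(n_genes = lengths(.data$genes))
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-gene feature table
#'
#' Tab-separated file with header columns `gene`, `cds_length` (bp),
#' `missense_z` (constraint z-score), `mean_coverage` (fold) and `brain_rpkm`
#' (mean RPKM across brain samples). These are the covariates used for
#' matched-null enrichment and the brain-expression flag.
#'
#' @param path Path to the TSV file.
#' @return Tibble with the five columns above.
#' @export
read_gene_features <- function(path) {
  feats <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    cds_length = readr::col_double(),
    missense_z = readr::col_double(),
    mean_coverage = readr::col_double(),
    brain_rpkm = readr::col_double()
  ))
  stopifnot(all(feats$cds_length > 0), all(feats$mean_coverage >= 0))
  feats
}

#' Write a per-gene feature table
#'
#' @param features Tibble as returned by [read_gene_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
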