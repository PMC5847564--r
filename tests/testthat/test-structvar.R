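test_that("deletion-run detection needs a run of supporting sites", {
  # fully consistent family: no calls
  ped <- simulate_pedigree("three_generation", "F1", seed = 3)
  vc <- as_variant_calls(gene_drop(ped, fixture_sites(40, af = 0.4), seed = 4))
  expect_equal(nrow(detect_deletion_runs(vc, ped)), 0)

  # two isolated inconsistent sites do not reach min_run = 3
  trio <- tibble::tibble(
    family_id = "F", id = c("d", "m", "k"),
    father_id = c(NA, NA, "d"), mother_id = c(NA, NA, "m"),
    sex = c("male", "female", "male"), phenotype = "unknown",
    age_of_onset = NA_real_, sequenced = TRUE, married_in = FALSE
  )
  gts <- rep("hom_ref", 52)
  vc2 <- dplyr::bind_rows(lapply(1:52, function(i) {
    g <- c(d = "hom_ref", m = "hom_ref", k = "hom_ref")
    if (i %in% c(1, 52)) g <- c(d = "hom_alt", m = "het", k = "hom_ref")
    fixture_calls(g, variant_id = sprintf("chr1:%d:A:G", i * 1000))
  }))
  vc2$pos <- as.integer(sub(".*:(\\d+):A:G", "\\1", vc2$variant_id))
  expect_equal(nrow(detect_deletion_runs(vc2, trio, min_run = 3)), 0)
  # but the same two sites do support a min_run = 2 call
  expect_equal(nrow(detect_deletion_runs(vc2, trio, min_run = 2)), 1)
})

test_that("spiked deletions are recovered with truthful intervals", {
  hits <- 0; tot <- 0
  for (s in 1:25) {
    ped <- simulate_pedigree("three_generation", "D", seed = 100 + s)
    sites <- fixture_sites(30, af = 0.4)
    sites$kind <- "common"
    st <- tryCatch(
      spike_deletion(gene_drop(ped, sites, seed = 200 + s), span = 10,
                     seed = 300 + s),
      error = function(e) NULL
    )
    if (is.null(st)) next
    tot <- tot + 1
    vc <- as_variant_calls(st)
    cnv <- detect_deletion_runs(vc, ped)
    tr <- st$truth$deletions
    ok <- nrow(cnv) > 0 &&
      any(cnv$start >= tr$start & cnv$end <= tr$end & cnv$chrom == tr$chrom)
    if (ok) hits <- hits + 1
  }
  expect_gte(tot, 20)
  expect_gte(hits / tot, 0.8)
})

test_that("transmission phasing is decisive exactly where Mendelian logic is", {
  # forced assignment
  ph <- famvar:::phase_trio("het", "hom_ref", "hom_alt")
  expect_equal(ph$pat, "ref")
  expect_equal(ph$mat, "alt")
  # all het: ambiguous
  ph <- famvar:::phase_trio("het", "het", "het")
  expect_true(is.na(ph$pat) && is.na(ph$mat))
  # inconsistent site: unknown, not an error
  ph <- famvar:::phase_trio("hom_alt", "hom_ref", "hom_ref")
  expect_true(is.na(ph$pat))
  # homozygous child is trivially phased
  ph <- famvar:::phase_trio("hom_alt", "het", "hom_alt")
  expect_equal(ph$pat, "alt")
})

test_that("phased alleles equal the simulator's true phase at decisive sites", {
  ped <- simulate_pedigree("three_generation", "F1", seed = 9)
  st <- gene_drop(ped, fixture_sites(60, af = 0.4), seed = 10)
  vc <- as_variant_calls(st)
  phased <- phase_by_transmission(vc, ped)
  truth <- true_phase(st)
  j <- dplyr::inner_join(phased, truth, by = c("subject_id", "variant_id"),
                         suffix = c("", "_true"))
  dec_p <- !is.na(j$paternal_allele)
  dec_m <- !is.na(j$maternal_allele)
  expect_gt(sum(dec_p), 0)
  expect_true(all(j$paternal_allele[dec_p] == j$paternal_allele_true[dec_p]))
  expect_true(all(j$maternal_allele[dec_m] == j$maternal_allele_true[dec_m]))
})

test_that("segregation inference is conservative and truthful", {
  found <- FALSE
  for (s in 1:10) {
    ped <- simulate_pedigree("three_generation", "S", seed = 400 + s)
    sites <- fixture_sites(30, af = 0.4)
    sites$kind <- "common"
    st <- tryCatch(
      spike_deletion(gene_drop(ped, sites, seed = 500 + s), span = 10,
                     seed = 600 + s),
      error = function(e) NULL
    )
    if (is.null(st)) next
    vc <- as_variant_calls(st)
    cnv <- detect_deletion_runs(vc, ped)
    if (nrow(cnv) == 0) next
    found <- TRUE
    seg <- infer_cnv_segregation(cnv[1, ], vc, ped)
    truth_car <- st$truth$deletions$carrier_ids[[1]]
    lab_car <- seg$subject_id[seg$status == "carrier"]
    lab_non <- seg$subject_id[seg$status == "non_carrier"]
    # never label a true non-carrier as carrier; never exclude a true carrier
    expect_true(all(lab_car %in% truth_car))
    expect_false(any(lab_non %in% truth_car))
  }
  expect_true(found)
})

test_that("CNV filters apply frequency, span and support thresholds", {
  calls <- tibble::tibble(
    family_id = "F", chrom = "chr1",
    start = c(1e6, 1e6, 1e6, 1e6),
    end = c(1e6 + 19999, 1e6 + 30000, 1e6 + 30000, 1e6 + 5e5),
    type = "deletion",
    n_supporting_sites = c(30L, 30L, 30L, 4L),
    carrier_ids = list("a", "a", "a", "a"),
    variant_ids = list("v", "v", "v", "v"),
    source = c("external_array", "external_array", "external_array",
               "wes_inconsistency"),
    pop_freq = c(0.01, 0.10, 0.01, NA)
  )
  kept <- filter_cnvs(calls)
  # 20 kb array call removed; 10% frequency removed; 30 kb rare call kept;
  # WES call judged on run support, not the probe rule
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$end - kept$start + 1 >= 25000 |
                    kept$source == "wes_inconsistency"))
  # BED export is 0-based half-open
  path <- withr::local_tempfile(fileext = ".bed")
  write_cnv_bed(kept, path)
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_equal(bed$X2, kept$start - 1)
  expect_equal(bed$X3, kept$end)
})

test_that("IBD estimates recover canonical relationships", {
  ped <- tibble::tibble(
    family_id = "F", id = c("p1", "p2", "c1", "c2"),
    father_id = c(NA, NA, "p1", "p1"), mother_id = c(NA, NA, "p2", "p2"),
    sex = c("male", "female", "male", "female"),
    phenotype = "unknown", age_of_onset = NA_real_,
    sequenced = TRUE, married_in = FALSE
  )
  m <- 4000
  sites <- tibble::tibble(
    variant_id = sprintf("chr%d:%d:A:G", rep(1:10, each = m / 10),
                         rep(seq(1e5, by = 1.5e5, length.out = m / 10), 10)),
    chrom = rep(paste0("chr", 1:10), each = m / 10),
    pos = rep(seq(1e5, by = 1.5e5, length.out = m / 10), 10),
    ref = "A", alt = "G",
    af = withr::with_seed(1, runif(m, 0.15, 0.5))
  )
  st <- gene_drop(ped, sites, seed = 2)
  vc <- as_variant_calls(st)
  af <- setNames(sites$af, sites$variant_id)
  res <- pairwise_ibd(vc, allele_freqs = af)
  get <- function(a, b) res[(res$id1 == a & res$id2 == b) |
                              (res$id1 == b & res$id2 == a), ]
  # founders unrelated
  expect_lt(abs(get("p1", "p2")$pi_hat - 0), 0.05)
  # parent-offspring: pi 0.5 with Z1 ~ 1
  po <- get("p1", "c1")
  expect_lt(abs(po$pi_hat - 0.5), 0.05)
  expect_gt(po$Z1, 0.9)
  # full sibs: pi ~ 0.5
  expect_lt(abs(get("c1", "c2")$pi_hat - 0.5), 0.05)
  # Z vector lies on the simplex
  expect_true(all(abs(rowSums(res[, c("Z0", "Z1", "Z2")]) - 1) < 1e-8))
  # duplicated subject vs itself
  dup <- vc[vc$subject_id == "p1", ]
  dup$subject_id <- "p1b"
  res2 <- pairwise_ibd(dplyr::bind_rows(vc, dup), allele_freqs = af,
                       pairs = data.frame(id1 = "p1", id2 = "p1b"))
  expect_gt(res2$pi_hat, 0.95)
})

test_that("sib-pair IBD distribution centres on (0.25, 0.5, 0.25)", {
  zs <- matrix(NA_real_, 40, 3)
  m <- 1500
  sites <- tibble::tibble(
    variant_id = sprintf("chr%d:%d:A:G", rep(1:10, each = m / 10),
                         rep(seq(1e5, by = 1.5e5, length.out = m / 10), 10)),
    chrom = rep(paste0("chr", 1:10), each = m / 10),
    pos = rep(seq(1e5, by = 1.5e5, length.out = m / 10), 10),
    ref = "A", alt = "G",
    af = withr::with_seed(3, runif(m, 0.2, 0.5))
  )
  ped <- tibble::tibble(
    family_id = "F", id = c("p1", "p2", "c1", "c2"),
    father_id = c(NA, NA, "p1", "p1"), mother_id = c(NA, NA, "p2", "p2"),
    sex = c("male", "female", "male", "female"),
    phenotype = "unknown", age_of_onset = NA_real_,
    sequenced = TRUE, married_in = FALSE
  )
  af <- setNames(sites$af, sites$variant_id)
  for (r in seq_len(nrow(zs))) {
    vc <- as_variant_calls(gene_drop(ped, sites, seed = 700 + r))
    res <- pairwise_ibd(vc, allele_freqs = af,
                        pairs = data.frame(id1 = "c1", id2 = "c2"))
    zs[r, ] <- unlist(res[, c("Z0", "Z1", "Z2")])
  }
  means <- colMeans(zs)
  ses <- apply(zs, 2, stats::sd) / sqrt(nrow(zs))
  expect_lt(abs(means[1] - 0.25), 3 * ses[1] + 0.02)
  expect_lt(abs(means[2] - 0.50), 3 * ses[2] + 0.02)
  expect_lt(abs(means[3] - 0.25), 3 * ses[3] + 0.02)
})

test_that("monomorphic-only input is rejected", {
  ped <- simulate_pedigree("nuclear", "F", seed = 1)
  vc <- as_variant_calls(gene_drop(ped, fixture_sites(10, af = 0), seed = 2))
  af <- setNames(rep(0, 10), unique(vc$variant_id))
  expect_error(pairwise_ibd(vc, allele_freqs = af, prune_bp = 0),
               regexp = "polymorphic")
})
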