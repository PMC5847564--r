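test_that("burden counts sites, not alleles, and splits by brain expression", {
  ped <- fixture_pedigree()
  features <- tibble::tibble(
    gene = c("G1", "G2"), cds_length = 1000, missense_z = 0,
    mean_coverage = 80, brain_rpkm = c(5, 0.2)
  )
  vc <- dplyr::bind_rows(
    dplyr::mutate(fixture_calls(c(gf = "hom_alt", gm = "hom_ref")),
                  consequence = "nonsense"),
    dplyr::mutate(fixture_calls(c(gf = "het", gm = "het"),
                                variant_id = "chr1:200:C:T"),
                  consequence = "frameshift_indel", gene = "G2"),
    dplyr::mutate(fixture_calls(c(gf = "het", gm = "hom_ref"),
                                variant_id = "chr1:300:C:G"),
                  consequence = "missense")
  )
  ann <- annotate_variants(vc, features)
  prof <- burden_per_subject(ann, ped)
  gf <- prof[prof$subject_id == "gf", ]
  # hom_alt nonsense counts once; frameshift counts once; missense never
  expect_equal(gf$n_lgd_total, 2L)
  expect_equal(gf$n_lgd_brain, 1L)  # only G1 is brain expressed
  gm <- prof[prof$subject_id == "gm", ]
  expect_equal(gm$n_lgd_total, 1L)
  # subjects with no calls appear with zero burden
  expect_equal(prof$n_lgd_total[prof$subject_id == "c3"], 0L)
  expect_equal(nrow(prof), sum(ped$sequenced))
})

test_that("burden counts equal a brute-force recount on simulated data", {
  study <- simulate_study(sim_config(n_families = 2, n_rare_sites = 120,
                                     n_common_sites = 40, n_pev_spikes = 0,
                                     n_deletion_spikes = 0, de_novo_rate = 0,
                                     seed = 12))
  ann <- annotate_variants(study$variant_calls, study$features)
  prof <- burden_per_subject(ann, study$pedigree)
  sites <- variant_sites(ann)
  lgd_ids <- sites$variant_id[sites$rare & sites$lgd]
  for (s in sample(prof$subject_id, 6)) {
    calls <- ann[ann$subject_id == s & ann$variant_id %in% lgd_ids &
                   ann$gt %in% c("het", "hom_alt"), ]
    expect_equal(prof$n_lgd_total[prof$subject_id == s],
                 length(unique(calls$variant_id)))
    brain_calls <- calls[calls$brain %in% TRUE, ]
    expect_equal(prof$n_lgd_brain[prof$subject_id == s],
                 length(unique(brain_calls$variant_id)))
  }
})

test_that("Mann-Whitney U matches its exact-permutation oracle", {
  # complete separation
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$u + res$u_y, 9)  # U_x + U_y = n_x n_y
  expect_equal(res$p_value, 2 / choose(6, 3), tolerance = 1e-12)
  # identical groups: p = 1
  expect_equal(mann_whitney_u(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  # tied data against an independent enumeration oracle
  oracle <- function(x, y) {
    n1 <- length(x); pooled <- c(x, y); r <- rank(pooled)
    mu <- n1 * length(y) / 2
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(length(pooled), n1)
    us <- apply(combos, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  cases <- list(
    list(x = c(13, 14, 12, 15), y = c(14, 13, 16)),
    list(x = c(1, 1, 2, 2, 3), y = c(2, 3, 3, 4)),
    list(x = c(0, 0, 0), y = c(0, 1, 2, 3))
  )
  for (cs in cases) {
    res <- mann_whitney_u(cs$x, cs$y)
    expect_equal(res$p_value, oracle(cs$x, cs$y), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), regexp = "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test on untied data", {
  withr::with_seed(9, {
    for (i in 1:5) {
      x <- rnorm(sample(4:8, 1)); y <- rnorm(sample(4:8, 1))
      ours <- mann_whitney_u(x, y)
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$u, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
    # large-sample path: U identity invariant and close to the normal ref
    x <- rnorm(30); y <- rnorm(25, 0.5)
    ours <- mann_whitney_u(x, y)
    expect_equal(ours$u + ours$u_y, 30 * 25)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  })
})

test_that("Spearman statistic matches rank-formula oracle and bounds", {
  # strictly decreasing: r_s = -1, permutation fallback p
  res <- spearman_test(1:6, 12 - (1:6))
  expect_equal(res$estimate, -1)
  expect_equal(res$p_value, 2 / factorial(6), tolerance = 1e-12)
  # tied example against direct average-rank computation
  x <- c(1, 2, 2, 3, 4, 4); y <- c(2, 1, 3, 3, 5, 4)
  res <- spearman_test(x, y)
  oracle <- stats::cor(rank(x), rank(y))
  expect_equal(res$estimate, oracle, tolerance = 1e-12)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(res$estimate, unname(ref$estimate), tolerance = 1e-12)
  # invariant to strictly monotone transforms
  res2 <- spearman_test(exp(x), y^3)
  expect_equal(res2$estimate, res$estimate)
  expect_error(spearman_test(rep(1, 5), 1:5), regexp = "constant")
  expect_error(spearman_test(1:3, 3:1), regexp = "n >= 4")
})

test_that("Spearman null keeps its nominal size (calibration oracle)", {
  reps <- 1000
  rej <- 0; rs <- numeric(reps)
  withr::with_seed(77, {
    for (i in seq_len(reps)) {
      x <- sample(100); y <- sample(100)
      res <- spearman_test(x, y)
      rs[i] <- res$estimate
      if (res$p_value <= 0.05) rej <- rej + 1
    }
  })
  expect_lt(abs(mean(rs)), 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rej / reps - 0.05), 3 * se)
})

test_that("onset-burden analysis filters to the typical-onset window", {
  prof <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:12), family_id = "F",
    phenotype = c(rep("BD1", 5), rep("RUD", 3), rep("unaffected", 4)),
    age_of_onset = c(20, 25, 30, 35, 40, 22, 28, 55, NA, NA, NA, NA),
    n_lgd_total = 1:12, n_lgd_brain = c(6, 5, 4, 3, 2, 6, 4, 9, 0, 0, 0, 0)
  )
  res <- onset_burden_analysis(prof)
  # broad scheme includes RUD; onset 55 and unaffected excluded
  expect_equal(res$n, 7)
  expect_lt(res$r_s, 0)
  # all onsets outside the window -> error
  prof2 <- dplyr::mutate(prof, age_of_onset = age_of_onset + 40)
  expect_error(onset_burden_analysis(prof2), regexp = ">= 4")
})

test_that("group burden test separates clear group differences", {
  prof <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:16), family_id = "F",
    phenotype = rep(c("BD1", "unaffected"), each = 8),
    age_of_onset = NA_real_,
    n_lgd_total = c(14:21, 6:13), n_lgd_brain = 0L
  )
  res <- burden_group_test(prof)
  expect_s3_class(res, "famvar_ranksum")
  expect_lt(res$p_value, 0.01)
  expect_gt(attr(res, "mean_affected"), attr(res, "mean_unaffected"))
  td <- tidy(res)
  expect_equal(td$p.value, res$p_value)
})
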