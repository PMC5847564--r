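test_that("pedigree templates satisfy their structural contracts", {
  ped <- simulate_pedigree("nuclear", "N1", seed = 1, n_offspring = 3)
  expect_equal(sum(is.na(ped$father_id) & is.na(ped$mother_id)), 2)
  expect_equal(nrow(ped), 5)

  for (s in 1:5) {
    ped <- simulate_pedigree("three_generation", "T1", seed = s)
    expect_gte(nrow(ped), 10)
    # every non-founder has both parents inside the pedigree
    nonf <- !(is.na(ped$father_id) & is.na(ped$mother_id))
    expect_true(all(ped$father_id[nonf] %in% ped$id))
    expect_true(all(ped$mother_id[nonf] %in% ped$id))
    expect_silent(validate_pedigree(ped))
    # ascertainment: >= 4 affected under the strict scheme
    expect_gte(sum(ped$phenotype %in% affection_scheme("strict")$affected), 4)
  }
})

test_that("gene drop is Mendelian-consistent and preserves frequency", {
  ped <- simulate_pedigree("three_generation", "F1", seed = 3)
  sites <- fixture_sites(200, af = 0.25)
  state <- gene_drop(ped, sites, seed = 4)
  vc <- as_variant_calls(state)
  # zero Mendelian inconsistencies without spikes or noise
  dn <- detect_de_novo(vc, ped, depth_min = 0, min_alt_reads = 0,
                       max_parent_alt_reads = 1000,
                       disqualify_other_carriers = FALSE)
  expect_equal(nrow(dn), 0)
  expect_equal(nrow(detect_deletion_runs(vc, ped, min_run = 1)), 0)
  # realized founder allele frequency ~ af within 3 SE
  founders <- is.na(ped$father_id) & is.na(ped$mother_id)
  H <- rbind(state$H_pat[ped$id[founders], ], state$H_mat[ped$id[founders], ])
  n_alleles <- length(H)
  se <- sqrt(0.25 * 0.75 / n_alleles)
  expect_lt(abs(mean(H) - 0.25), 3 * se)
})

test_that("gene drop handles boundary frequencies", {
  ped <- simulate_pedigree("nuclear", "F1", seed = 1)
  state <- gene_drop(ped, fixture_sites(5, af = 0), seed = 2)
  expect_true(all(as_variant_calls(state)$gt == "hom_ref"))
  expect_error(gene_drop(ped, fixture_sites(2, af = 1), seed = 2),
               regexp = "\\[0, 1\\)")
})

test_that("transmission from a het parent is fair (binomial oracle)", {
  # one het founder parent, many offspring: transmitted fraction 0.5 +- 3 SE
  n_kids <- 4000
  ped <- tibble::tibble(
    family_id = "F",
    id = c("p1", "p2", paste0("k", seq_len(n_kids))),
    father_id = c(NA, NA, rep("p1", n_kids)),
    mother_id = c(NA, NA, rep("p2", n_kids)),
    sex = c("male", "female", rep("unknown", n_kids)),
    phenotype = "unknown", age_of_onset = NA_real_,
    sequenced = TRUE, married_in = FALSE
  )
  sites <- fixture_sites(1, af = 0)
  state <- gene_drop(ped, sites, seed = 6)
  state$H_pat["p1", 1] <- 1L  # force father het
  # re-drop transmissions deterministically from the modified founder
  withr::with_seed(7, {
    kids <- paste0("k", seq_len(n_kids))
    pick <- runif(n_kids) < 0.5
    state$H_pat[kids, 1] <- ifelse(pick, state$H_pat["p1", 1],
                                   state$H_mat["p1", 1])
  })
  frac <- mean(state$H_pat[paste0("k", seq_len(n_kids)), 1])
  se <- sqrt(0.25 / n_kids)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("full sibs share a founder allele consistently with IBD", {
  # a specific founder haplotype reaches each child with p = 1/2;
  # both of two sibs carry it with p = 1/4
  hits <- 0; reps <- 2000
  withr::with_seed(11, {
    ped <- tibble::tibble(
      family_id = "F", id = c("p1", "p2", "k1", "k2"),
      father_id = c(NA, NA, "p1", "p1"), mother_id = c(NA, NA, "p2", "p2"),
      sex = c("male", "female", "unknown", "unknown"),
      phenotype = "unknown", age_of_onset = NA_real_,
      sequenced = TRUE, married_in = FALSE
    )
    for (r in seq_len(reps)) {
      drop <- famvar:::drop_single_allele(ped, 1, "pat")
      carried <- (drop$pat + drop$mat)[3:4] > 0
      if (all(carried)) hits <- hits + 1
    }
  })
  se <- sqrt(0.25 * 0.75 / reps)
  expect_lt(abs(hits / reps - 0.25), 3 * se)
})

test_that("spiked etiologic variants satisfy and record their constraint", {
  ped <- simulate_pedigree("three_generation", "F1", seed = 22)
  state <- gene_drop(ped, fixture_sites(10, af = 0.1), seed = 23)
  state <- spike_pev(state, penetrance = 1, gene = "GX", seed = 24)
  truth <- state$truth$pev_sites
  expect_equal(nrow(truth), 1)
  carriers <- truth$carrier_ids[[1]]
  scheme <- affection_scheme("strict")
  aff <- ped$id[ped$phenotype %in% scheme$affected]
  unaff <- ped$id[ped$phenotype %in% scheme$unaffected]
  expect_gte(sum(carriers %in% aff), 3)
  expect_equal(sum(carriers %in% unaff), 0)  # penetrance 1
  # classifier labels it PEV
  vc <- as_variant_calls(state)
  sh <- classify_sharing(vc[vc$variant_id == truth$variant_id, ], ped)
  expect_equal(sh$label, "PEV")
})

test_that("spike_pev requires affected members", {
  ped <- simulate_pedigree("nuclear", "F1", seed = 2)
  ped$phenotype <- "unaffected"
  state <- gene_drop(ped, fixture_sites(5), seed = 3)
  expect_error(spike_pev(state, seed = 4), regexp = "affected")
})

test_that("de novo spikes are Poisson with hom_ref parents", {
  # rate 0 -> no events
  ped <- simulate_pedigree("three_generation", "F1", seed = 5)
  state <- gene_drop(ped, fixture_sites(5, af = 0.1), seed = 6)
  expect_equal(nrow(spike_de_novo(state, rate = 0, seed = 7)$truth$denovo_events), 0)
  # every spiked event has both parents hom_ref and offspring het
  state <- spike_de_novo(state, rate = 2, seed = 8)
  ev <- state$truth$denovo_events
  expect_gt(nrow(ev), 0)
  vc <- as_variant_calls(state)
  for (i in seq_len(nrow(ev))) {
    o <- ev$subject_id[i]; v <- ev$variant_id[i]
    fa <- ped$father_id[ped$id == o]; mo <- ped$mother_id[ped$id == o]
    gt_of <- function(s) vc$gt[vc$variant_id == v & vc$subject_id == s]
    expect_equal(gt_of(o), "het")
    expect_equal(gt_of(fa), "hom_ref")
    expect_equal(gt_of(mo), "hom_ref")
  }
})

test_that("de novo spike count calibrates to its rate (Poisson oracle)", {
  # many nuclear trios: mean events per offspring ~ rate within 3 SE
  rate <- 1
  n_trio <- 400
  total <- 0
  withr::with_seed(31, {
    for (r in seq_len(n_trio)) {
      ped <- tibble::tibble(
        family_id = "F", id = c("a", "b", "c"),
        father_id = c(NA, NA, "a"), mother_id = c(NA, NA, "b"),
        sex = c("male", "female", "unknown"),
        phenotype = "unknown", age_of_onset = NA_real_,
        sequenced = TRUE, married_in = FALSE
      )
      st <- gene_drop(ped, fixture_sites(2, af = 0.1))
      st <- spike_de_novo(st, rate = rate)
      total <- total + nrow(st$truth$denovo_events)
    }
  })
  se <- sqrt(rate / n_trio)
  expect_lt(abs(total / n_trio - rate), 3 * se)
})

test_that("deletion spikes produce hemizygous carriers, others untouched", {
  ped <- simulate_pedigree("three_generation", "F1", seed = 41)
  sites <- fixture_sites(30, af = 0.4)
  state0 <- gene_drop(ped, sites, seed = 42)
  state <- spike_deletion(state0, span = 8, seed = 43)
  tr <- state$truth$deletions
  expect_equal(nrow(tr), 1)
  carriers <- tr$carrier_ids[[1]]
  vids <- tr$variant_ids[[1]]
  expect_length(vids, 8)
  vc <- as_variant_calls(state)
  win <- vc[vc$variant_id %in% vids, ]
  # carriers never heterozygous in the interval
  expect_false(any(win$gt[win$subject_id %in% carriers] == "het"))
  # genotypes outside the interval are unchanged
  vc0 <- as_variant_calls(state0)
  out_ids <- setdiff(vc$variant_id, vids)
  keep0 <- vc0$variant_id %in% out_ids
  expect_equal(vc$gt[vc$variant_id %in% out_ids], vc0$gt[keep0])
})

test_that("noise layer matches its Poisson and binomial oracles", {
  ped <- simulate_pedigree("three_generation", "F1", seed = 51)
  sites <- fixture_sites(300, af = 0.3)
  vc <- as_variant_calls(gene_drop(ped, sites, seed = 52))
  # error 0: genotypes unchanged
  vc0 <- apply_noise(vc, error_rate = 0, depth_mean = 112, seed = 53)
  expect_equal(vc0$gt, vc$gt)
  # mean depth ~ depth_mean within 3 SE
  n <- nrow(vc0)
  expect_lt(abs(mean(vc0$dp) - 112), 3 * sqrt(112 / n))
  # perturbed fraction ~ error rate within 3 SE
  eps <- 0.01
  vc1 <- apply_noise(vc, error_rate = eps, depth_mean = 112, seed = 54)
  flipped <- mean(vc1$gt != vc$gt)
  expect_lt(abs(flipped - eps), 3 * sqrt(eps * (1 - eps) / n))
})

test_that("onset model couples onset to burden as specified", {
  ped <- simulate_pedigree("three_generation", "F1", seed = 61)
  ids <- ped$id
  # sigma -> 0 with beta1 > 0: onset strictly decreasing in burden
  burden <- setNames(seq_along(ids), ids)
  ped2 <- assign_phenotypes(
    ped, list(type = "burden_coupled", beta0 = 45, beta1 = 0.1, sigma = 1e-9),
    burden = burden, seed = 62
  )
  aff <- !is.na(ped2$age_of_onset)
  ons <- ped2$age_of_onset[aff]
  bur <- burden[ped2$id[aff]]
  expect_equal(unname(stats::cor(rank(ons), rank(bur))), -1)
  expect_true(all(ons >= 15 & ons <= 50))
  expect_error(
    assign_phenotypes(ped, list(type = "burden_coupled", beta0 = 45,
                                beta1 = 1, sigma = 0), burden = burden),
    regexp = "sigma"
  )
  # beta1 = 0: onset independent of burden over many subjects
  big <- tibble::tibble(
    family_id = "F", id = sprintf("s%04d", 1:1000),
    father_id = NA_character_, mother_id = NA_character_,
    sex = "unknown", phenotype = "BD1", age_of_onset = NA_real_,
    sequenced = TRUE, married_in = FALSE
  )
  b2 <- setNames(rpois(1000, 8), big$id)
  ped3 <- assign_phenotypes(
    big, list(type = "burden_coupled", beta0 = 32, beta1 = 0, sigma = 5),
    burden = b2, seed = 63
  )
  r <- stats::cor(rank(ped3$age_of_onset), rank(b2[ped3$id]))
  expect_lt(abs(r), 0.1)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_families = 2, n_rare_sites = 40, n_common_sites = 40,
                    seed = 71)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_study(simulate_study(cfg), d1)
  p2 <- write_study(simulate_study(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = sprintf("file %s", k))
  }
})
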