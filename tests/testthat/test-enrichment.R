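make_features <- function(n, seed = 1, low_cov_frac = 0) {
  withr::with_seed(seed, tibble::tibble(
    gene = sprintf("G%04d", seq_len(n)),
    cds_length = pmax(150, round(stats::rlnorm(n, log(1500), 0.7))),
    missense_z = round(rnorm(n, 0, 2), 3),
    mean_coverage = ifelse(seq_len(n) <= n * low_cov_frac, 5, 80),
    brain_rpkm = stats::rlnorm(n, 0, 1)
  ))
}

test_that("background pool applies the coverage filter and partitions genes", {
  feats <- make_features(500, low_cov_frac = 0.1)
  bg <- build_background(feats, null_spec(n_length_bins = 10, n_z_bins = 5))
  expect_equal(nrow(bg), 450)  # 10% below 10x coverage excluded
  expect_true(all(table(bg$gene) == 1))  # each gene in exactly one stratum
  expect_lte(length(unique(bg$stratum)), 50)
  # all-low coverage -> error
  feats_low <- dplyr::mutate(feats, mean_coverage = 5)
  expect_error(build_background(feats_low), regexp = "empty")
})

test_that("bin boundaries equal independently computed quantile cut-points", {
  feats <- make_features(400)
  spec <- null_spec(n_length_bins = 4, n_z_bins = 1)
  bg <- build_background(feats, spec)
  # sort-based oracle: quartile membership by position in the sorted vector
  ord <- order(bg$cds_length)
  oracle_bin <- integer(nrow(bg))
  qs <- stats::quantile(bg$cds_length, probs = seq(0, 1, 0.25), type = 7)
  oracle_bin <- cut(bg$cds_length, breaks = unique(qs), include.lowest = TRUE,
                    labels = FALSE)
  # strata are a relabeling of the oracle bins
  expect_equal(length(unique(paste(bg$stratum, oracle_bin))),
               length(unique(oracle_bin)))
})

test_that("matched draws conserve size and match covariates in expectation", {
  feats <- make_features(600)
  spec <- null_spec(seed = 5)
  bg <- build_background(feats, spec)
  query <- withr::with_seed(6, sample(bg$gene, 40))
  draw <- draw_matched_set(query, bg, seed = 7)
  expect_length(draw, 40)
  expect_true(all(draw %in% bg$gene))
  expect_equal(anyDuplicated(draw), 0)
  # matching fidelity: mean cds_length of draws ~ mean of query over draws
  q_mean <- mean(bg$cds_length[match(query, bg$gene)])
  reps <- 300
  d_means <- withr::with_seed(8, vapply(seq_len(reps), function(i) {
    mean(bg$cds_length[match(draw_matched_set(query, bg), bg$gene)])
  }, numeric(1)))
  se <- stats::sd(d_means) / sqrt(reps)
  # binned matching is approximate: allow 3 SE around the query mean plus
  # the within-bin discretisation, bounded by one bin width
  expect_lt(abs(mean(d_means) - q_mean), max(3 * se, 0.15 * q_mean))
})

test_that("single-gene stratum draws itself back", {
  feats <- tibble::tibble(
    gene = c("A", "B", "C"), cds_length = c(100, 10000, 10100),
    missense_z = c(0, 0, 0), mean_coverage = 80, brain_rpkm = 1
  )
  spec <- null_spec(n_length_bins = 3, n_z_bins = 1)
  bg <- build_background(feats, spec)
  # gene A sits alone in the low-length stratum
  stopifnot(sum(bg$stratum == bg$stratum[bg$gene == "A"]) == 1)
  draw <- draw_matched_set("A", bg, seed = 1)
  expect_equal(draw, "A")
})

test_that("empirical enrichment handles degenerate and extreme inputs", {
  feats <- make_features(200)
  spec <- null_spec(n_draws = 200, match_covariates = character(0), seed = 2)
  bg <- build_background(feats, spec)
  query <- bg$gene[1:20]
  # disjoint gene set: O = 0, p = 1
  res <- empirical_enrichment(query, c("NOPE1", "NOPE2"), bg, spec)
  expect_equal(res$observed, 0)
  expect_equal(res$empirical_p, 1)
  # query wholly inside the set, set tiny in pool: O above every null -> floor
  res <- empirical_enrichment(bg$gene[1:5], bg$gene[1:5], bg,
                              null_spec(n_draws = 200,
                                        match_covariates = character(0),
                                        seed = 3))
  expect_gte(res$empirical_p, 1 / 201)
  expect_lte(res$empirical_p, 5 / 201)
  # monotone: for the same nulls, p is non-increasing in O
  nulls <- res$null_overlap
  p_of <- function(O) (1 + sum(nulls >= O)) / (1 + length(nulls))
  expect_true(all(diff(vapply(0:5, p_of, numeric(1))) <= 0))
})

test_that("empirical p is deterministic given a seed", {
  feats <- make_features(300)
  spec <- null_spec(n_draws = 500, seed = 11)
  bg <- build_background(feats, spec)
  query <- bg$gene[seq(1, 250, by = 10)]
  set <- bg$gene[seq(1, 290, by = 3)]
  r1 <- empirical_enrichment(query, set, bg, spec)
  r2 <- empirical_enrichment(query, set, bg, spec)
  expect_identical(r1$empirical_p, r2$empirical_p)
  expect_identical(r1$null_overlap, r2$null_overlap)
})

test_that("with one stratum the empirical p matches the hypergeometric tail", {
  feats <- make_features(250)
  grid <- list(c(K = 50, k = 20), c(K = 100, k = 30), c(K = 25, k = 40))
  for (g in grid) {
    spec <- null_spec(n_draws = 3000, match_covariates = character(0),
                      seed = 17 + g[["K"]])
    bg <- build_background(feats, spec)
    N <- nrow(bg)
    set <- bg$gene[seq_len(g[["K"]])]
    query <- withr::with_seed(g[["K"]], sample(bg$gene, g[["k"]]))
    res <- empirical_enrichment(query, set, bg, spec)
    p_hyper <- hypergeometric_tail(res$observed, N, g[["K"]], g[["k"]])
    mc_se <- sqrt(p_hyper * (1 - p_hyper) / spec$n_draws)
    expect_lt(abs(res$empirical_p - p_hyper), 3 * mc_se + 2 / spec$n_draws)
  }
})

test_that("hypergeometric tail matches exact combinatorics and normalises", {
  expect_equal(hypergeometric_tail(0, 100, 20, 10), 1)
  expect_equal(hypergeometric_tail(5, 10, 5, 5), 1 / 252, tolerance = 1e-12)
  # point masses over the support sum to one
  N <- 40; K <- 12; k <- 15
  total <- sum(vapply(0:min(K, k), function(x) {
    hypergeometric_tail(x, N, K, k) -
      if (x < min(K, k)) hypergeometric_tail(x + 1, N, K, k) else 0
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
  # against base R
  expect_equal(hypergeometric_tail(7, 200, 50, 30),
               stats::phyper(6, 50, 150, 30, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(hypergeometric_tail(6, 10, 5, 5), regexp = "inconsistent")
})

test_that("bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.002, 12), 0.024)
  expect_equal(bonferroni(0.2, 12), 1)
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(0, 12))
})
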