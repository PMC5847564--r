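#' Specification of the matched resampling null
#'
#' The empirical enrichment null draws `n_draws` random gene sets matched to
#' the query genes by quantile-bin stratification on coding-sequence length
#' and missense constraint z-score. Genes enter the background pool only with
#' mean coverage strictly above `coverage_min`.
#'
#' @param n_draws Number of null draws, default 10000.
#' @param match_covariates Subset of `c("cds_length", "missense_z")` to match
#'   on; empty means uniform draws from the pool.
#' @param n_length_bins,n_z_bins Quantile bin counts, defaults 10 and 5.
#' @param coverage_min Background eligibility coverage cut (strict `>`).
#' @param seed Integer seed for the draws, or `NULL`.
#' @return A list of parameters.
#' @export
null_spec <- function(n_draws = 10000,
                      match_covariates = c("cds_length", "missense_z"),
                      n_length_bins = 10, n_z_bins = 5,
                      coverage_min = 10, seed = NULL) {
  stopifnot(n_draws >= 1, n_length_bins >= 1, n_z_bins >= 1)
  stopifnot(all(match_covariates %in% c("cds_length", "missense_z")))
  list(n_draws = as.integer(n_draws), match_covariates = match_covariates,
       n_length_bins = as.integer(n_length_bins),
       n_z_bins = as.integer(n_z_bins),
       coverage_min = coverage_min, seed = seed)
}

# quantile bin assignment; breaks are the empirical quantile cut-points
quantile_bins <- function(x, n_bins) {
  if (n_bins <= 1) return(rep(1L, length(x)))
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE))
}

#' Build the covariate-stratified background gene pool
#'
#' Filters the feature table to genes with mean coverage strictly above
#' `coverage_min` and assigns each eligible gene to a stratum formed by the
#' cross of coding-length quantile bins and constraint z-score quantile bins
#' (only the covariates named in `spec$match_covariates` contribute; with no
#' matching covariates there is a single stratum).
#'
#' @param features Gene feature table (see [read_gene_features()]).
#' @param spec See [null_spec()].
#' @return Tibble with `gene`, `cds_length`, `missense_z`, `stratum`.
#' @export
build_background <- function(features, spec = null_spec()) {
  pool <- features[features$mean_coverage > spec$coverage_min, ]
  if (nrow(pool) == 0) {
    rlang::abort("no genes pass the coverage filter; background pool is empty")
  }
  lb <- if ("cds_length" %in% spec$match_covariates) {
    quantile_bins(pool$cds_length, spec$n_length_bins)
  } else rep(1L, nrow(pool))
  zb <- if ("missense_z" %in% spec$match_covariates) {
    quantile_bins(pool$missense_z, spec$n_z_bins)
  } else rep(1L, nrow(pool))
  tibble::tibble(
    gene = pool$gene,
    cds_length = pool$cds_length,
    missense_z = pool$missense_z,
    stratum = as.integer(interaction(lb, zb, drop = FALSE))
  )
}

#' Draw one covariate-matched random gene set
#'
#' For each query gene, one background gene is drawn uniformly from the query
#' gene's stratum, without replacement within the draw; query genes themselves
#' are eligible. When a stratum is exhausted the draw falls back to the
#' nearest non-empty stratum by covariate distance (reported via a
#' `famvar_stratum_fallback` condition).
#'
#' @param query_genes Character vector of query gene symbols; genes absent
#'   from the background are dropped with a warning.
#' @param background Stratified pool from [build_background()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Character vector of drawn genes, same length as the (retained)
#'   query.
#' @export
draw_matched_set <- function(query_genes, background, seed = NULL) {
  local_seed(seed)
  idx <- match(query_genes, background$gene)
  if (anyNA(idx)) {
    rlang::warn(sprintf("%d query gene(s) absent from background pool; excluded",
                        sum(is.na(idx))),
                class = "famvar_query_excluded")
    idx <- idx[!is.na(idx)]
  }
  draw_matched_indices(background$stratum[idx], background, n_rep = 1)[[1]] |>
    (\(i) background$gene[i])()
}

# core sampler: for each replicate, draw one gene index per query stratum,
# without replacement within the replicate. Returns a list of index vectors.
draw_matched_indices <- function(query_strata, background, n_rep) {
  strata_idx <- split(seq_len(nrow(background)), background$stratum)
  need <- table(query_strata)
  # centroids for nearest-stratum fallback
  cent <- vapply(strata_idx, function(ii) {
    c(mean(rank(background$cds_length)[ii]), mean(rank(background$missense_z)[ii]))
  }, numeric(2))
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    drawn <- integer(0)
    crossed <- FALSE  # TRUE once a fallback breached stratum boundaries
    for (s in names(need)) {
      m <- need[[s]]
      avail <- strata_idx[[s]]
      if (crossed) avail <- setdiff(avail, drawn)
      if (length(avail) < m) {
        # exhausted: top up from nearest strata by covariate centroid
        rlang::signal("stratum exhausted; falling back to nearest stratum",
                      class = "famvar_stratum_fallback")
        crossed <- TRUE
        deficit <- m - length(avail)
        ord <- order(colSums((cent - cent[, s])^2))
        for (s2 in names(strata_idx)[ord]) {
          if (deficit == 0) break
          extra <- setdiff(strata_idx[[s2]], c(drawn, avail))
          take <- head(extra, deficit)
          avail <- c(avail, take)
          deficit <- deficit - length(take)
        }
      }
      picked <- if (length(avail) == 1 && m == 1) avail else sample(avail, m)
      drawn <- c(drawn, picked)
    }
    out[[r]] <- drawn
  }
  out
}

#' Empirical matched-resampling enrichment test
#'
#' Tests over-representation of the query genes in a gene set against a null
#' of `spec$n_draws` covariate-matched random gene sets. The observed overlap
#' is `O = |query ∩ set ∩ pool|`; each null overlap is the size of the
#' intersection of one matched draw with the set; the empirical p-value is
#' `(1 + #\{null >= O\}) / (1 + n_draws)`, which is never exactly zero.
#'
#' Each null draw takes, independently per stratum, as many genes as the
#' query holds there, uniformly without replacement; its overlap with the set
#' is therefore a sum of independent hypergeometric counts across strata, and
#' the null overlaps are sampled directly from that distribution. Explicit
#' gene identities for a draw are available from [draw_matched_set()], which
#' realises the same scheme; when any stratum holds fewer genes than the
#' query requires, the explicit sampler (with its nearest-stratum fallback)
#' is used instead.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param gene_set Character vector of gene symbols defining the set.
#' @param background Stratified pool from [build_background()].
#' @param spec See [null_spec()]; its `seed` drives the draws.
#' @param set_name Optional label carried into the result.
#' @return A `famvar_enrichment` object: list with `set_name`, `observed`,
#'   `expected`, `empirical_p`, `n_query_genes`, `n_draws`, `null_mean`,
#'   `null_sd`, `null_max`, and the vector `null_overlap`.
#' @export
empirical_enrichment <- function(query_genes, gene_set, background,
                                 spec = null_spec(), set_name = NA_character_) {
  local_seed(spec$seed)
  query_genes <- unique(query_genes)
  idx <- match(query_genes, background$gene)
  n_excluded <- sum(is.na(idx))
  if (n_excluded > 0) {
    rlang::warn(sprintf("%d query gene(s) absent from background pool; excluded",
                        n_excluded), class = "famvar_query_excluded")
    idx <- idx[!is.na(idx)]
  }
  in_set <- background$gene %in% gene_set
  observed <- sum(in_set[idx])
  q_strata <- background$stratum[idx]
  need <- table(q_strata)
  pool_size <- table(background$stratum)[names(need)]
  if (any(need > pool_size)) {
    # exhausted stratum: realise explicit draws with fallback
    draws <- draw_matched_indices(q_strata, background, n_rep = spec$n_draws)
    null_overlap <- vapply(draws, function(ii) sum(in_set[ii]), integer(1))
  } else {
    set_in_stratum <- tapply(in_set, background$stratum, sum)[names(need)]
    null_overlap <- rep(0L, spec$n_draws)
    for (s in names(need)) {
      null_overlap <- null_overlap +
        stats::rhyper(spec$n_draws, set_in_stratum[[s]],
                      pool_size[[s]] - set_in_stratum[[s]], need[[s]])
    }
  }
  res <- list(
    set_name = set_name,
    observed = observed,
    expected = mean(null_overlap),
    empirical_p = (1 + sum(null_overlap >= observed)) / (1 + spec$n_draws),
    n_query_genes = length(idx),
    n_query_excluded = n_excluded,
    n_draws = spec$n_draws,
    null_mean = mean(null_overlap),
    null_sd = stats::sd(null_overlap),
    null_max = max(null_overlap),
    null_overlap = null_overlap
  )
  structure(res, class = "famvar_enrichment")
}

#' @export
print.famvar_enrichment <- function(x, ...) {
  cat(sprintf(
    "Matched-set enrichment%s: O = %d, E = %.1f, empirical p = %.4g (%d draws, k = %d)\n",
    if (is.na(x$set_name)) "" else paste0(" [", x$set_name, "]"),
    x$observed, x$expected, x$empirical_p, x$n_draws, x$n_query_genes
  ))
  invisible(x)
}

#' Enrichment of a query gene list across several gene sets
#'
#' Runs [empirical_enrichment()] for each set and applies a Bonferroni
#' correction for `m` tests (default: twice the number of sets, reflecting a
#' design that tests each set against two query pools).
#'
#' @param query_genes Character vector of query genes.
#' @param gene_sets Gene-set tibble (see [read_gene_sets()]) or named list of
#'   character vectors.
#' @param background Stratified pool from [build_background()].
#' @param spec See [null_spec()].
#' @param m Number of tests for the Bonferroni correction; `NULL` uses
#'   `2 * length(gene_sets)`.
#' @return Tibble with one row per set: `set_name`, `set_size`, `observed`,
#'   `expected`, `empirical_p`, `corrected_p`, `hypergeom_p`,
#'   `n_query_genes`, `null_sd`, `null_max`.
#' @export
enrich_gene_sets <- function(query_genes, gene_sets, background,
                             spec = null_spec(), m = NULL) {
  if (is.data.frame(gene_sets)) {
    sets <- setNames(gene_sets$genes, gene_sets$name)
  } else {
    sets <- gene_sets
  }
  if (is.null(m)) m <- 2L * length(sets)
  seeds <- if (is.null(spec$seed)) rep(list(NULL), length(sets)) else
    as.list(spec$seed + seq_along(sets) - 1L)
  rows <- purrr::imap(sets, function(genes, nm) {
    sp <- spec
    sp$seed <- seeds[[match(nm, names(sets))]]
    res <- empirical_enrichment(query_genes, genes, background, sp,
                                set_name = nm)
    K <- sum(background$gene %in% genes)
    tibble::tibble(
      set_name = nm,
      set_size = length(genes),
      observed = res$observed,
      expected = res$expected,
      empirical_p = res$empirical_p,
      corrected_p = bonferroni(res$empirical_p, m),
      hypergeom_p = hypergeometric_tail(res$observed, nrow(background), K,
                                        res$n_query_genes),
      n_query_genes = res$n_query_genes,
      null_sd = res$null_sd,
      null_max = res$null_max
    )
  })
  dplyr::bind_rows(rows)
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= O)` for `X ~ Hypergeometric(N, K, k)` — drawing `k` genes from a
#' pool of `N` containing `K` set members — computed by summing log-gamma
#' point masses for numerical stability.
#'
#' @param O Observed overlap (non-negative integer).
#' @param N Pool size.
#' @param K Set members in the pool.
#' @param k Query size.
#' @return The tail probability.
#' @export
hypergeometric_tail <- function(O, N, K, k) {
  stopifnot(length(O) == 1, O >= 0, K >= 0, k >= 0, K <= N, k <= N)
  if (O > min(K, k)) {
    rlang::abort("inconsistent counts: O exceeds min(K, k)")
  }
  support <- max(0, k - (N - K)):min(K, k)
  x <- support[support >= O]
  if (length(x) == 0) return(0)
  logp <- lgamma(K + 1) - lgamma(x + 1) - lgamma(K - x + 1) +
    lgamma(N - K + 1) - lgamma(k - x + 1) - lgamma(N - K - (k - x) + 1) -
    (lgamma(N + 1) - lgamma(k + 1) - lgamma(N - k + 1))
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}

#' Bonferroni correction
#'
#' @param p P-value(s) in `(0, 1]`.
#' @param m Number of tests, default 12.
#' @return `min(1, m * p)`, vectorised over `p`.
#' @export
bonferroni <- function(p, m = 12) {
  stopifnot(m >= 1, all(p > 0 & p <= 1))
  pmin(1, m * p)
}
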