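#' Per-subject burden of rare likely gene-disruptive variants
#'
#' Counts, for every sequenced subject, the number of distinct rare LGD
#' variant sites carried (genotype `het` or `hom_alt`; a homozygous alternate
#' call counts the site once, not twice), together with the subset of those
#' sites in brain-expressed genes. Genes with unknown brain expression are
#' excluded from the brain-restricted count rather than imputed.
#'
#' @param vc Variant-call table annotated by [annotate_variants()] (columns
#'   `rare`, `lgd` and — when `features` was supplied — `brain`).
#' @param ped Pedigree tibble.
#' @return Tibble with one row per sequenced subject: `subject_id`,
#'   `family_id`, `phenotype`, `age_of_onset`, `n_lgd_total`, `n_lgd_brain`.
#' @export
burden_per_subject <- function(vc, ped) {
  stopifnot(all(c("rare", "lgd") %in% names(vc)))
  if (!"brain" %in% names(vc)) vc$brain <- NA
  lgd <- vc[vc$rare & vc$lgd & vc$gt %in% c("het", "hom_alt"), ]
  counts <- lgd |>
    dplyr::distinct(.data$subject_id, .data$variant_id, .data$brain) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_lgd_total = dplyr::n(),
      n_lgd_brain = sum(.data$brain %in% TRUE),
      .groups = "drop"
    )
  ped[ped$sequenced, c("family_id", "id", "phenotype", "age_of_onset")] |>
    dplyr::rename(subject_id = "id") |>
    dplyr::left_join(counts, by = "subject_id") |>
    dplyr::mutate(
      n_lgd_total = dplyr::coalesce(.data$n_lgd_total, 0L),
      n_lgd_brain = dplyr::coalesce(.data$n_lgd_brain, 0L)
    ) |>
    dplyr::relocate("subject_id")
}

#' Mann–Whitney U test (rank-sum), self-contained
#'
#' Computes U from rank sums with average ranks for ties. For small samples
#' (both groups at most `exact_max`) the two-tailed p-value is obtained by
#' exact enumeration of all assignments of the pooled observations to the two
#' groups; otherwise by a normal approximation with tie-corrected variance and
#' a 0.5 continuity correction. `U_x + U_y = n_x * n_y` always holds.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max Largest per-group size for the exact path, default 8.
#' @return A `famvar_ranksum` object: list with `u` (for `x`), `u_y`,
#'   `p_value`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("both groups must be non-empty")
  }
  n1 <- length(x); n2 <- length(y)
  u_of <- function(ranks_x) sum(ranks_x) - n1 * (n1 + 1) / 2
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- u_of(r[seq_len(n1)])
  u2 <- n1 * n2 - u1
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    stat <- abs(colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2 - mu)
    p <- mean(stat >= abs(u1 - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  structure(list(u = u1, u_y = u2, p_value = p, n_x = n1, n_y = n2,
                 method = method),
            class = "famvar_ranksum")
}

#' @export
print.famvar_ranksum <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), two-tailed p = %.4g [%s]\n",
              x$u, x$n_x, x$n_y, x$p_value, x$method))
  invisible(x)
}

#' @export
tidy.famvar_ranksum <- function(x, ...) {
  tibble::tibble(statistic = x$u, p.value = x$p_value,
                 method = paste("Mann-Whitney U,", x$method))
}

#' @export
glance.famvar_ranksum <- function(x, ...) {
  tibble::tibble(statistic = x$u, p.value = x$p_value,
                 n_x = x$n_x, n_y = x$n_y)
}

#' Spearman rank correlation test, self-contained
#'
#' Average-rank transform of both vectors followed by a Pearson correlation on
#' the ranks; the two-tailed p-value uses `t = r_s sqrt((n-2)/(1-r_s^2))` with
#' `n - 2` degrees of freedom. A perfect correlation (`r_s = ±1`), where the
#' t statistic degenerates, is reported with the exact permutation tail
#' `2 / n!` (the two monotone orderings among the `n!` equally likely rank
#' permutations).
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`; constant input is an
#'   error (the correlation is undefined).
#' @return A `famvar_spearman` object: list with `estimate`, `p_value`, `n`,
#'   `method`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) rlang::abort("spearman_test() requires n >= 4")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    rlang::abort("correlation undefined for constant input")
  }
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1 - 1e-12) {
    p <- min(1, 2 * exp(-lfactorial(n)))
    method <- "permutation (degenerate)"
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  structure(list(estimate = rs, p_value = p, n = n, method = method),
            class = "famvar_spearman")
}

#' @export
print.famvar_spearman <- function(x, ...) {
  cat(sprintf("Spearman r_s = %.3f (n = %d), two-tailed p = %.4g [%s]\n",
              x$estimate, x$n, x$p_value, x$method))
  invisible(x)
}

#' @export
tidy.famvar_spearman <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, p.value = x$p_value,
                 method = paste("Spearman,", x$method))
}

#' @export
glance.famvar_spearman <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, p.value = x$p_value, n = x$n)
}

#' Burden comparison between affected and unaffected relatives
#'
#' Rank-sum comparison of total rare-LGD burden between affected subjects
#' (strict scheme by default) and the remaining sequenced relatives.
#'
#' @param profiles Burden table from [burden_per_subject()].
#' @param scheme Affection scheme for the affected group.
#' @param include_married_in Should married-in unaffected parents enter the
#'   comparison group? Default `TRUE`.
#' @param which `"total"` or `"brain"`: which burden column to compare.
#' @return A `famvar_ranksum` object with means attached as attributes
#'   `mean_affected` / `mean_unaffected`.
#' @export
burden_group_test <- function(profiles, scheme = affection_scheme("strict"),
                              include_married_in = TRUE,
                              which = c("total", "brain")) {
  which <- match.arg(which)
  col <- if (which == "total") "n_lgd_total" else "n_lgd_brain"
  status <- affection_status(profiles$phenotype, scheme)
  keep <- !is.na(status)
  if (!include_married_in && "married_in" %in% names(profiles)) {
    keep <- keep & !(profiles$married_in & status == "unaffected")
  }
  a <- profiles[[col]][keep & status == "affected"]
  u <- profiles[[col]][keep & status == "unaffected"]
  res <- mann_whitney_u(a, u)
  attr(res, "mean_affected") <- mean(a)
  attr(res, "mean_unaffected") <- mean(u)
  res
}

#' Age-of-onset versus brain-expressed disruptive burden
#'
#' Restricts burden profiles to affected subjects under the broad scheme
#' (which includes recurrent unipolar depression) with age of onset inside the
#' typical-onset window, and correlates onset with the brain-expressed LGD
#' burden by Spearman rank correlation.
#'
#' @param profiles Burden table from [burden_per_subject()].
#' @param scheme Affection scheme, default broad.
#' @param onset_window Inclusive onset window in years, default `c(15, 50)`.
#' @return Tibble with one row: `r_s`, `p_value`, `n`.
#' @export
onset_burden_analysis <- function(profiles,
                                  scheme = affection_scheme("broad"),
                                  onset_window = c(15, 50)) {
  status <- affection_status(profiles$phenotype, scheme)
  keep <- !is.na(status) & status == "affected" &
    !is.na(profiles$age_of_onset) &
    profiles$age_of_onset >= onset_window[1] &
    profiles$age_of_onset <= onset_window[2]
  d <- profiles[keep, ]
  if (nrow(d) < 4) {
    rlang::abort(sprintf(
      "only %d subjects remain after onset/affection filtering (need >= 4)",
      nrow(d)
    ))
  }
  res <- spearman_test(d$age_of_onset, d$n_lgd_brain)
  tibble::tibble(r_s = res$estimate, p_value = res$p_value, n = res$n)
}
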