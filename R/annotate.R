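#' Variant filter and score thresholds
#'
#' Defaults follow the analysis design: rarity requires minor allele frequency
#' below 1% in every population panel supplied; missense variants are
#' predicted pathogenic at a combined PolyPhen-2/SIFT (CAROL) score of at
#' least 0.99; genes enter the enrichment background with mean coverage above
#' 10-fold; a gene counts as brain expressed when its mean RPKM exceeds 1.
#'
#' @param maf_max Maximum population minor allele frequency (strict `<`).
#' @param carol_min Minimum CAROL score for missense candidacy (`>=`).
#' @param coverage_min Minimum mean fold coverage for background eligibility
#'   (strict `>`).
#' @param rpkm_min Brain-expression RPKM cut (strict `>`).
#' @return A list of thresholds.
#' @export
annotation_thresholds <- function(maf_max = 0.01, carol_min = 0.99,
                                  coverage_min = 10, rpkm_min = 1.0) {
  stopifnot(maf_max > 0, maf_max <= 1, carol_min >= 0, carol_min <= 1,
            coverage_min >= 0, rpkm_min >= 0)
  list(maf_max = maf_max, carol_min = carol_min,
       coverage_min = coverage_min, rpkm_min = rpkm_min)
}

#' Is a variant rare in every population panel?
#'
#' A variant is rare when its allele frequency is strictly below `maf_max` in
#' every supplied panel. Panels with missing frequency are treated as 0 (a
#' novel variant is by definition rare), so a variant absent from all panels
#' is rare vacuously.
#'
#' @param af Numeric vector of per-panel allele frequencies (may be empty or
#'   contain `NA` for panels without an entry).
#' @param maf_max Rarity threshold, default 0.01.
#' @return Single logical.
#' @export
#' @examples
#' is_rare(c(evs = 0.005, kg = 0.02))   # FALSE: fails one panel
#' is_rare(numeric(0))                  # TRUE: novel variant
is_rare <- function(af, maf_max = 0.01) {
  stopifnot(all(is.na(af) | (af >= 0 & af <= 1)))
  af <- af[!is.na(af)]
  all(af < maf_max)
}

#' Most damaging consequence among overlapping gene models
#'
#' Returns the maximum of the input under the severity order
#' nonsense > frameshift_indel > canonical_splice > start_lost > missense >
#' synonymous > other (see [CONSEQUENCES]).
#'
#' @param consequences Non-empty character vector of consequence classes.
#' @return The single worst class.
#' @export
worst_consequence <- function(consequences) {
  if (length(consequences) == 0) {
    rlang::abort("worst_consequence() requires a non-empty list")
  }
  idx <- match(consequences, CONSEQUENCES)
  if (anyNA(idx)) {
    rlang::abort(sprintf("unknown consequence class: %s",
                         paste(consequences[is.na(idx)], collapse = ", ")))
  }
  CONSEQUENCES[min(idx)]
}

#' Combined PolyPhen-2/SIFT pathogenicity (CAROL) score
#'
#' Weighted-Z combination of the two predictors on a common damaging scale:
#' PolyPhen-2 is used as-is and SIFT is reversed (`1 - sift`), both clipped to
#' `[eps, 1 - eps]` to keep the normal quantile finite; the probit-transformed
#' scores are combined as `Z = (w1 z1 + w2 z2) / sqrt(w1^2 + w2^2)` and mapped
#' back through the normal CDF. Equal weights by default. When exactly one
#' score is available its weight alone is used (the combination degenerates to
#' the single transformed score); when both are missing the result is `NA`.
#' The score is monotone increasing in `polyphen2` and decreasing in `sift`.
#'
#' @param polyphen2,sift Numeric vectors in `[0, 1]` (recycled to a common
#'   length); `NA` marks a missing score.
#' @param weights Length-2 positive weights for (PolyPhen-2, reversed SIFT).
#' @param eps Clipping constant for degenerate scores, default `1e-8`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
#' @examples
#' carol_score(1.0, 0.0)    # both maximally damaging: ~1
#' carol_score(0.95, 0.02)
carol_score <- function(polyphen2, sift, weights = c(1, 1), eps = 1e-8) {
  n <- max(length(polyphen2), length(sift))
  polyphen2 <- rep_len(polyphen2, n)
  sift <- rep_len(sift, n)
  ok <- function(x) is.na(x) | (x >= 0 & x <= 1)
  if (!all(ok(polyphen2)) || !all(ok(sift))) {
    rlang::abort("scores must lie in [0, 1]")
  }
  stopifnot(length(weights) == 2, all(weights > 0), eps > 0, eps < 0.5)
  clip <- function(x) pmin(pmax(x, eps), 1 - eps)
  z1 <- qnorm(clip(polyphen2))
  z2 <- qnorm(clip(1 - sift))
  w1 <- ifelse(is.na(z1), 0, weights[1])
  w2 <- ifelse(is.na(z2), 0, weights[2])
  z1 <- ifelse(is.na(z1), 0, z1)
  z2 <- ifelse(is.na(z2), 0, z2)
  denom <- sqrt(w1^2 + w2^2)
  out <- pnorm((w1 * z1 + w2 * z2) / denom)
  out[denom == 0] <- NA_real_
  out
}

#' Is a consequence class likely gene-disruptive (LGD)?
#'
#' LGD classes are nonsense, frameshift indel, canonical splice and
#' start-lost. LGD status is a consequence class, not a score: a missense
#' variant is never LGD however damaging its CAROL score.
#'
#' @param consequence Character vector of consequence classes.
#' @return Logical vector.
#' @export
is_lgd <- function(consequence) {
  consequence %in% c("nonsense", "frameshift_indel", "canonical_splice",
                     "start_lost")
}

#' Is a gene brain expressed?
#'
#' `TRUE` when the gene's mean brain RPKM strictly exceeds `rpkm_min`,
#' `FALSE` when it does not, and `NA` (unknown, distinct from `FALSE`) when
#' the gene is absent from the feature table.
#'
#' @param gene Character vector of gene symbols.
#' @param features Gene feature table (see [read_gene_features()]).
#' @param rpkm_min Expression cut, default 1.
#' @return Logical vector with `NA` for unknown genes.
#' @export
is_brain_expressed <- function(gene, features, rpkm_min = 1.0) {
  rpkm <- features$brain_rpkm[match(gene, features$gene)]
  rpkm > rpkm_min
}

#' Annotate a variant table with rarity, pathogenicity and expression flags
#'
#' Adds site-level columns to a variant-call (or site) table:
#' \describe{
#'   \item{rare}{allele frequency below `maf_max` in every `af_*` column;
#'     missing frequencies count as 0.}
#'   \item{carol}{combined PolyPhen-2/SIFT score (see [carol_score()]).}
#'   \item{lgd}{likely gene-disruptive consequence class.}
#'   \item{path_candidate}{rare and (LGD, or missense with
#'     `carol >= carol_min`); the potentially pathogenic pool.}
#'   \item{brain}{gene brain expressed (`NA` = unknown); only added when
#'     `features` is supplied.}
#' }
#'
#' @param vc Variant-call or site table with the columns produced by
#'   [read_variants()].
#' @param features Optional gene feature table for the brain flag.
#' @param thresholds See [annotation_thresholds()].
#' @return `vc` with the flag columns appended.
#' @export
annotate_variants <- function(vc, features = NULL,
                              thresholds = annotation_thresholds()) {
  af_cols <- grep("^af_", names(vc), value = TRUE)
  if (length(af_cols) == 0) {
    rare <- rep(TRUE, nrow(vc))
  } else {
    af <- as.matrix(vc[, af_cols])
    af[is.na(af)] <- 0
    rare <- rowSums(af >= thresholds$maf_max) == 0
  }
  out <- dplyr::mutate(
    vc,
    rare = rare,
    carol = carol_score(.data$polyphen2, .data$sift),
    lgd = is_lgd(.data$consequence),
    path_candidate = rare & (is_lgd(.data$consequence) |
      (.data$consequence == "missense" &
         !is.na(carol_score(.data$polyphen2, .data$sift)) &
         carol_score(.data$polyphen2, .data$sift) >= thresholds$carol_min))
  )
  if (!is.null(features)) {
    out$brain <- is_brain_expressed(out$gene, features, thresholds$rpkm_min)
  }
  out
}
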