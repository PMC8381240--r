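#' Median-of-ratios size factors
#'
#' Library-size scaling for count matrices: each sample's factor is the
#' median ratio of its counts to the per-feature geometric mean, computed
#' over features with all-positive counts. When any sample has fewer than
#' 50% nonzero features (common on tiny matrices), all samples fall back to
#' total-count scaling normalised to geometric mean 1.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 1L)
  frac_nonzero <- colMeans(counts > 0)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  use_total <- any(frac_nonzero < 0.5) || sum(all_pos) < 1L
  if (use_total) {
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total count", call. = FALSE)
    sf <- tot / exp(mean(log(tot)))
  } else {
    logref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- apply(counts[all_pos, , drop = FALSE], 2L, function(x) {
      exp(stats::median(log(x) - logref))
    })
  }
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion per feature
#'
#' On size-factor-scaled counts, pools within-group means and variances and
#' solves `var = mean + dispersion * mean^2` for each feature. Estimates
#' below `floor` (including negative ones, which arise under Poisson-like
#' noise) are floored.
#'
#' @param counts Feature x sample count matrix.
#' @param groups Group label per sample (two or more groups, >= 2 samples
#'   each).
#' @param sf Optional size factors (computed if `NULL`).
#' @param floor Minimum dispersion (default 1e-8).
#' @return Named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, groups, sf = NULL, floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts))
  if (any(table(groups) < 2L)) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  x <- sweep(counts, 2L, sf, "/")
  num <- 0; den <- 0
  for (idx in split(seq_along(groups), groups)) {
    m <- rowMeans(x[, idx, drop = FALSE])
    v <- rowVars_(x[, idx, drop = FALSE])
    w <- length(idx) - 1L
    num <- num + (v - m) * w
    den <- den + m^2 * w
  }
  disp <- num / pmax(den, .Machine$double.xmin)
  stats::setNames(pmax(disp, floor), rownames(counts))
}

rowVars_ <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A documented, calibrated substitute for a full shrinkage-based NB GLM.
#' Per feature, counts are scaled by median-of-ratios size factors; the
#' log2 fold change is `log2((m2 + pc) / (m1 + pc))` on scaled group means;
#' its variance comes from the delta method under the NB mean-variance
#' relation with a moderated dispersion (per-feature method-of-moments
#' estimate shrunk toward the common median with prior weight
#' `dispersion_prior_df`); the two-sided p-value uses the normal reference,
#' and Benjamini-Hochberg adjustment runs across tested features. Features
#' with all-zero counts in both groups are excluded from testing and
#' reported with `p_value = fdr = 1`.
#'
#' @param counts Feature x sample count matrix (rownames = feature names).
#' @param groups Two-group label per sample; the first level (factor order,
#'   or order of appearance) is the reference, so `log2fc` is group 2 versus
#'   group 1.
#' @param pseudocount Added to scaled group means (default 0.5).
#' @param dispersion_prior_df Prior degrees of freedom pulling per-feature
#'   dispersions toward the common value (default 10).
#' @return Data frame: `feature`, `mean_1`, `mean_2` (scaled), `log2fc`,
#'   `p_value`, `fdr`, `tested`.
#' @export
nb_wald_test <- function(counts, groups, pseudocount = 0.5,
                         dispersion_prior_df = 10) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("feature", seq_len(nrow(counts)))
  }
  lev <- if (is.factor(groups)) levels(droplevels(groups))
         else unique(as.character(groups))
  groups <- as.character(groups)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  idx1 <- which(groups == lev[1]); idx2 <- which(groups == lev[2])
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  sf <- size_factors(counts)
  x <- sweep(counts, 2L, sf, "/")
  tested <- rowSums(counts) > 0
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  log2fc <- ifelse(tested, log2((m2 + pseudocount) / (m1 + pseudocount)), 0)
  p <- rep(1, nrow(counts))
  if (any(tested)) {
    a_i <- estimate_dispersion(counts[tested, , drop = FALSE], groups,
                               sf = sf)
    a_common <- stats::median(a_i)
    df_i <- (length(idx1) - 1L) + (length(idx2) - 1L)
    a <- (dispersion_prior_df * a_common + df_i * a_i) /
      (dispersion_prior_df + df_i)
    mm1 <- m1[tested] + pseudocount
    mm2 <- m2[tested] + pseudocount
    v1 <- (mm1 + a * mm1^2) / (length(idx1) * mm1^2 * log(2)^2)
    v2 <- (mm2 + a * mm2^2) / (length(idx2) * mm2^2 * log(2)^2)
    z <- log2fc[tested] / sqrt(v1 + v2)
    p[tested] <- 2 * stats::pnorm(-abs(z))
  }
  fdr <- rep(1, nrow(counts))
  fdr[tested] <- bh_adjust(p[tested])
  data.frame(feature = rownames(counts), mean_1 = m1, mean_2 = m2,
             log2fc = log2fc, p_value = p, fdr = fdr, tested = tested,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return FDR values in the original order, bounded in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression filter profiles
#'
#' Two selection rules: the `"genes"` profile keeps features with
#' FDR < 0.05 and |fold change| > 2 (i.e. |log2fc| > 1); the
#' `"retroelements"` profile keeps loci with FDR < 0.05 only.
#'
#' @param name `"genes"` or `"retroelements"`.
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_fold_change Two-sided fold-change threshold (genes profile
#'   only; `NA` disables it).
#' @return List of class `de_profile`.
#' @export
de_profile <- function(name = c("genes", "retroelements"), fdr_max = 0.05,
                       min_fold_change = if (name == "genes") 2 else NA) {
  name <- match.arg(name)
  stopifnot(fdr_max > 0, fdr_max < 1)
  structure(list(name = name, fdr_max = fdr_max,
                 min_fold_change = min_fold_change),
            class = "de_profile")
}

#' Which results pass a filter profile
#'
#' @param results Data frame from [nb_wald_test()] (needs `fdr`, `log2fc`).
#' @param profile A [de_profile()] or a profile name.
#' @return Logical vector over rows of `results`.
#' @export
de_passes <- function(results, profile) {
  if (is.character(profile)) profile <- de_profile(profile)
  pass <- results$fdr < profile$fdr_max
  if (!is.na(profile$min_fold_change)) {
    pass <- pass & abs(results$log2fc) > log2(profile$min_fold_change)
  }
  pass
}

#' Filter differential-expression results with a profile
#'
#' @inheritParams de_passes
#' @return The rows of `results` surviving the profile.
#' @export
apply_de_filter <- function(results, profile) {
  results[de_passes(results, profile), , drop = FALSE]
}
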