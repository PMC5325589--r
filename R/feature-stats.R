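# Two-round PCA variable-selection workflow over per-cell imaging
# features, plus a contract-level two-factor group-comparison wrapper.

#' Principal component analysis of a per-cell feature table
#'
#' One PCA round over the numeric feature columns. Features are centered
#' and, by default, scaled to unit variance (the per-cell variables mix
#' indices, percentages, counts and volumes on incommensurate scales).
#' Constant columns cannot be standardized and raise an error naming the
#' offending column.
#'
#' @param table data.frame; non-numeric columns (labels) are ignored.
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @return A list: `loadings` (variables x components, orthonormal),
#'   `scores` (rows x components), `explained` (variance fractions,
#'   non-increasing, summing to 1), `eigenvalues`.
#' @export
pca_round <- function(table, standardize = TRUE) {
  num <- table[vapply(table, is.numeric, logical(1))]
  stop_if_not(ncol(num) >= 2, "need >= 2 numeric feature columns")
  stop_if_not(nrow(num) >= 2, "need >= 2 rows")
  stop_if_not(!anyNA(num), "missing values are barred; impute explicitly")
  sds <- vapply(num, stats::sd, numeric(1))
  if (standardize && any(sds == 0)) {
    stop("constant column cannot be standardized: ",
         paste(names(num)[sds == 0], collapse = ", "), call. = FALSE)
  }
  p <- stats::prcomp(num, center = TRUE, scale. = standardize)
  ev <- p$sdev^2
  list(loadings = p$rotation, scores = p$x, explained = ev / sum(ev),
       eigenvalues = ev)
}

#' Rank and select variables from PCA loadings
#'
#' Variables are ranked by their maximum absolute loading across the
#' leading components whose cumulative explained variance first exceeds
#' `cum_threshold` (at least one component is always used); the top
#' `n_keep` are returned together with the component on which each
#' achieves its maximum (its "attribution"). Invariant to sign flips of
#' the loadings.
#'
#' @param loadings Variables x components loading matrix.
#' @param explained Explained-variance fractions per component.
#' @param n_keep Number of variables to keep (<= number of variables).
#' @param cum_threshold Cumulative explained-variance cutoff selecting
#'   how many leading components inform the ranking (default 0.55).
#' @return data.frame ordered by rank: `variable`, `component`
#'   (attribution), `max_abs_loading`.
#' @export
select_variables <- function(loadings, explained, n_keep,
                             cum_threshold = 0.55) {
  stop_if_not(n_keep <= nrow(loadings),
              "n_keep exceeds the number of variables")
  n_comp <- max(1L, which(cumsum(explained) >= cum_threshold)[1])
  if (is.na(n_comp)) n_comp <- length(explained)
  l <- abs(loadings[, seq_len(n_comp), drop = FALSE])
  max_load <- apply(l, 1, max)
  attribution <- apply(l, 1, which.max)
  ord <- order(-max_load)
  out <- data.frame(variable = rownames(loadings)[ord],
                    component = attribution[ord],
                    max_abs_loading = max_load[ord],
                    stringsAsFactors = FALSE)
  out[seq_len(n_keep), , drop = FALSE]
}

#' Two-factor comparison of component scores
#'
#' Contract-level wrapper around the standard two-factor analysis of
#' variance on (first-)component scores, with step-down
#' multiplicity-adjusted pairwise comparisons within each factor
#' (\pkg{emmeans} contrasts; Holm step-down adjustment by default, the
#' conservative equivalent of step-down Sidak procedures).
#'
#' @param scores Numeric vector of component scores (one per sample).
#' @param group_labels data.frame with two factor columns, or a factor
#'   (one-factor fallback is rejected: two groups minimum per factor is
#'   required for the two-factor design).
#' @param alpha Significance level for flags (default 0.05).
#' @param adjust Multiplicity adjustment passed to \pkg{emmeans}
#'   (default `"holm"`).
#' @return A list: `anova` (the two-way ANOVA table) and `pairwise`
#'   (data.frame of contrasts: `factor`, `contrast`, `estimate`,
#'   `p_adjusted`, `significant`).
#' @export
component_score_test <- function(scores, group_labels, alpha = 0.05,
                                 adjust = "holm") {
  group_labels <- as.data.frame(group_labels)
  stop_if_not(ncol(group_labels) == 2,
              "group_labels must supply exactly two factors")
  f1 <- factor(group_labels[[1]])
  f2 <- factor(group_labels[[2]])
  stop_if_not(nlevels(f1) >= 2 && nlevels(f2) >= 2,
              "need >= 2 groups per factor")
  counts <- table(f1, f2)
  stop_if_not(all(counts >= 3), "need >= 3 samples per group")
  dat <- data.frame(score = scores, f1 = f1, f2 = f2)
  fit <- stats::aov(score ~ f1 * f2, data = dat)
  pairwise <- do.call(rbind, lapply(c("f1", "f2"), function(f) {
    emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", f)))
    ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = adjust))
    data.frame(factor = if (f == "f1") names(group_labels)[1] else
                 names(group_labels)[2],
               contrast = ct$contrast, estimate = ct$estimate,
               p_adjusted = ct$p.value,
               significant = ct$p.value < alpha,
               stringsAsFactors = FALSE)
  }))
  list(anova = summary(fit), pairwise = pairwise)
}

#' Two-round PCA variable-selection workflow
#'
#' Round 1: PCA over the full feature table; components with eigenvalue
#' above 1 on standardized data (the Kaiser rule) are deemed informative.
#' The top `n_keep` variables by leading-component loadings are selected
#' and a second PCA is run over them. The round-2 first-component score
#' per cell is the global readout used for group comparison.
#'
#' @param table Per-cell feature data.frame (numeric feature columns plus
#'   optional label columns, which are carried into the result).
#' @param n_keep Number of variables to select for round 2 (default 11).
#' @param cum_threshold Passed to [select_variables()].
#' @param standardize Passed to [pca_round()].
#' @return A list: `round1`, `round2` (both [pca_round()] results),
#'   `selected` (the [select_variables()] table), `n_informative`
#'   (Kaiser-rule component count in round 1), `component1_score`
#'   (numeric per-cell score from round 2).
#' @export
pca_two_round <- function(table, n_keep = 11, cum_threshold = 0.55,
                          standardize = TRUE) {
  r1 <- pca_round(table, standardize = standardize)
  sel <- select_variables(r1$loadings, r1$explained, n_keep, cum_threshold)
  n_informative <- sum(r1$eigenvalues > 1)
  r2 <- pca_round(table[, sel$variable, drop = FALSE],
                  standardize = standardize)
  list(round1 = r1, round2 = r2, selected = sel,
       n_informative = n_informative,
       component1_score = r2$scores[, 1])
}
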