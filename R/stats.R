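#' Wilcoxon-Mann-Whitney rank-sum p-value
#'
#' Two-sample rank-sum test using the tie- and continuity-corrected normal
#' approximation
#' (appropriate at the sample sizes arising here: 21 data windows vs
#' thousands of surrogate windows, or handfuls of subjects per group).
#'
#' @param a,b Nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger
#'   than b) or `"less"`.
#' @return p-value.
#' @export
rank_sum <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("empty sample")
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                      exact = FALSE,
                                      correct = TRUE)$p.value)
}

#' Kruskal-Wallis test across several groups
#'
#' Nonparametric one-way comparison (tie-corrected H statistic,
#' chi-square reference).
#'
#' @param groups List of two or more nonempty numeric samples.
#' @return p-value.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(!lengths(groups)))
    stop("need >= 2 nonempty groups")
  if (length(unique(unlist(groups))) == 1L) return(1)
  stats::kruskal.test(groups)$p.value
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure: with ordered p-values `p(1) <= ... <= p(m)`, reject
#' all hypotheses up to the largest k with `p(k) <= k * q / m`.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return Logical rejection flags in the original order.
#' @export
bh_fdr <- function(pvals, q) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH") <= q
}

#' AUROC effect size of two samples
#'
#' The probability that a value drawn from `b` exceeds one drawn from `a`,
#' counting ties as 1/2: `U / (n_a * n_b)`. 0.5 means the score
#' distributions are identical; 1 means every value of `b` exceeds every
#' value of `a`; 0 the reverse.
#'
#' @param a Reference sample.
#' @param b Tested sample.
#' @return Effect size in [0, 1].
#' @export
auroc <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  r <- rank(c(a, b))
  u_b <- sum(r[(length(a) + 1):length(r)]) - length(b) * (length(b) + 1) / 2
  u_b / (length(a) * length(b))
}

#' Per-node group comparison with FDR control and effect-size gating
#'
#' For each node (column), compares the two cohorts with [rank_sum()],
#' applies Benjamini-Hochberg control over the nodes at level `q`, and
#' computes the AUROC of the tested cohort against the reference. A node is
#' `reported` when its FDR flag is set and its effect size clears the
#' bound: AUROC < `auroc_bounds[1]` or > `auroc_bounds[2]` for a two-sided
#' comparison, AUROC > `auroc_bounds[2]` for `alternative = "greater"`
#' (and symmetrically for `"less"`).
#'
#' @param reference subjects x nodes matrix of per-node values in the
#'   reference cohort (e.g. day 0).
#' @param tested subjects x nodes matrix for the tested cohort (same node
#'   count).
#' @param alternative Sidedness of the rank-sum test, referring to the
#'   tested cohort relative to the reference.
#' @param q FDR level (default 0.1).
#' @param auroc_bounds Effect-size gates (default `c(0.2, 0.8)`).
#' @return data.frame with `node`, `p`, `fdr_flag`, `auroc`, `reported`.
#' @export
compare_nodes <- function(reference, tested,
                          alternative = c("two.sided", "greater", "less"),
                          q = 0.1, auroc_bounds = c(0.2, 0.8)) {
  alternative <- match.arg(alternative)
  reference <- as.matrix(reference); tested <- as.matrix(tested)
  if (ncol(reference) != ncol(tested)) stop("node-count mismatch")
  n_nodes <- ncol(reference)
  p <- vapply(seq_len(n_nodes), function(i)
    rank_sum(tested[, i], reference[, i], alternative), numeric(1))
  flags <- bh_fdr(p, q)
  es <- vapply(seq_len(n_nodes), function(i)
    auroc(reference[, i], tested[, i]), numeric(1))
  effect_ok <- switch(alternative,
    two.sided = es < auroc_bounds[1] | es > auroc_bounds[2],
    greater = es > auroc_bounds[2],
    less = es < auroc_bounds[1])
  data.frame(node = seq_len(n_nodes), p = p, fdr_flag = flags, auroc = es,
             reported = flags & effect_ok)
}
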