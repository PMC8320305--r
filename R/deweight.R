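# Permutation weighting of external differentially-expressed gene lists:
# are a DE list's genes more positively or negatively weighted on the
# selected PLS component than same-size random gene sets?

#' Filter a DE list by absolute fold change
#'
#' Keeps entries with absolute linear fold change strictly greater than the
#' threshold. Log2 inputs are converted via `2^|lfc|` before comparison; the
#' scale must be declared (a `fold_change` column is linear, a `log2fc`
#' column is log2).
#'
#' @param de_list data.frame with a `gene` column and either `fold_change`
#'   (signed, linear) or `log2fc`.
#' @param threshold Linear fold-change threshold (default 1.5, strict `>`).
#' @return The filtered data.frame.
#' @export
fold_change_filter <- function(de_list, threshold = 1.5) {
  assert_that("gene" %in% names(de_list), "de_list needs a gene column")
  if ("fold_change" %in% names(de_list)) {
    fc <- abs(de_list$fold_change)
  } else if ("log2fc" %in% names(de_list)) {
    fc <- 2^abs(de_list$log2fc)
  } else {
    stop_ironmap("fold-change scale undeclared: need a fold_change or log2fc column",
                 "ironmap_configuration_error")
  }
  assert_that(all(fc != 0), "fold changes must be non-zero")
  de_list[fc > threshold, , drop = FALSE]
}

#' Permutation test of a DE list's mean PLS weight
#'
#' DE genes are matched to the weight universe (case-insensitive symbols;
#' unmatched genes dropped and counted). The observed statistic is the mean
#' weight of the matched genes (or mean bootstrap z with
#' `statistic = "z"`); the null is `n_perm` uniform same-size draws from the
#' whole universe. `p_up = (1 + #\{null >= obs\}) / (n_perm + 1)`; `p_down`
#' analogous with `<=`.
#'
#' @param de_genes Character vector of DE gene ids.
#' @param gene_weights Gene-weight table (columns `gene`, `weight`, `z`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param statistic "weight" (default) or "z".
#' @return List: observed, null_mean, null_sd, p_up, p_down, n_matched,
#'   n_dropped.
#' @export
weight_permutation_test <- function(de_genes, gene_weights, n_perm = 10000L,
                                    seed = 1L,
                                    statistic = c("weight", "z")) {
  statistic <- match.arg(statistic)
  assert_that(all(c("gene", statistic) %in% names(gene_weights)),
              "gene_weights needs gene and %s columns", statistic = statistic)
  w <- gene_weights[[statistic]]
  names(w) <- toupper(gene_weights$gene)
  matched <- unique(toupper(de_genes))
  matched <- matched[matched %in% names(w)]
  n_dropped <- length(unique(toupper(de_genes))) - length(matched)
  if (length(matched) < 5L) {
    stop_ironmap("fewer than 5 DE genes matched the weight universe (%d)",
                 "ironmap_sample_size_error", length(matched))
  }
  m <- length(matched)
  obs <- mean(w[matched])
  null <- local_seed(seed, {
    idx <- matrix(sample.int(length(w), n_perm * m, replace = TRUE), n_perm, m)
    rowMeans(matrix(w[idx], n_perm, m))
  })
  list(
    observed = obs, null_mean = mean(null), null_sd = stats::sd(null),
    p_up = (1 + sum(null >= obs)) / (n_perm + 1),
    p_down = (1 + sum(null <= obs)) / (n_perm + 1),
    n_matched = m, n_dropped = n_dropped
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_comparisons Number of comparisons in the family (>= 1).
#' @return `alpha / n_comparisons`.
#' @examples
#' bonferroni_threshold(0.05, 22) # ~0.0023
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_comparisons) {
  assert_that(n_comparisons >= 1, "n_comparisons must be at least 1")
  alpha / n_comparisons
}
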