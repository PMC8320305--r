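# Over-representation analysis of significant gene lists against a gene-set
# collection, with term-size filtering and the random / spatial-spin
# null-control reruns of the full ranking chain.

#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= k)` where `k` is the overlap between target and term, drawing
#' `|target|` genes from a background of size `N` containing `|term ∩
#' background|` term genes. The term is intersected with the background
#' first; the target must be contained in the background.
#'
#' @param target,term,background Character vectors of gene ids.
#' @return The p-value.
#' @export
hypergeometric_test <- function(target, term, background) {
  target <- unique(target); background <- unique(background)
  term <- unique(term)
  if (!all(target %in% background)) {
    stop_ironmap("target genes outside the background set",
                 "ironmap_invalid_argument")
  }
  term <- intersect(term, background)
  k <- length(intersect(target, term))
  stats::phyper(k - 1, length(term), length(background) - length(term),
                length(target), lower.tail = FALSE)
}

#' Over-representation analysis against a gene-set collection
#'
#' @param target Character vector of gene ids (subset of background).
#' @param collection An `ironmap_genesets` (see [read_gmt()]) or named list
#'   of gene-id vectors.
#' @param background Character vector: the gene universe (by this package's
#'   convention, all genes that entered the PLS).
#' @return data.frame of class `ironmap_enrichment`: term_id, term_name,
#'   overlap, term_size (within background), target_size, background_size,
#'   p.
#' @export
ora_test <- function(target, collection, background) {
  sets <- as_geneset_list(collection)
  target <- unique(target); background <- unique(background)
  assert_that(length(target) > 0, "empty target list",
              class = "ironmap_empty_input_error")
  if (!all(target %in% background)) {
    stop_ironmap("target genes outside the background set",
                 "ironmap_invalid_argument")
  }
  rows <- lapply(names(sets$members), function(id) {
    term <- intersect(sets$members[[id]], background)
    data.frame(
      term_id = id, term_name = sets$names[[id]] %||% id,
      overlap = length(intersect(target, term)), term_size = length(term),
      target_size = length(target), background_size = length(background),
      p = stats::phyper(length(intersect(target, term)) - 1, length(term),
                        length(background) - length(term), length(target),
                        lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ironmap_enrichment", "data.frame")
  out
}

#' Adjust and filter an enrichment table
#'
#' Multiple-testing correction across terms (BH by default, Bonferroni
#' selectable), then terms are kept iff corrected p < alpha and the term
#' size lies in `[min_term_size, max_term_size]` (both bounds inclusive; the
#' default 2500 ceiling discards over-general terms).
#'
#' @param results An `ironmap_enrichment` table.
#' @param alpha Significance threshold on corrected p.
#' @param max_term_size,min_term_size Inclusive size bounds.
#' @param method "BH" or "bonferroni".
#' @return The table with `p_adj` and logical `kept` columns, sorted by p.
#' @export
adjust_and_filter <- function(results, alpha = 0.05, max_term_size = 2500L,
                              min_term_size = 5L,
                              method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  assert_that(nrow(results) > 0, "empty enrichment table",
              class = "ironmap_empty_input_error")
  results$p_adj <- stats::p.adjust(results$p, method = method)
  results$kept <- results$p_adj < alpha &
    results$term_size <= max_term_size & results$term_size >= min_term_size
  results[order(results$p), , drop = FALSE]
}

#' Null-control enrichment rerun
#'
#' Permutes the response map (uniform shuffle for mode "random", one spin
#' draw for mode "spin"), reruns the full PLS -> bootstrap -> FIQT -> split
#' -> ORA chain, and returns the null run's enrichment tables. Used to check
#' that enriched terms are specific to the observed map rather than to
#' gene-gene co-expression or spatial autocorrelation.
#'
#' @param X,y,geometry,K,n_boot,algorithm As in the main chain.
#' @param collection Gene-set collection.
#' @param mode "random" or "spin".
#' @param seed Integer seed (drives both the permutation and the bootstrap).
#' @param alpha Significance threshold for the split and the filter.
#' @param rotation Optional fixed rotation for mode "spin" (e.g. `diag(3)`).
#' @return List: `up` and `down` adjusted enrichment tables (`NULL` where a
#'   direction has no significant genes), plus `permuted_y`.
#' @export
null_control_enrichment <- function(X, y, geometry, collection,
                                    mode = c("random", "spin"), seed = 1L,
                                    K = 2L, n_boot = 1000L, alpha = 0.05,
                                    algorithm = "simpls", rotation = NULL) {
  mode <- match.arg(mode)
  al <- align_xy(X, y)
  yv <- al$y
  yp <- if (mode == "random") {
    local_seed(seed, stats::setNames(sample(yv), names(yv)))
  } else {
    yfull <- rep(NA_real_, geometry$n_regions)
    names(yfull) <- geometry$region_id
    yfull[names(yv)] <- yv
    perm <- spin_permute(geometry, seed = seed, rotation = rotation)
    stats::setNames(yfull[perm], geometry$region_id)[names(yv)]
  }
  tbl <- rank_genes(al$X, yp, K = K, n_boot = n_boot, seed = seed + 1L,
                    algorithm = algorithm)
  sig <- split_significant(tbl, alpha = alpha)
  bg <- tbl$gene
  run <- function(genes) {
    if (!length(genes)) return(NULL)
    adjust_and_filter(ora_test(genes, collection, bg), alpha = alpha)
  }
  list(up = run(sig$up), down = run(sig$down), permuted_y = yp)
}
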