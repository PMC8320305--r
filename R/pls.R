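# Partial least squares regression of the regional QSM score map on the
# region x gene expression matrix, with:
#   * spin-permutation (sphere-rotation) significance for the selected
#     component, preserving spatial autocorrelation;
#   * bootstrap-over-regions gene weight standard errors and z-ratios;
#   * the FDR inverse quantile transformation (winner's-curse shrinkage);
#   * splitting into significantly up-/down-weighted gene lists.

# SIMPLS core for a univariate response. Xs: centred/standardized predictor
# matrix (columns with NA scale must be pre-zeroed), yc: centred response.
# Returns weights W (columns give scores t_a = Xs %*% w_a with unit norm),
# orthonormal score matrix Tn, y-loadings q (t'y), and per-component
# fraction of Y variance explained q_a^2 / ||yc||^2.
pls_simpls_core <- function(Xs, yc, K) {
  n <- nrow(Xs); p <- ncol(Xs)
  K <- min(K, n - 1L, p)
  W <- matrix(0, p, K); Tn <- matrix(0, n, K)
  q <- numeric(K)
  V <- matrix(0, p, K)
  s <- crossprod(Xs, yc)
  ssy <- sum(yc^2)
  a <- 0L
  for (k in seq_len(K)) {
    r <- s
    t <- Xs %*% r
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t <- t / nt; r <- r / nt
    pl <- crossprod(Xs, t)
    qk <- sum(yc * t)
    if (qk < 0) { r <- -r; t <- -t; pl <- -pl; qk <- -qk }
    v <- pl
    if (k > 1L) {
      Vk <- V[, seq_len(k - 1L), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, pl)
    }
    v <- v / sqrt(sum(v^2))
    V[, k] <- v
    s <- s - v %*% crossprod(v, s)
    W[, k] <- r; Tn[, k] <- t; q[k] <- qk
    a <- k
  }
  if (a < K) {
    W <- W[, seq_len(a), drop = FALSE]
    Tn <- Tn[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
  }
  list(weights = W, scores = Tn, yloadings = q,
       varexp_y = if (ssy > 0) q^2 / ssy else rep(0, a), K = a)
}

# NIPALS alternative (config switch). For a univariate response NIPALS
# weights are X'y-proportional with X deflated each round; results differ
# from SIMPLS only in deflation bookkeeping.
pls_nipals_core <- function(Xs, yc, K) {
  n <- nrow(Xs); p <- ncol(Xs)
  K <- min(K, n - 1L, p)
  W <- matrix(0, p, K); Tn <- matrix(0, n, K); q <- numeric(K)
  ssy <- sum(yc^2)
  Xd <- Xs
  a <- 0L
  for (k in seq_len(K)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xd %*% w
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    tu <- t / nt
    qk <- sum(yc * tu)
    if (qk < 0) { w <- -w; tu <- -tu; qk <- -qk }
    pl <- crossprod(Xd, tu)
    Xd <- Xd - tcrossprod(tu, pl)
    W[, k] <- w; Tn[, k] <- tu; q[k] <- qk
    a <- k
  }
  if (a < K) {
    W <- W[, seq_len(a), drop = FALSE]
    Tn <- Tn[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
  }
  list(weights = W, scores = Tn, yloadings = q,
       varexp_y = if (ssy > 0) q^2 / ssy else rep(0, a), K = a)
}

# Align X (regions x genes) with a response that may be a qsm_scores
# data.frame or a named/plain numeric vector; drops NA-score regions
# (pairwise deletion of flagged regions).
align_xy <- function(X, y) {
  assert_that(is.matrix(X) && !is.null(rownames(X)),
              "X must be a matrix with region rownames")
  if (inherits(y, "ironmap_qsm_scores")) {
    yv <- stats::setNames(y$score, y$region_id)
  } else if (!is.null(names(y))) {
    yv <- y
  } else {
    assert_that(length(y) == nrow(X),
                "unnamed y must match nrow(X)", class = "ironmap_key_error")
    yv <- stats::setNames(as.numeric(y), rownames(X))
  }
  common <- intersect(rownames(X), names(yv))
  if (length(common) < length(union(rownames(X), names(yv)))) {
    if (!length(common)) {
      stop_ironmap("X and y share no region ids", "ironmap_key_error")
    }
  }
  yv <- yv[common]
  keep <- !is.na(yv)
  list(X = X[common[keep], , drop = FALSE], y = yv[keep])
}

#' Fit a PLS regression of the QSM score map on regional expression
#'
#' Columns of `X` are standardized (zero mean, unit variance) and `y` is
#' centred; components are extracted by SIMPLS (default) or NIPALS,
#' maximizing covariance with `y`. Each component's sign is flipped so its
#' region scores correlate positively with `y`. Constant expression columns
#' are dropped with a warning. Regions are aligned by id; regions with
#' undefined scores are excluded.
#'
#' @param X Regions x genes matrix with region rownames and gene colnames.
#' @param y QSM score vector: an `ironmap_qsm_scores` data.frame or a named
#'   numeric vector.
#' @param K Number of components (default 2; the component of interest in
#'   this design is the one explaining most response variance).
#' @param algorithm "simpls" or "nipals".
#' @return An `ironmap_pls` object: `weights` (genes x K), `scores`
#'   (regions x K, orthonormal, zero mean), `yloadings`, `varexp_y`
#'   (fraction of Y variance per component), `K`, centring/scaling
#'   parameters, `region_id`, `gene_id`.
#' @export
fit_pls <- function(X, y, K = 2L, algorithm = c("simpls", "nipals")) {
  algorithm <- match.arg(algorithm)
  al <- align_xy(X, y)
  X <- al$X; yv <- al$y
  assert_that(K >= 1 && K <= min(nrow(X) - 1L, ncol(X)),
              "K must be in 1..min(n_regions - 1, n_genes)")
  std <- standardize_columns(X)
  bad <- is.na(std$scale)
  if (any(bad)) {
    warning(sprintf("%d constant expression column(s) dropped", sum(bad)))
    std$x <- std$x[, !bad, drop = FALSE]
    std$center <- std$center[!bad]; std$scale <- std$scale[!bad]
  }
  yc <- yv - mean(yv)
  core <- if (algorithm == "simpls") pls_simpls_core(std$x, yc, K)
          else pls_nipals_core(std$x, yc, K)
  gene_id <- colnames(std$x)
  rownames(core$weights) <- gene_id
  rownames(core$scores) <- rownames(X)
  structure(
    list(weights = core$weights, scores = core$scores,
         yloadings = core$yloadings, varexp_y = core$varexp_y, K = core$K,
         x_center = std$center, x_scale = std$scale, y_center = mean(yv),
         algorithm = algorithm, region_id = rownames(X), gene_id = gene_id,
         y = yv),
    class = "ironmap_pls"
  )
}

#' @export
print.ironmap_pls <- function(x, ...) {
  cat(sprintf("<ironmap_pls> %d regions x %d genes, %d component(s) [%s]\n",
              length(x$region_id), length(x$gene_id), x$K, x$algorithm))
  cat("  Y-variance explained:",
      paste(sprintf("%.3f", x$varexp_y), collapse = ", "), "\n")
  invisible(x)
}

#' Select the response component
#'
#' Index of the component explaining the largest fraction of Y variance;
#' ties break toward the lower index.
#'
#' @param model An `ironmap_pls`.
#' @return Integer component index.
#' @export
select_response_component <- function(model) {
  stopifnot(inherits(model, "ironmap_pls"))
  which.max(model$varexp_y)
}

#' One spin permutation of a spherical parcellation
#'
#' Draws (or takes) a uniform random rotation, rotates all centroids, and
#' relabels each region with the nearest unrotated centroid. Because the
#' assignment is nearest-neighbour, some source regions may be duplicated
#' and others dropped, as in the standard rotation scheme.
#'
#' @param geometry An `ironmap_geometry`.
#' @param seed Optional integer seed for the rotation draw.
#' @param rotation Optional 3x3 rotation matrix (e.g. `diag(3)` for the
#'   identity relabelling); overrides the random draw.
#' @return Integer vector `perm` of length `n_regions`: region `i` takes the
#'   value of original region `perm[i]` (`y_spun = y[perm]`).
#' @export
spin_permute <- function(geometry, seed = NULL, rotation = NULL) {
  stopifnot(inherits(geometry, "ironmap_geometry"))
  rot <- rotation %||% local_seed(seed, random_rotation())
  assert_that(all(dim(rot) == c(3L, 3L)), "rotation must be 3x3",
              class = "ironmap_geometry_error")
  rotated <- geometry$centroids %*% t(rot)
  max.col(tcrossprod(rotated, geometry$centroids), ties.method = "first")
}

#' Spin-permutation test of the selected PLS component
#'
#' The observed statistic is the fraction of Y variance explained by the
#' component picked by `select_response_component()`. For each of `n_perm`
#' sphere rotations the response map is relabelled, the PLS refitted on the
#' same predictors, the component re-selected, and the statistic recorded.
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param X Regions x genes matrix (rownames = region ids present in
#'   `geometry`).
#' @param y QSM score vector (see [fit_pls()]).
#' @param geometry An `ironmap_geometry` covering the regions of `X`.
#' @param K Components per fit.
#' @param n_perm Number of rotations (>= 100; default 10000).
#' @param seed Integer seed.
#' @param algorithm PLS algorithm.
#' @param store_relabellings Keep the n_perm x n_regions relabelling matrix
#'   (memory!); default TRUE.
#' @return An `ironmap_spin` object: `p` (selected component), `p_component`
#'   (per fixed component index), `observed` (per-component varexp),
#'   `selected`, `null_selected` (per-permutation statistic under
#'   re-selection), `null_component` (n_perm x K matrix), `relabellings`.
#' @export
spin_test <- function(X, y, geometry, K = 2L, n_perm = 10000L, seed = 1L,
                      algorithm = c("simpls", "nipals"),
                      store_relabellings = TRUE) {
  algorithm <- match.arg(algorithm)
  assert_that(n_perm >= 100, "n_perm must be at least 100")
  stopifnot(inherits(geometry, "ironmap_geometry"))
  al <- align_xy(X, y)
  assert_that(all(rownames(al$X) %in% geometry$region_id),
              "X regions missing from geometry", class = "ironmap_key_error")
  # Full-geometry response for spinning; regions without data spin too but
  # only surviving rows enter the refit.
  yfull <- rep(NA_real_, geometry$n_regions)
  names(yfull) <- geometry$region_id
  yfull[names(al$y)] <- al$y
  rows <- match(rownames(al$X), geometry$region_id)

  std <- standardize_columns(al$X)
  bad <- is.na(std$scale)
  Xs <- std$x
  if (any(bad)) Xs <- Xs[, !bad, drop = FALSE]
  core_fun <- if (algorithm == "simpls") pls_simpls_core else pls_nipals_core

  yc <- al$y - mean(al$y)
  obs_fit <- core_fun(Xs, yc, K)
  observed <- obs_fit$varexp_y
  selected <- which.max(observed)

  null_comp <- matrix(NA_real_, n_perm, obs_fit$K)
  null_sel <- numeric(n_perm)
  relab <- if (store_relabellings) {
    matrix(NA_integer_, n_perm, geometry$n_regions)
  } else NULL
  local_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- spin_permute(geometry)
      if (store_relabellings) relab[b, ] <- perm
      yp <- yfull[perm][rows]
      ok <- !is.na(yp)
      ypc <- yp[ok] - mean(yp[ok])
      fit <- core_fun(Xs[ok, , drop = FALSE], ypc, K)
      ve <- fit$varexp_y
      null_comp[b, seq_along(ve)] <- ve
      null_sel[b] <- max(ve)
    }
  })
  p_comp <- vapply(seq_len(obs_fit$K), function(k) {
    nk <- null_comp[, k]
    (1 + sum(nk[!is.na(nk)] >= observed[k])) / (n_perm + 1)
  }, 0)
  p_sel <- (1 + sum(null_sel >= observed[selected])) / (n_perm + 1)
  structure(
    list(p = p_sel, p_component = p_comp, observed = observed,
         selected = selected, null_selected = null_sel,
         null_component = null_comp, n_perm = n_perm, seed = seed,
         relabellings = relab),
    class = "ironmap_spin"
  )
}

#' @export
print.ironmap_spin <- function(x, ...) {
  cat(sprintf("<ironmap_spin> %d rotations; selected component %d, p = %.4g\n",
              x$n_perm, x$selected, x$p))
  invisible(x)
}

#' Bootstrap gene-weight standard errors and z-ratios
#'
#' Regions are resampled with replacement and the PLS refitted; the
#' component of interest keeps a fixed index with its replicate weight
#' vector sign-aligned to the original (flipped if the inner product is
#' negative). The gene's z-ratio is its original weight divided by the SD of
#' its replicate weights; a two-sided p comes from the standard normal.
#' Degenerate resamples (a single unique region) are skipped and counted.
#'
#' @param X,y,K,algorithm As in [fit_pls()].
#' @param component Component index; default the selected response
#'   component.
#' @param n_boot Number of bootstrap replicates (>= 100; default 1000).
#' @param seed Integer seed.
#' @param keep_replicates Attach the replicate weight matrix (genes x
#'   n_boot) as attribute `replicates`.
#' @return data.frame of class `ironmap_gene_weights`: gene, weight, se, z,
#'   p; attributes `component`, `n_skipped`.
#' @export
bootstrap_weights <- function(X, y, component = NULL, n_boot = 1000L,
                              seed = 1L, K = 2L,
                              algorithm = c("simpls", "nipals"),
                              keep_replicates = FALSE) {
  algorithm <- match.arg(algorithm)
  assert_that(n_boot >= 100, "n_boot must be at least 100")
  model <- fit_pls(X, y, K = K, algorithm = algorithm)
  component <- component %||% select_response_component(model)
  assert_that(component >= 1 && component <= model$K,
              "component index out of range")
  core_fun <- if (algorithm == "simpls") pls_simpls_core else pls_nipals_core
  al <- align_xy(X, y)
  Xal <- al$X[, model$gene_id, drop = FALSE]
  yal <- al$y
  n <- nrow(Xal); p <- ncol(Xal)
  w0 <- model$weights[, component]
  reps <- matrix(NA_real_, p, n_boot)
  skipped <- 0L
  local_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) < 2L) { skipped <- skipped + 1L; next }
      Xb <- Xal[idx, , drop = FALSE]
      ctr <- colMeans(Xb)
      scl <- matrixStats::colSds(Xb)
      zero <- scl < .Machine$double.eps^0.5
      scl[zero] <- 1
      Xbs <- sweep(sweep(Xb, 2L, ctr, "-"), 2L, scl, "/")
      if (any(zero)) Xbs[, zero] <- 0
      yb <- yal[idx]; ybc <- yb - mean(yb)
      fit <- core_fun(Xbs, ybc, K)
      if (fit$K < component) { skipped <- skipped + 1L; next }
      wb <- fit$weights[, component]
      if (sum(wb * w0) < 0) wb <- -wb
      reps[, b] <- wb
    }
  })
  se <- matrixStats::rowSds(reps, na.rm = TRUE)
  z <- w0 / se
  z[se == 0 | !is.finite(se)] <- 0
  out <- data.frame(gene = model$gene_id, weight = w0, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ironmap_gene_weights", "data.frame")
  attr(out, "component") <- component
  attr(out, "n_skipped") <- skipped
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}

#' FDR inverse quantile transformation
#'
#' Winner's-curse correction for a vector of z-statistics: two-sided normal
#' p-values are Benjamini-Hochberg adjusted and mapped back through the
#' normal quantile function, giving shrunken z-scores
#' `z_adj = sign(z) * qnorm(1 - q / 2)` with `|z_adj| <= |z|`.
#'
#' @param z Finite numeric vector of z-statistics.
#' @return List: `p` (two-sided), `q` (BH-adjusted), `z_adj`.
#' @export
fiqt <- function(z) {
  assert_that(length(z) > 0, "empty z vector",
              class = "ironmap_empty_input_error")
  assert_that(all(is.finite(z)), "z must be finite")
  p <- 2 * stats::pnorm(-abs(z))
  q <- bh_adjust(p)
  list(p = p, q = q, z_adj = sign(z) * stats::qnorm(1 - q / 2))
}

#' Annotate a gene-weight table with FIQT statistics
#'
#' @param table An `ironmap_gene_weights` (from [bootstrap_weights()]).
#' @return The table with added columns `q`, `z_adj`, `direction`
#'   ("up"/"down" by weight sign) and `rank` (1 = largest |z|).
#' @export
apply_fiqt <- function(table) {
  stopifnot(inherits(table, "ironmap_gene_weights"))
  f <- fiqt(table$z)
  table$q <- f$q
  table$z_adj <- f$z_adj
  table$direction <- ifelse(table$weight > 0, "up",
                            ifelse(table$weight < 0, "down", "none"))
  table$rank <- rank(-abs(table$z), ties.method = "first")
  table
}

#' Split the weight table into significant up/down gene lists
#'
#' @param table A gene-weight table with `q`, `z` and `weight` columns.
#' @param alpha Significance threshold on FIQT q (default 0.05).
#' @return List with `up` (q < alpha, weight > 0, descending z) and `down`
#'   (q < alpha, weight < 0, ascending z) character vectors of gene ids.
#' @export
split_significant <- function(table, alpha = 0.05) {
  assert_that(all(c("gene", "q", "z", "weight") %in% names(table)),
              "table needs gene, q, z, weight columns")
  up <- table[table$q < alpha & table$weight > 0, , drop = FALSE]
  down <- table[table$q < alpha & table$weight < 0, , drop = FALSE]
  list(up = up$gene[order(-up$z)], down = down$gene[order(down$z)])
}

#' Full gene-ranking chain: PLS, bootstrap, FIQT
#'
#' Convenience wrapper used by the pipeline and the null-control reruns:
#' fits the PLS, selects the response component, bootstraps weights and
#' applies the FIQT correction.
#'
#' @inheritParams bootstrap_weights
#' @return An annotated `ironmap_gene_weights` table (see [apply_fiqt()]);
#'   attribute `model` carries the fitted `ironmap_pls`.
#' @export
rank_genes <- function(X, y, K = 2L, n_boot = 1000L, seed = 1L,
                       algorithm = "simpls") {
  tbl <- bootstrap_weights(X, y, component = NULL, n_boot = n_boot,
                           seed = seed, K = K, algorithm = algorithm)
  apply_fiqt(tbl)
}
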