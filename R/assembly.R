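# Assembly of the region x gene expression matrix from donor-level tissue
# samples: nearest-centroid assignment, background filtering, scaled robust
# sigmoid normalization across the cortex, and donor aggregation.

#' Assign tissue samples to parcels
#'
#' Each sample goes to the nearest centroid, by great-circle distance for
#' unit-sphere coordinates (default) or Euclidean distance for native-space
#' coordinates. Ties go to the lower region id (by the geometry's region
#' order). Samples farther than `max_distance` stay unassigned (`NA`).
#'
#' @param samples data.frame with `sample_id`, `x`, `y`, `z` (and optionally
#'   `donor_id`).
#' @param geometry An `ironmap_geometry`.
#' @param max_distance Assignment radius (radians or same units as
#'   coordinates); default `Inf`.
#' @param metric "greatcircle" (coordinates are normalized onto the sphere)
#'   or "euclidean".
#' @return data.frame: sample_id, region_id, distance.
#' @export
assign_samples <- function(samples, geometry, max_distance = Inf,
                           metric = c("greatcircle", "euclidean")) {
  metric <- match.arg(metric)
  assert_that(nrow(samples) > 0, "empty sample table",
              class = "ironmap_empty_input_error")
  assert_that(all(c("sample_id", "x", "y", "z") %in% names(samples)),
              "samples need sample_id, x, y, z columns")
  xyz <- as.matrix(samples[, c("x", "y", "z")])
  assert_that(all(is.finite(xyz)), "sample coordinates must be finite")
  if (metric == "greatcircle") {
    nrm <- sqrt(rowSums(xyz^2))
    assert_that(all(nrm > 0), "zero-norm coordinate cannot be projected")
    d <- great_circle_distance(xyz / nrm, geometry$centroids)
  } else {
    d <- outer(rowSums(xyz^2), rep(1, geometry$n_regions)) -
      2 * tcrossprod(xyz, geometry$centroids) +
      outer(rep(1, nrow(xyz)), rowSums(geometry$centroids^2))
    d <- sqrt(pmax(d, 0))
  }
  idx <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(d)), idx)]
  region <- geometry$region_id[idx]
  region[dist > max_distance] <- NA_character_
  data.frame(sample_id = as.character(samples$sample_id),
             region_id = region, distance = dist,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter genes by the above-background fraction
#'
#' A gene is retained iff the fraction of samples in which it is flagged
#' above background is at least `threshold` (inclusive; the default 0.5 is
#' the conventional 50% rule).
#'
#' @param flags Samples x genes 0/1 matrix (or logical) of above-background
#'   calls, with gene colnames.
#' @param threshold Minimum fraction in `[0, 1]`.
#' @return Character vector of retained gene ids.
#' @export
filter_background <- function(flags, threshold = 0.5) {
  assert_that(is.matrix(flags) && !is.null(colnames(flags)),
              "flags must be a matrix with gene colnames",
              class = "ironmap_configuration_error")
  assert_that(all(flags %in% c(0, 1)), "flags must be 0/1",
              class = "ironmap_configuration_error")
  colnames(flags)[colMeans(flags) >= threshold]
}

#' Scaled-robust-sigmoid normalization across regions
#'
#' Per gene (column), across a donor's regions: a robust sigmoid
#' `s(x) = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))` followed by min-max
#' rescaling to `[0, 1]`. Constant genes (IQR = 0) are set to 0.5 and
#' reported in the `constant_genes` attribute.
#'
#' @param values Regions x genes matrix for one donor (>= 2 regions).
#' @return Normalized matrix in `[0, 1]`, same dimnames, with attribute
#'   `constant_genes`.
#' @export
normalize_expression <- function(values) {
  assert_that(is.matrix(values), "values must be a matrix")
  if (nrow(values) < 2L) {
    stop_ironmap("normalization needs at least 2 regions per donor",
                 "ironmap_degenerate_input_error")
  }
  med <- matrixStats::colMedians(values)
  iqr <- matrixStats::colIQRs(values)
  const <- iqr == 0
  iqr[const] <- 1 # placeholder; constant columns overwritten below
  s <- 1 / (1 + exp(-sweep(sweep(values, 2L, med, "-"), 2L, iqr / 1.35, "/")))
  rng <- matrixStats::colRanges(s)
  span <- rng[, 2] - rng[, 1]
  span[span == 0] <- 1
  out <- sweep(sweep(s, 2L, rng[, 1], "-"), 2L, span, "/")
  out[, const] <- 0.5
  attr(out, "constant_genes") <- colnames(values)[const]
  out
}

#' Aggregate donor-level regional expression
#'
#' Mean over donors per region/gene cell, ignoring donors with no data
#' there; regions with no donor data anywhere stay `NA` (flagged missing and
#' excluded pairwise downstream).
#'
#' @param donor_matrices List of regions x genes matrices on a shared gene
#'   universe; region sets may differ (align by rowname).
#' @return Regions x genes matrix (union of regions).
#' @export
aggregate_donors <- function(donor_matrices) {
  assert_that(length(donor_matrices) > 0, "zero donors",
              class = "ironmap_empty_input_error")
  genes <- colnames(donor_matrices[[1]])
  for (m in donor_matrices) {
    assert_that(identical(colnames(m), genes),
                "donors must share the gene universe after filtering")
  }
  regions <- sort(unique(unlist(lapply(donor_matrices, rownames))))
  acc <- matrix(0, length(regions), length(genes),
                dimnames = list(regions, genes))
  cnt <- matrix(0L, length(regions), length(genes))
  for (m in donor_matrices) {
    r <- match(rownames(m), regions)
    ok <- !is.na(m)
    mm <- m; mm[!ok] <- 0
    acc[r, ] <- acc[r, ] + mm
    cnt[r, ] <- cnt[r, ] + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Assemble a region x gene matrix from donor samples
#'
#' Convenience wrapper running the full assembly chain: assignment,
#' background filtering, per-donor region averaging, scaled-robust-sigmoid
#' normalization, donor aggregation.
#'
#' @param samples data.frame: donor_id, sample_id, x, y, z, then one column
#'   per gene.
#' @param flags Samples x genes 0/1 matrix of above-background calls (rows
#'   aligned with `samples`).
#' @param geometry An `ironmap_geometry`.
#' @param background_threshold Passed to [filter_background()].
#' @param max_distance,metric Passed to [assign_samples()].
#' @return Regions x genes normalized matrix.
#' @export
assemble_expression <- function(samples, flags, geometry,
                                background_threshold = 0.5,
                                max_distance = Inf,
                                metric = "greatcircle") {
  meta_cols <- c("donor_id", "sample_id", "x", "y", "z")
  assert_that(all(meta_cols %in% names(samples)),
              "samples need donor_id, sample_id, x, y, z")
  genes <- setdiff(names(samples), meta_cols)
  keep <- filter_background(flags[, genes, drop = FALSE], background_threshold)
  asg <- assign_samples(samples, geometry, max_distance, metric)
  donor_mats <- lapply(split(seq_len(nrow(samples)), samples$donor_id),
                       function(rows) {
    reg <- asg$region_id[rows]
    rows <- rows[!is.na(reg)]; reg <- reg[!is.na(reg)]
    if (!length(rows)) return(NULL)
    expr <- as.matrix(samples[rows, keep, drop = FALSE])
    by_region <- rowsum(expr, reg) / as.vector(table(reg)[sort(unique(reg))])
    if (nrow(by_region) < 2L) {
      warning("donor with a single sampled region skipped")
      return(NULL)
    }
    normalize_expression(by_region)
  })
  donor_mats <- Filter(Negate(is.null), donor_mats)
  aggregate_donors(donor_mats)
}
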