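# Synthetic-data generators. These state the world the pipeline is tested
# in: a case-control cohort with linear age/sex effects and a spatially
# smooth planted disease effect; a region x gene expression matrix with
# spatial autocorrelation and planted gene sets tracking the disease map; a
# gene x cell-type specificity structure with planted markers; and external
# DE lists overlapping the planted sets.

#' Specify a synthetic case-control cohort
#'
#' Defaults mirror the study scale: 35 controls and 96 cases aged 49-80,
#' susceptibility values on the ppm scale. Per-region parameters may be
#' supplied explicitly; when `NULL` they are drawn from the stated priors at
#' generation time.
#'
#' @param n_controls,n_cases Group sizes (each >= 3).
#' @param age_range Length-2 numeric, years.
#' @param alpha Per-region intercepts (ppm), or `NULL` to draw
#'   `Normal(0, 0.004)` (the scale of reported regional means).
#' @param beta Per-region age slopes (ppm/year), or `NULL` to draw
#'   `Normal(5e-5, 3e-5)` (slow iron accrual with age).
#' @param sex_effect Per-region sex effects (ppm, male minus female), or
#'   `NULL` to draw `Normal(0, 5e-4)`.
#' @param disease_map Per-region case-group shifts delta_i (ppm), `NULL` to
#'   draw a smooth field scaled to `disease_effect_sd`, or `0` for a global
#'   null.
#' @param disease_effect_sd Marginal SD of the drawn disease map (ppm);
#'   default half the subject noise, giving QSM scores of order 0.5.
#' @param noise_sd Subject-level measurement noise SD (ppm).
#' @param correlation_length Smoothness of the drawn disease map (radians).
#' @param seed Integer seed used by `generate_cohort()`.
#' @return A list of class `ironmap_cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 35L, n_cases = 96L,
                        age_range = c(49, 80),
                        alpha = NULL, beta = NULL, sex_effect = NULL,
                        disease_map = NULL,
                        disease_effect_sd = 0.0015,
                        noise_sd = 0.003,
                        correlation_length = 0.5,
                        seed = 1L) {
  assert_that(n_controls >= 3 && n_cases >= 3,
              "need at least 3 subjects per group")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(length(age_range) == 2L && age_range[2] > age_range[1],
              "age_range must be an increasing length-2 vector")
  structure(
    list(n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
         age_range = age_range, alpha = alpha, beta = beta,
         sex_effect = sex_effect, disease_map = disease_map,
         disease_effect_sd = disease_effect_sd, noise_sd = noise_sd,
         correlation_length = correlation_length, seed = seed),
    class = "ironmap_cohort_spec"
  )
}

expand_region_param <- function(x, n, default) {
  if (is.null(x)) return(default)
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  assert_that(length(x) == n,
              "per-region parameter has length %d, expected %d",
              class = "ironmap_dimension_error")
  as.numeric(x)
}

#' Generate a synthetic case-control cohort
#'
#' Subject j's value in region i is
#' `alpha_i + beta_i * age_j + sexeffect_i * sex_j + delta_i * group_j + eps`,
#' with `eps ~ Normal(0, noise_sd)`, sex coded 0/1 (female/male) and group
#' coded 0/1 (control/case).
#'
#' @param spec An [cohort_spec()].
#' @param geometry An `ironmap_geometry`; region count must match any
#'   explicit per-region parameters in `spec`.
#' @return List with `values` (subjects x regions matrix, ppm), `covariates`
#'   (data.frame: subject_id, group, age, sex) and `truth` (the per-region
#'   parameters actually used, including `disease_map`).
#' @export
generate_cohort <- function(spec, geometry) {
  stopifnot(inherits(spec, "ironmap_cohort_spec"),
            inherits(geometry, "ironmap_geometry"))
  n <- geometry$n_regions
  for (nm in c("alpha", "beta", "sex_effect", "disease_map")) {
    v <- spec[[nm]]
    if (!is.null(v) && length(v) > 1L && length(v) != n) {
      stop_ironmap("spec parameter '%s' has length %d but geometry has %d regions",
                   "ironmap_dimension_error", nm, length(v), n)
    }
  }
  local_seed(spec$seed, {
    alpha <- expand_region_param(spec$alpha, n, stats::rnorm(n, 0, 0.004))
    beta <- expand_region_param(spec$beta, n, stats::rnorm(n, 5e-5, 3e-5))
    sexeff <- expand_region_param(spec$sex_effect, n, stats::rnorm(n, 0, 5e-4))
    delta <- expand_region_param(
      spec$disease_map, n,
      drop(sample_smooth_fields(geometry, 1L, spec$correlation_length)) *
        spec$disease_effect_sd
    )
    n_sub <- spec$n_controls + spec$n_cases
    group <- rep(c(0L, 1L), c(spec$n_controls, spec$n_cases))
    age <- stats::runif(n_sub, spec$age_range[1], spec$age_range[2])
    sex <- stats::rbinom(n_sub, 1L, 0.5)
    values <- outer(rep(1, n_sub), alpha) +
      outer(age, beta) + outer(sex, sexeff) + outer(group, delta) +
      matrix(stats::rnorm(n_sub * n, 0, spec$noise_sd), n_sub, n)
    subject_id <- sprintf("S%03d", seq_len(n_sub))
    dimnames(values) <- list(subject_id, geometry$region_id)
    list(
      values = values,
      covariates = data.frame(
        subject_id = subject_id,
        group = factor(ifelse(group == 1L, "case", "control"),
                       levels = c("control", "case")),
        age = age, sex = sex, stringsAsFactors = FALSE
      ),
      truth = list(alpha = alpha, beta = beta, sex_effect = sexeff,
                   disease_map = delta)
    )
  })
}

#' Specify a synthetic regional expression matrix
#'
#' @param n_genes Number of genes (>= 50); the study scale is 15,745, tests
#'   run at 500-2,000.
#' @param spatial_smoothness Correlation length (radians) of each gene's
#'   smooth spatial component.
#' @param planted_sets Named list; each element is
#'   `list(genes = <ids or 1-based indices>, effect = <loading>)`. Planted
#'   genes' regional profiles load on the standardized disease map with the
#'   stated effect size (in units of the smooth field's SD). Sets must be
#'   disjoint.
#' @param noise_sd SD of the white-noise component (default 0.5, the planted
#'   recovery regime).
#' @param seed Integer seed.
#' @return List of class `ironmap_expression_spec`.
#' @export
expression_spec <- function(n_genes = 2000L, spatial_smoothness = 0.5,
                            planted_sets = list(), noise_sd = 0.5,
                            seed = 1L) {
  assert_that(n_genes >= 50, "n_genes must be at least 50")
  ids <- unlist(lapply(planted_sets, `[[`, "genes"))
  assert_that(!anyDuplicated(ids), "planted sets must be disjoint")
  effects <- vapply(planted_sets, function(s) as.numeric(s$effect), 0)
  assert_that(all(is.finite(effects)) || length(effects) == 0L,
              "planted effect sizes must be finite")
  structure(
    list(n_genes = as.integer(n_genes),
         spatial_smoothness = spatial_smoothness,
         planted_sets = planted_sets, noise_sd = noise_sd, seed = seed),
    class = "ironmap_expression_spec"
  )
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

resolve_gene_ids <- function(genes, universe) {
  if (is.numeric(genes)) {
    if (any(genes < 1 | genes > length(universe))) {
      stop_ironmap("planted gene index outside 1..%d",
                   "ironmap_invalid_argument", length(universe))
    }
    return(universe[as.integer(genes)])
  }
  missing <- setdiff(genes, universe)
  if (length(missing)) {
    stop_ironmap("planted gene ids not in the generated universe: %s",
                 "ironmap_invalid_argument",
                 paste(utils::head(missing, 3), collapse = ", "))
  }
  as.character(genes)
}

#' Generate a region x gene expression matrix with planted structure
#'
#' Each gene's regional profile is
#' `effect * standardized(disease_map) + smooth field + white noise`,
#' where the smooth field has unit marginal SD and Gaussian-kernel spatial
#' covariance, then min-max normalized to `[0, 1]` per gene (matching the
#' normalization the assembly module applies to real donor data).
#'
#' @param spec An [expression_spec()].
#' @param geometry An `ironmap_geometry`.
#' @param disease_map Numeric vector, one value per region.
#' @return Matrix (regions x genes, values in `[0, 1]`) with attribute
#'   `planted` (named list of planted gene-id vectors).
#' @export
generate_expression <- function(spec, geometry, disease_map) {
  stopifnot(inherits(spec, "ironmap_expression_spec"),
            inherits(geometry, "ironmap_geometry"))
  n <- geometry$n_regions
  assert_that(length(disease_map) == n,
              "disease_map length %d != %d regions",
              class = "ironmap_dimension_error")
  ids <- gene_ids(spec$n_genes)
  dsd <- stats::sd(disease_map)
  zmap <- if (is.na(dsd) || dsd == 0) rep(0, n) else
    (disease_map - mean(disease_map)) / dsd
  local_seed(spec$seed, {
    E <- sample_smooth_fields(geometry, spec$n_genes, spec$spatial_smoothness)
    if (spec$noise_sd > 0) {
      E <- E + matrix(stats::rnorm(n * spec$n_genes, 0, spec$noise_sd),
                      n, spec$n_genes)
    }
    colnames(E) <- ids
    planted <- lapply(spec$planted_sets, function(s) {
      g <- resolve_gene_ids(s$genes, ids)
      E[, g] <<- E[, g] + zmap * s$effect
      g
    })
    rng <- matrixStats::colRanges(E)
    span <- rng[, 2] - rng[, 1]
    span[span == 0] <- 1
    E <- sweep(sweep(E, 2L, rng[, 1], "-"), 2L, span, "/")
    rownames(E) <- geometry$region_id
    attr(E, "planted") <- planted
    E
  })
}

#' Generate a gene x cell-type mean-expression table
#'
#' Baseline expression is Gamma-distributed and roughly exchangeable across
#' cell types; planted marker genes have their expression concentrated in
#' their own type.
#'
#' @param n_genes Number of genes.
#' @param cell_types Character vector of cell-type names.
#' @param planted_markers Named list mapping cell type -> gene ids (or
#'   1-based indices); names must be in `cell_types`.
#' @param marker_purity Fraction of a marker gene's expression in its own
#'   type (default 0.9).
#' @param seed Integer seed.
#' @return Matrix (genes x cell types) of non-negative mean expression.
#' @export
generate_cell_specificity <- function(n_genes, cell_types,
                                      planted_markers = list(),
                                      marker_purity = 0.9, seed = 1L) {
  cell_types <- as.character(cell_types)
  unknown <- setdiff(names(planted_markers), cell_types)
  if (length(unknown)) {
    stop_ironmap("unknown cell type in planted_markers: %s",
                 "ironmap_invalid_argument", paste(unknown, collapse = ", "))
  }
  ids <- gene_ids(n_genes)
  local_seed(seed, {
    M <- matrix(stats::rgamma(n_genes * length(cell_types), shape = 2, rate = 1),
                n_genes, length(cell_types), dimnames = list(ids, cell_types))
    for (ct in names(planted_markers)) {
      g <- resolve_gene_ids(planted_markers[[ct]], ids)
      tot <- rowSums(M[g, , drop = FALSE])
      off <- tot * (1 - marker_purity) / max(1L, length(cell_types) - 1L)
      M[g, ] <- matrix(off, length(g), length(cell_types))
      M[g, ct] <- tot * marker_purity
    }
    M
  })
}

#' Generate external differentially-expressed gene lists
#'
#' Each list samples mostly from a planted set, with signed fold changes in
#' `fold_change_range` (direction "up" positive), plus sub-threshold decoy
#' entries with |fold change| in (1, 1.5] that a 1.5 filter removes.
#'
#' @param planted_sets Named list of gene-id vectors; each becomes one list.
#' @param directions Character vector ("up"/"down"), one per list.
#' @param fold_change_range Length-2 numeric > 1.5 (linear scale).
#' @param decoy_genes Pool of gene ids for sub-threshold decoy entries;
#'   defaults to synthetic placeholder ids absent from any weight universe.
#' @param n_decoys Decoy entries per list (default 10).
#' @param seed Integer seed.
#' @return data.frame: study, contrast, gene, fold_change (signed, linear),
#'   p.
#' @export
generate_de_lists <- function(planted_sets, directions,
                              fold_change_range = c(1.6, 4),
                              decoy_genes = NULL, n_decoys = 10L, seed = 1L) {
  assert_that(length(planted_sets) >= 1L, "need at least one planted set")
  assert_that(all(lengths(planted_sets) > 0L), "empty planted set")
  assert_that(all(directions %in% c("up", "down")),
              "directions must be 'up' or 'down'")
  assert_that(length(directions) == length(planted_sets),
              "one direction per planted set required")
  nm <- names(planted_sets) %||% sprintf("study%d", seq_along(planted_sets))
  local_seed(seed, {
    rows <- lapply(seq_along(planted_sets), function(k) {
      genes <- as.character(planted_sets[[k]])
      sgn <- if (directions[k] == "up") 1 else -1
      fc <- sgn * stats::runif(length(genes), fold_change_range[1],
                               fold_change_range[2])
      dec <- decoy_genes %||% sprintf("DECOY%03d", seq_len(n_decoys))
      dec <- sample(dec, min(n_decoys, length(dec)))
      dfc <- sgn * stats::runif(length(dec), 1.0001, 1.5)
      data.frame(
        study = nm[k], contrast = directions[k],
        gene = c(genes, dec), fold_change = c(fc, dfc),
        p = stats::runif(length(genes) + length(dec), 1e-6, 0.04),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
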