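# Regional susceptibility scoring: age/sex adjustment of subject-level
# regional QSM values, the case-control z-score map, and per-region group
# tests.
#
# Adjustment follows the two-step scheme: age models are fitted on controls
# only (so disease-with-age effects are not removed) and applied to both
# groups; sex models are fitted within each group separately.

check_alignment <- function(values, covariates) {
  assert_that(is.matrix(values) && !is.null(rownames(values)) &&
                !is.null(colnames(values)),
              "values must be a matrix with subject rownames and region colnames")
  assert_that(all(c("subject_id", "group", "age", "sex") %in% names(covariates)),
              "covariates must have subject_id, group, age, sex")
  assert_that(all(rownames(values) %in% covariates$subject_id),
              "every subject in values needs a covariate row",
              class = "ironmap_key_error")
  assert_that(all(is.finite(values)), "values must be finite")
  covariates[match(rownames(values), covariates$subject_id), , drop = FALSE]
}

#' Fit per-region age models on the control group
#'
#' Ordinary least squares of regional susceptibility on age, one model per
#' region, fitted in controls only. The reference age `mu` is the mean
#' control age.
#'
#' @param values Subjects x regions matrix (ppm) with subject rownames and
#'   region colnames. Rows not belonging to controls are ignored.
#' @param covariates data.frame with `subject_id`, `group` (levels including
#'   "control"), `age`, `sex`.
#' @return An `ironmap_age_models` object: `alpha`, `beta` (named per
#'   region), `mu`.
#' @export
fit_age_models <- function(values, covariates) {
  cov <- check_alignment(values, covariates)
  ctrl <- cov$group == "control"
  if (sum(ctrl) < 3L) {
    stop_ironmap("need at least 3 control subjects, got %d",
                 "ironmap_sample_size_error", sum(ctrl))
  }
  age <- cov$age[ctrl]
  if (stats::var(age) <= 0) {
    stop_ironmap("control ages have zero variance: age model is degenerate",
                 "ironmap_degenerate_design_error")
  }
  Y <- values[ctrl, , drop = FALSE]
  ac <- age - mean(age)
  beta <- drop(crossprod(ac, sweep(Y, 2L, colMeans(Y), "-"))) / sum(ac^2)
  alpha <- colMeans(Y) - beta * mean(age)
  structure(list(alpha = alpha, beta = beta, mu = mean(age),
                 region_id = colnames(values)),
            class = "ironmap_age_models")
}

#' Age-adjust regional susceptibility values
#'
#' Applies `chi_ij = Y_ij + beta_i * (mu - A_j)` elementwise, using control
#' fits for both groups.
#'
#' @param values Subjects x regions matrix (ppm).
#' @param models An [fit_age_models()] result covering all regions.
#' @param covariates Covariate table with ages.
#' @return Matrix of age-adjusted values, same shape and dimnames.
#' @export
age_adjust <- function(values, models, covariates) {
  stopifnot(inherits(models, "ironmap_age_models"))
  cov <- check_alignment(values, covariates)
  missing <- setdiff(colnames(values), models$region_id)
  if (length(missing)) {
    stop_ironmap("regions missing from age models: %s", "ironmap_key_error",
                 paste(utils::head(missing, 3), collapse = ", "))
  }
  beta <- models$beta[match(colnames(values), models$region_id)]
  values + outer(models$mu - cov$age, beta)
}

#' Sex-adjust regional susceptibility values within each group
#'
#' For each group k a per-region OLS of (age-adjusted) susceptibility on the
#' 0/1 sex code is fitted, then `chi'_ijk = chi_ijk + beta_ik (mu_k - S_jk)`
#' with `mu_k` the group's mean sex code. A single-sex group gets zero
#' adjustment with a warning.
#'
#' @param values Subjects x regions matrix (typically age-adjusted).
#' @param covariates Covariate table with `sex` in {0, 1}.
#' @return Matrix of adjusted values; attribute `sex_models` carries the
#'   per-group slopes and mean sex.
#' @export
sex_adjust <- function(values, covariates) {
  cov <- check_alignment(values, covariates)
  assert_that(all(cov$sex %in% c(0, 1)), "sex must be coded 0/1")
  out <- values
  models <- list()
  for (g in levels(factor(cov$group))) {
    rows <- which(cov$group == g)
    s <- cov$sex[rows]
    mu_k <- mean(s)
    if (stats::var(s) == 0) {
      warning(sprintf("group '%s' has a single sex; sex adjustment skipped", g))
      beta <- stats::setNames(rep(0, ncol(values)), colnames(values))
    } else {
      Y <- values[rows, , drop = FALSE]
      sc <- s - mu_k
      beta <- drop(crossprod(sc, sweep(Y, 2L, colMeans(Y), "-"))) / sum(sc^2)
    }
    out[rows, ] <- values[rows, , drop = FALSE] + outer(mu_k - s, beta)
    models[[g]] <- list(beta = beta, mu = mu_k)
  }
  attr(out, "sex_models") <- models
  out
}

#' Case-control QSM score map
#'
#' Per region, the case-group mean is z-scored against the control
#' distribution: `score_i = (mean_case_i - mean_control_i) / sd_control_i`,
#' with the sample SD (n - 1 denominator). Regions with zero control SD are
#' flagged (`NA` score) and excluded downstream.
#'
#' @param adjusted_controls,adjusted_cases Subjects x regions matrices of
#'   adjusted values with matching region columns.
#' @return data.frame of class `ironmap_qsm_scores`: region_id, score,
#'   control_mean, control_sd, case_mean.
#' @export
compute_qsm_scores <- function(adjusted_controls, adjusted_cases) {
  assert_that(identical(colnames(adjusted_controls), colnames(adjusted_cases)),
              "control and case matrices must share region columns",
              class = "ironmap_key_error")
  cm <- colMeans(adjusted_controls)
  csd <- matrixStats::colSds(adjusted_controls)
  pm <- colMeans(adjusted_cases)
  score <- (pm - cm) / csd
  score[csd == 0] <- NA_real_
  if (anyNA(score)) {
    warning(sprintf("%d region(s) with zero control SD flagged undefined",
                    sum(is.na(score))))
  }
  structure(
    data.frame(region_id = colnames(adjusted_controls), score = score,
               control_mean = cm, control_sd = csd, case_mean = pm,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("ironmap_qsm_scores", "data.frame")
  )
}

#' Per-region two-sample group tests
#'
#' Pooled-variance (Student) two-sided t-test per region, with
#' Benjamini-Hochberg correction across regions. The pooled test, not
#' Welch's, is used throughout: it is the variant that reproduces the
#' package's reference demographic comparisons.
#'
#' @param adjusted_controls,adjusted_cases Subjects x regions matrices.
#' @return data.frame: region_id, t, p, q, direction ("case>control" /
#'   "control>case" / "none").
#' @export
compare_regions <- function(adjusted_controls, adjusted_cases) {
  assert_that(identical(colnames(adjusted_controls), colnames(adjusted_cases)),
              "control and case matrices must share region columns",
              class = "ironmap_key_error")
  n1 <- nrow(adjusted_controls); n2 <- nrow(adjusted_cases)
  if (n1 < 2L || n2 < 2L) {
    stop_ironmap("need at least 2 subjects per group",
                 "ironmap_sample_size_error")
  }
  res <- mapply(function(m1, s1, m2, s2) {
    pooled_ttest_from_summary(n1, m1, s1, n2, m2, s2)
  },
  colMeans(adjusted_controls), matrixStats::colSds(adjusted_controls),
  colMeans(adjusted_cases), matrixStats::colSds(adjusted_cases))
  t <- unlist(res["t", ]); p <- unlist(res["p", ])
  data.frame(
    region_id = colnames(adjusted_controls), t = t, p = p, q = bh_adjust(p),
    direction = ifelse(t < 0, "case>control",
                       ifelse(t > 0, "control>case", "none")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's two-sample t with pooled variance, computed from group sizes,
#' means and SDs; two-sided p with `df = n1 + n2 - 2`. Useful for checking
#' published demographic tables that report means (SD).
#'
#' @param n1,mean1,sd1 First group: size, mean, sample SD.
#' @param n2,mean2,sd2 Second group.
#' @return List with `t`, `df`, `p`.
#' @examples
#' pooled_ttest_from_summary(35, 66.26, 9.16, 96, 64.52, 7.79)$p # ~0.284
#' @export
pooled_ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  assert_that(n1 >= 2 && n2 >= 2, "need n >= 2 in both groups",
              class = "ironmap_sample_size_error")
  assert_that(sd1 >= 0 && sd2 >= 0, "SDs must be non-negative")
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    stop_ironmap("degenerate input: both SDs zero and means equal",
                 "ironmap_degenerate_design_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Extract regional mean susceptibility from label/density volumes
#'
#' Per integer label, the mean of signed susceptibility over voxels carrying
#' that label whose grey-matter density passes the cutoff (inclusive `>=` by
#' default; set `inclusive = FALSE` for strict `>`). Volumes are plain 3-D
#' arrays on a shared grid.
#'
#' @param susceptibility,label,gm_density 3-D arrays of identical dimension;
#'   `label` holds non-negative integers (0 = unlabelled).
#' @param cutoff Grey-matter density threshold (default 0.25).
#' @param inclusive Logical; whether voxels at exactly the cutoff survive.
#' @return Named numeric vector of per-label means; labels whose voxels all
#'   fail the density mask are `NA` (flagged missing).
#' @export
extract_regional_means <- function(susceptibility, label, gm_density,
                                   cutoff = 0.25, inclusive = TRUE) {
  if (!identical(dim(susceptibility), dim(label)) ||
      !identical(dim(susceptibility), dim(gm_density))) {
    stop_ironmap("volumes must share grid dimensions", "ironmap_dimension_error")
  }
  assert_that(all(label >= 0) && all(label == floor(label)),
              "labels must be non-negative integers")
  labs <- sort(unique(as.vector(label[label > 0])))
  if (!length(labs)) {
    stop_ironmap("no labelled voxels in the label volume",
                 "ironmap_empty_input_error")
  }
  keep <- if (inclusive) gm_density >= cutoff else gm_density > cutoff
  out <- vapply(labs, function(l) {
    sel <- label == l & keep
    if (!any(sel)) NA_real_ else mean(susceptibility[sel])
  }, 0)
  names(out) <- as.character(labs)
  out
}
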