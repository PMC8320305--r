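# Regional susceptibility: age/sex adjustment identities, QSM scores,
# group tests against independent oracles.

test_that("fit_age_models recovers exact and noisy coefficients", {
  geom <- generate_parcellation(10, seed = 1)
  # exact line: 0.001 + 0.0002 * age
  ch <- make_cohort(geom, alpha = 0.001, beta = 2e-4)
  m <- fit_age_models(ch$values, ch$covariates)
  expect_equal(unname(m$alpha), rep(0.001, 10), tolerance = 1e-12)
  expect_equal(unname(m$beta), rep(2e-4, 10), tolerance = 1e-12)
  # constant response: alpha = c, beta = 0
  ch2 <- make_cohort(geom, alpha = 0.007, beta = 0)
  m2 <- fit_age_models(ch2$values, ch2$covariates)
  expect_equal(unname(m2$alpha), rep(0.007, 10), tolerance = 1e-12)
  expect_equal(unname(m2$beta), rep(0, 10), tolerance = 1e-12)
  # noisy controls vs a normal-equations oracle computed independently
  ch3 <- make_cohort(geom, noise_sd = 0.002, seed = 8, n_controls = 20L)
  m3 <- fit_age_models(ch3$values, ch3$covariates)
  ctrl <- ch3$covariates$group == "control"
  A <- cbind(1, ch3$covariates$age[ctrl])
  coef_oracle <- solve(crossprod(A), crossprod(A, ch3$values[ctrl, ]))
  expect_equal(unname(m3$alpha), unname(coef_oracle[1, ]), tolerance = 1e-10)
  expect_equal(unname(m3$beta), unname(coef_oracle[2, ]), tolerance = 1e-10)
})

test_that("fit_age_models rejects degenerate designs", {
  geom <- generate_parcellation(10, seed = 1)
  ch <- make_cohort(geom, n_controls = 5L)
  cov <- ch$covariates
  cov$age[cov$group == "control"] <- 60
  expect_error(fit_age_models(ch$values, cov),
               class = "ironmap_degenerate_design_error")
  cov2 <- ch$covariates
  cov2$group <- factor("case", levels = c("control", "case")) # no controls
  expect_error(fit_age_models(ch$values, cov2),
               class = "ironmap_sample_size_error")
})

test_that("age_adjust applies the correction identity", {
  geom <- generate_parcellation(10, seed = 2)
  ch <- make_cohort(geom, noise_sd = 0.001, seed = 3)
  m <- fit_age_models(ch$values, ch$covariates)
  adj <- age_adjust(ch$values, m, ch$covariates)
  # direct single-cell evaluation: chi = 0.005 + 0.0002 * (66 - 60) = 0.0062
  m_toy <- structure(list(alpha = c(R1 = 0), beta = c(R1 = 2e-4), mu = 66,
                          region_id = "R1"), class = "ironmap_age_models")
  v <- matrix(0.005, 1, 1, dimnames = list("S1", "R1"))
  cov_toy <- data.frame(subject_id = "S1", group = "case", age = 60, sex = 0)
  expect_equal(as.numeric(age_adjust(v, m_toy, cov_toy)), 0.0062,
               tolerance = 1e-15)
  # subjects at the reference age are unchanged
  cov_mu <- ch$covariates; cov_mu$age <- m$mu
  expect_equal(age_adjust(ch$values, m, cov_mu), ch$values, tolerance = 1e-12)
  # zero slopes leave everything unchanged
  m0 <- m; m0$beta[] <- 0
  expect_equal(age_adjust(ch$values, m0, ch$covariates), ch$values,
               tolerance = 1e-15)
  # missing region is a key error
  m_miss <- m; m_miss$region_id <- m$region_id[-1]
  expect_error(age_adjust(ch$values, m_miss, ch$covariates),
               class = "ironmap_key_error")
})

test_that("sex_adjust shifts by beta * (mean sex - sex) within group", {
  # one group, sexes half/half coded 0/1, slope 0.002 per region
  vals <- matrix(0.01 + 0.002 * c(0, 0, 1, 1), 4, 3,
                 dimnames = list(paste0("S", 1:4), paste0("R", 1:3)))
  cov <- data.frame(subject_id = paste0("S", 1:4),
                    group = factor(rep("case", 4),
                                   levels = c("control", "case")),
                    age = 60, sex = c(0, 0, 1, 1))
  adj <- sex_adjust(vals, cov)
  # males (code 1) shift by -0.001, females by +0.001 (mu_k = 0.5)
  expect_equal(unname(adj[, 1] - vals[, 1]),
               c(0.001, 0.001, -0.001, -0.001), tolerance = 1e-15)
  # group means equal across sexes after adjustment (noiseless)
  expect_equal(mean(adj[1:2, 1]), mean(adj[3:4, 1]), tolerance = 1e-15)
  # single-sex group: warning, values unchanged
  cov1 <- cov; cov1$sex <- 1
  expect_warning(adj1 <- sex_adjust(vals, cov1), "single sex")
  expect_equal(adj1, vals, ignore_attr = TRUE)
})

test_that("compute_qsm_scores matches hand evaluation and flags zero SD", {
  ctrl <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "R1"))
  case <- matrix(c(4, 4), 2, 1, dimnames = list(NULL, "R1"))
  sc <- compute_qsm_scores(ctrl, case)
  expect_equal(sc$score, 2) # (4 - 2) / 1 with n-1 SD
  expect_equal(sc$control_sd, 1)
  # identical groups give zero
  sc0 <- compute_qsm_scores(ctrl, ctrl)
  expect_equal(sc0$score, 0)
  # one control SD above the mean gives exactly 1
  case1 <- matrix(c(3, 3), 2, 1, dimnames = list(NULL, "R1"))
  expect_equal(compute_qsm_scores(ctrl, case1)$score, 1)
  # zero-SD regions are flagged NA with a warning
  flat <- matrix(5, 3, 1, dimnames = list(NULL, "R1"))
  expect_warning(scf <- compute_qsm_scores(flat, case), "zero control SD")
  expect_true(is.na(scf$score))
})

test_that("compare_regions matches a from-scratch pooled-t oracle", {
  a <- matrix(c(1.2, 0.8, 1.1), 3, 1, dimnames = list(NULL, "R1"))
  b <- matrix(c(2.0, 1.6), 2, 1, dimnames = list(NULL, "R1"))
  res <- compare_regions(a, b)
  oracle <- t.test(a[, 1], b[, 1], var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1 everywhere
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("R", 1:3)))
  res0 <- compare_regions(m, m)
  expect_equal(res0$t, rep(0, 3))
  expect_equal(res0$p, rep(1, 3))
  # BH q monotone non-decreasing in p
  set.seed(11)
  x <- matrix(rnorm(200), 10, 20, dimnames = list(NULL, paste0("R", 1:20)))
  y <- matrix(rnorm(200, 0.5), 10, 20, dimnames = list(NULL, paste0("R", 1:20)))
  rr <- compare_regions(x, y)
  o <- order(rr$p)
  expect_true(all(diff(rr$q[o]) >= -1e-15))
  expect_error(compare_regions(x[1, , drop = FALSE], y),
               class = "ironmap_sample_size_error")
})

test_that("pooled_ttest_from_summary agrees with t.test on raw data", {
  set.seed(3)
  x <- rnorm(8); y <- rnorm(13, 0.7)
  r <- pooled_ttest_from_summary(8, mean(x), sd(x), 13, mean(y), sd(y))
  o <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$t, unname(o$statistic), tolerance = 1e-12)
  expect_equal(r$p, o$p.value, tolerance = 1e-12)
  expect_equal(r$df, 19)
  # equal means give the exact null
  expect_equal(pooled_ttest_from_summary(5, 1, 1, 5, 1, 2)$t, 0)
  expect_equal(pooled_ttest_from_summary(5, 1, 1, 5, 1, 2)$p, 1)
  expect_error(pooled_ttest_from_summary(5, 1, 0, 5, 1, 0),
               class = "ironmap_degenerate_design_error")
})

test_that("adjustment pipeline is unbiased and idempotent", {
  geom <- generate_parcellation(12, seed = 6)
  # null cohort: adjusted scores have mean near 0 over replicates
  means <- vapply(1:100, function(r) {
    ch <- make_cohort(geom, noise_sd = 0.003, seed = 100 + r)
    cov <- ch$covariates
    m <- fit_age_models(ch$values, cov)
    adj <- age_adjust(ch$values, m, cov)
    sc <- compute_qsm_scores(adj[cov$group == "control", ],
                             adj[cov$group == "case", ])
    mean(sc$score)
  }, 0)
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
  # noiseless: re-fitting age models on adjusted controls gives beta ~ 0
  ch <- make_cohort(geom, alpha = 0.002, beta = 3e-4)
  cov <- ch$covariates
  m <- fit_age_models(ch$values, cov)
  adj <- age_adjust(ch$values, m, cov)
  m2 <- fit_age_models(adj, cov)
  expect_lt(max(abs(m2$beta)), 1e-10)
})

test_that("extract_regional_means intersects labels with the density mask", {
  dims <- c(2, 2, 1)
  susc <- array(c(0.01, 0.03, 0.05, 0.07), dims)
  lab <- array(c(1, 1, 2, 0), dims)
  gm <- array(c(0.3, 0.2, 0.1, 0.9), dims)
  out <- extract_regional_means(susc, lab, gm, cutoff = 0.25)
  expect_equal(unname(out["1"]), 0.01)   # only the first voxel survives
  expect_true(is.na(out["2"]))           # all label-2 voxels below cutoff
  # constant field: every region mean is that value
  outc <- extract_regional_means(array(0.4, dims), lab, array(1, dims))
  expect_equal(unname(outc), c(0.4, 0.4))
  # boundary: inclusive vs strict cutoff
  gm2 <- array(0.25, dims)
  expect_equal(unname(extract_regional_means(susc, lab, gm2)["1"]), 0.02)
  expect_true(is.na(extract_regional_means(susc, lab, gm2,
                                           inclusive = FALSE)["1"]))
  expect_error(extract_regional_means(susc, array(1, c(2, 2, 2)), gm),
               class = "ironmap_dimension_error")
  expect_error(extract_regional_means(susc, array(0, dims), gm),
               class = "ironmap_empty_input_error")
})
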