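# PLS core, spin permutations, bootstrap z-ratios and the FIQT correction.

test_that("fit_pls recovers a perfect predictor and satisfies invariants", {
  set.seed(1)
  # many regions so chance correlations of the noise genes are negligible
  X <- matrix(rnorm(500 * 4), 500, 4,
              dimnames = list(sprintf("R%03d", 1:500), paste0("g", 1:4)))
  y <- setNames(scale(X[, 3])[, 1], rownames(X))
  fit <- fit_pls(X, y, K = 2)
  expect_gt(fit$varexp_y[1], 0.99)
  # region scores have zero mean; varexp in [0,1] summing to <= 1
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
  expect_true(all(fit$varexp_y >= 0 & fit$varexp_y <= 1))
  expect_lte(sum(fit$varexp_y), 1 + 1e-9)
  # sign convention: scores correlate positively with y
  for (k in seq_len(fit$K)) expect_gte(cor(fit$scores[, k], y), 0)
})

test_that("per-component Y-variance matches an independent regression oracle", {
  set.seed(2)
  X <- matrix(rnorm(12 * 6), 12, 6,
              dimnames = list(sprintf("R%02d", 1:12), paste0("g", 1:6)))
  y <- setNames(rnorm(12), rownames(X))
  for (alg in c("simpls", "nipals")) {
    fit <- fit_pls(X, y, K = 4, algorithm = alg)
    r2 <- vapply(seq_len(fit$K), function(k) {
      summary(lm(y ~ fit$scores[, seq_len(k), drop = FALSE]))$r.squared
    }, 0)
    expect_equal(fit$varexp_y, diff(c(0, r2)), tolerance = 1e-10)
  }
})

test_that("fit_pls is equivariant to gene and region permutations", {
  set.seed(3)
  X <- matrix(rnorm(15 * 8), 15, 8,
              dimnames = list(sprintf("R%02d", 1:15), paste0("g", 1:8)))
  y <- setNames(rnorm(15), rownames(X))
  fit <- fit_pls(X, y, K = 2)
  gp <- sample(8)
  fitg <- fit_pls(X[, gp], y, K = 2)
  expect_equal(fitg$weights, fit$weights[gp, ], tolerance = 1e-12)
  expect_equal(fitg$scores, fit$scores, tolerance = 1e-12)
  rp <- sample(15)
  fitr <- fit_pls(X[rp, ], y[rp], K = 2) # id-aligned: same model
  expect_equal(fitr$varexp_y, fit$varexp_y, tolerance = 1e-12)
  # constant column dropped with a warning
  Xc <- cbind(X, const = 1)
  expect_warning(fitc <- fit_pls(Xc, y, K = 2), "constant")
  expect_false("const" %in% fitc$gene_id)
})

test_that("select_response_component takes the argmax with low-index ties", {
  fit <- structure(list(varexp_y = c(0.05, 0.20, 0.03), K = 3),
                   class = "ironmap_pls")
  expect_equal(select_response_component(fit), 2)
  fit1 <- structure(list(varexp_y = 0.4, K = 1), class = "ironmap_pls")
  expect_equal(select_response_component(fit1), 1)
  tie <- structure(list(varexp_y = c(0.2, 0.2), K = 2), class = "ironmap_pls")
  expect_equal(select_response_component(tie), 1)
})

test_that("spin_permute handles identity, closure and the antipodal swap", {
  geom <- make_swap_geometry()
  expect_identical(spin_permute(geom, rotation = diag(3)), seq_len(12))
  expect_identical(spin_permute(geom, rotation = rot_z_180),
                   c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L, 10L, 9L, 12L, 11L))
  # relabelling values are always original region indices
  big <- generate_parcellation(50, seed = 4)
  for (s in 1:5) {
    perm <- spin_permute(big, seed = s)
    expect_true(all(perm %in% seq_len(50)))
    expect_identical(perm, spin_permute(big, seed = s))
  }
})

test_that("spin_test p-values behave at bounds and under determinism", {
  w <- make_world(n_regions = 40, n_genes = 100, effect = 5, noise_sd = 0.1)
  sp <- spin_test(w$X, w$y, w$geom, K = 2, n_perm = 200, seed = 5)
  expect_identical(sp$p,
                   spin_test(w$X, w$y, w$geom, K = 2, n_perm = 200, seed = 5)$p)
  expect_gte(sp$p, 1 / 201)
  # p follows the add-one convention exactly (recomputed from stored nulls;
  # at coarse parcellations a small rotation may reproduce the identity
  # relabelling, so the floor is not guaranteed)
  expect_equal(sp$p,
               (1 + sum(sp$null_selected >= max(sp$observed))) / 201)
  expect_lte(sp$p, 5 / 201)
  # drawn null values are a sub-multiset of the original y per relabelling
  for (b in c(1, 50, 200)) {
    drawn <- w$y[sp$relabellings[b, ]]
    expect_true(all(drawn %in% w$y))
  }
  expect_error(spin_test(w$X, w$y, w$geom, n_perm = 50),
               class = "ironmap_invalid_argument")
})

test_that("spin_test statistics are invariant to consistent reordering", {
  w <- make_world(n_regions = 30, n_genes = 60, effect = 1, noise_sd = 0.5)
  sp1 <- spin_test(w$X, w$y, w$geom, K = 2, n_perm = 100, seed = 6)
  rp <- sample(30)
  sp2 <- spin_test(w$X[rp, ], w$y[rp], w$geom, K = 2, n_perm = 100, seed = 6)
  expect_equal(sp1$observed, sp2$observed, tolerance = 1e-10)
  gp <- sample(60)
  sp3 <- spin_test(w$X[, gp], w$y, w$geom, K = 2, n_perm = 100, seed = 6)
  expect_equal(sp1$observed, sp3$observed, tolerance = 1e-10)
})

test_that("bootstrap SEs equal the SD of stored replicate weights", {
  w <- make_world(n_regions = 30, n_genes = 60, effect = 2, noise_sd = 0.5)
  tbl <- bootstrap_weights(w$X, w$y, n_boot = 120, seed = 7,
                           keep_replicates = TRUE)
  reps <- attr(tbl, "replicates")
  oracle_se <- apply(reps, 1, sd, na.rm = TRUE)
  expect_equal(tbl$se, unname(oracle_se), tolerance = 1e-12)
  expect_equal(sign(tbl$z[tbl$se > 0]), sign(tbl$weight[tbl$se > 0]))
  # scaling y leaves the z-ranking unchanged
  tbl10 <- bootstrap_weights(w$X, setNames(10 * w$y, names(w$y)),
                             n_boot = 120, seed = 7)
  expect_equal(order(-abs(tbl10$z)), order(-abs(tbl$z)))
})

test_that("null genes have z centred on zero", {
  zs <- vapply(1:30, function(s) {
    w <- make_world(n_regions = 25, n_genes = 60, effect = 0, noise_sd = 0.5,
                    seed = 200 + s)
    y <- setNames(rnorm(25), w$geom$region_id) # unrelated response
    tbl <- bootstrap_weights(w$X, y, n_boot = 100, seed = s)
    mean(tbl$z)
  }, 0)
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("fiqt matches a brute-force BH oracle and shrinks z", {
  brute_bh <- function(p) {
    m <- length(p)
    vapply(seq_len(m), function(i) {
      min(vapply(which(p >= p[i] - 1e-15), function(j) {
        min(1, m * p[j] / sum(p <= p[j] + 1e-15))
      }, 0))
    }, 0)
  }
  set.seed(8)
  z <- rnorm(10, 0, 2)
  f <- fiqt(z)
  p <- 2 * pnorm(-abs(z))
  expect_equal(f$q, brute_bh(p), tolerance = 1e-12)
  expect_true(all(abs(f$z_adj) <= abs(z) + 1e-12))
  # |z1| >= |z2| implies q1 <= q2
  o <- order(-abs(z))
  expect_true(all(diff(f$q[o]) >= -1e-15))
  # single zero z
  f0 <- fiqt(0)
  expect_equal(f0$p, 1); expect_equal(f0$q, 1); expect_equal(f0$z_adj, 0)
  expect_error(fiqt(numeric()), class = "ironmap_empty_input_error")
})

test_that("split_significant partitions by sign and sorts by z", {
  tbl <- data.frame(gene = paste0("g", 1:6),
                    weight = c(1, 2, -1, -2, 3, -3),
                    z = c(2.5, 4, -2.2, -5, 0.1, -0.2),
                    q = c(0.01, 0.001, 0.04, 0.001, 0.9, 0.8))
  sig <- split_significant(tbl)
  expect_identical(sig$up, c("g2", "g1"))       # descending z
  expect_identical(sig$down, c("g4", "g3"))     # ascending z
  expect_length(intersect(sig$up, sig$down), 0)
  allq1 <- tbl; allq1$q <- 1
  s0 <- split_significant(allq1)
  expect_length(s0$up, 0); expect_length(s0$down, 0)
})

test_that("planted genes are recovered in the matching direction", {
  w <- make_world(n_regions = 60, n_genes = 300, n_planted = 20,
                  effect = 2, noise_sd = 0.5, seed = 31)
  tbl <- rank_genes(w$X, w$y, K = 2, n_boot = 200, seed = 32)
  sig <- split_significant(tbl)
  recall <- mean(w$planted %in% sig$up)
  expect_gte(recall, 0.8)
})
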