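# Transcriptome assembly: sample assignment, background filtering,
# scaled-robust-sigmoid normalization, donor aggregation.

test_that("assign_samples matches an exhaustive nearest-neighbour scan", {
  geom <- generate_parcellation(30, seed = 1)
  set.seed(2)
  pts <- matrix(rnorm(150), 50, 3)
  pts <- pts / sqrt(rowSums(pts^2))
  samples <- data.frame(sample_id = paste0("s", 1:50),
                        x = pts[, 1], y = pts[, 2], z = pts[, 3])
  asg <- assign_samples(samples, geom)
  d <- ironmap:::great_circle_distance(pts, geom$centroids)
  brute <- geom$region_id[apply(d, 1, which.min)]
  expect_identical(asg$region_id, brute)
  # a sample exactly at a centroid goes to that region
  at <- data.frame(sample_id = "c5", x = geom$centroids[5, 1],
                   y = geom$centroids[5, 2], z = geom$centroids[5, 3])
  expect_identical(assign_samples(at, geom)$region_id, geom$region_id[5])
  # max_distance leaves remote samples unassigned
  far <- assign_samples(samples, geom, max_distance = 0)
  expect_true(all(is.na(far$region_id[far$distance > 0])))
  expect_error(assign_samples(samples[0, ], geom),
               class = "ironmap_empty_input_error")
})

test_that("equidistant samples break ties toward the lower region id", {
  geom <- make_swap_geometry() # regions 1 (+x) and 3 (+y) are symmetric
  mid <- c(1, 1, 0) / sqrt(2)  # equidistant from +x and +y
  s <- data.frame(sample_id = "m", x = mid[1], y = mid[2], z = mid[3])
  expect_identical(assign_samples(s, geom)$region_id, geom$region_id[1])
})

test_that("filter_background applies the inclusive 50% rule", {
  # 10 samples: enumerate retention around the boundary
  flags <- cbind(all1 = rep(1, 10), none = rep(0, 10),
                 exactly5 = rep(c(1, 0), each = 5),
                 four = rep(c(1, 0), c(4, 6)))
  expect_setequal_chr(filter_background(flags), c("all1", "exactly5"))
  # enumeration oracle on the same fixture
  keep <- colnames(flags)[colSums(flags) / nrow(flags) >= 0.5]
  expect_setequal_chr(filter_background(flags), keep)
  expect_error(filter_background(data.frame(a = 1)),
               class = "ironmap_configuration_error")
})

test_that("normalize_expression matches the hand-evaluated sigmoid", {
  x <- matrix(c(0, 1, 10), 3, 1, dimnames = list(NULL, "g"))
  out <- normalize_expression(x)
  # direct evaluation: median 1, IQR 5 (type-7 quantiles)
  s <- 1 / (1 + exp(-(c(0, 1, 10) - 1) / (5 / 1.35)))
  expected <- (s - min(s)) / (max(s) - min(s))
  expect_equal(as.numeric(out), expected, tolerance = 1e-12)
  # min-max property
  v <- matrix(1:5, 5, 1, dimnames = list(NULL, "g"))
  o <- normalize_expression(v)
  expect_equal(range(o), c(0, 1))
  expect_equal(unname(o[which.min(v), 1]), 0)
  expect_equal(unname(o[which.max(v), 1]), 1)
  # constant gene: all 0.5, flagged
  cm <- matrix(3, 4, 2, dimnames = list(NULL, c("const", "const2")))
  oc <- normalize_expression(cm)
  expect_true(all(oc == 0.5))
  expect_setequal_chr(attr(oc, "constant_genes"), c("const", "const2"))
  expect_error(normalize_expression(x[1, , drop = FALSE]),
               class = "ironmap_degenerate_input_error")
})

test_that("aggregate_donors averages and propagates missingness", {
  a <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("R1", "R2"), "g"))
  b <- matrix(c(0.6, 0.8), 2, 1, dimnames = list(c("R1", "R3"), "g"))
  out <- aggregate_donors(list(a, b))
  expect_equal(out["R1", "g"], 0.4)  # mean of 0.2 and 0.6
  expect_equal(out["R2", "g"], 0.4)  # single donor
  expect_equal(out["R3", "g"], 0.8)
  # single donor is the identity; identical donors change nothing
  expect_equal(aggregate_donors(list(a)), a)
  expect_equal(aggregate_donors(list(a, a)), a)
  expect_error(aggregate_donors(list()), class = "ironmap_empty_input_error")
})

test_that("assembly is equivariant and improves with donor count", {
  geom <- generate_parcellation(20, seed = 3)
  set.seed(4)
  truth <- matrix(runif(20 * 8), 20, 8,
                  dimnames = list(geom$region_id, paste0("g", 1:8)))
  make_donor <- function(seed) {
    set.seed(seed)
    # 3 samples per region, near-centroid jitter
    reg <- rep(seq_len(20), each = 3)
    pts <- geom$centroids[reg, ] + matrix(rnorm(60 * 3, 0, 0.05), 60, 3)
    pts <- pts / sqrt(rowSums(pts^2))
    expr <- truth[reg, ] + matrix(rnorm(60 * 8, 0, 0.3), 60, 8)
    cbind(data.frame(donor_id = paste0("D", seed), sample_id = paste0("s", 1:60),
                     x = pts[, 1], y = pts[, 2], z = pts[, 3]), expr)
  }
  donors <- lapply(1:6, make_donor)
  cor_with_truth <- function(k) {
    samples <- do.call(rbind, donors[seq_len(k)])
    flags <- matrix(1, nrow(samples), 8,
                    dimnames = list(NULL, paste0("g", 1:8)))
    X <- assemble_expression(samples, flags, geom)
    mean(diag(cor(X[geom$region_id, ], truth)))
  }
  r <- vapply(c(1, 3, 6), cor_with_truth, 0)
  expect_true(all(diff(r) > 0)) # monotone improvement at 1, 3, 6 donors
  # gene-order permutation equivariance
  samples <- donors[[1]]
  flags <- matrix(1, nrow(samples), 8, dimnames = list(NULL, paste0("g", 1:8)))
  X1 <- assemble_expression(samples, flags, geom)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  samples2 <- samples[, c(1:5, 5 + perm)]
  X2 <- assemble_expression(samples2, flags[, perm], geom)
  expect_equal(X2, X1[, perm], tolerance = 1e-12)
  # re-running is bit-identical (no hidden randomness)
  expect_identical(X1, assemble_expression(samples, flags, geom))
})
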