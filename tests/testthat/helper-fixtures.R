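# Shared fixtures, built in code at test time.

# A small synthetic world: geometry, smooth disease map, expression matrix
# with one planted set, and a response aligned with the map.
make_world <- function(n_regions = 40L, n_genes = 200L, n_planted = 15L,
                       effect = 2, noise_sd = 0.5, seed = 1L) {
  geom <- generate_parcellation(n_regions, seed = seed)
  dmap <- drop(sample_smooth_fields(geom, 1L, ell = 0.5, seed = seed + 1L))
  es <- expression_spec(
    n_genes = n_genes,
    planted_sets = list(planted = list(genes = seq_len(n_planted),
                                       effect = effect)),
    noise_sd = noise_sd, seed = seed + 2L
  )
  X <- generate_expression(es, geom, dmap)
  y <- stats::setNames(dmap, geom$region_id)
  list(geom = geom, dmap = dmap, X = X, y = y,
       planted = attr(X, "planted")$planted)
}

# A deterministic 12-region geometry whose spin under a 180-degree rotation
# about z is an exact pairwise swap (equatorial cross + two polar rings).
make_swap_geometry <- function() {
  ring <- function(z) {
    r <- sqrt(1 - z^2)
    rbind(c(r, 0, z), c(-r, 0, z), c(0, r, z), c(0, -r, z))
  }
  parcellation_geometry(rbind(ring(0), ring(0.8), ring(-0.8)))
}

rot_z_180 <- diag(c(-1, -1, 1))

# Tiny cohort with exactly known structure (no noise unless asked).
make_cohort <- function(geom, noise_sd = 0, disease_map = 0, sex_effect = 0,
                        alpha = NULL, beta = NULL, seed = 1L,
                        n_controls = 10L, n_cases = 12L) {
  spc <- cohort_spec(
    n_controls = n_controls, n_cases = n_cases,
    alpha = alpha, beta = beta, sex_effect = sex_effect,
    disease_map = disease_map, noise_sd = noise_sd, seed = seed
  )
  generate_cohort(spc, geom)
}

expect_setequal_chr <- function(a, b) {
  testthat::expect_setequal(as.character(a), as.character(b))
}
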