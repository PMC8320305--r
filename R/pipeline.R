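# End-to-end orchestration: configuration, stage sequencing, output files
# and the run manifest. The synthetic mode generates every input itself, so
# a default run needs nothing but an output directory.

#' Default pipeline configuration
#'
#' All stochastic stages have explicit seeds derived from the single
#' top-level `seed`; every threshold is exposed. Counts default to a
#' reduced-but-realistic scale so a full run stays interactive; the study
#' scale (180 regions, 35/96 subjects, ~15.7k genes, 10k permutations) is a
#' matter of turning the dials up.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; stage seeds are deterministic offsets of it.
#' @param n_regions,n_genes,n_controls,n_cases Problem sizes.
#' @param n_perm,n_boot Spin permutations and bootstrap replicates.
#' @param alpha Significance threshold used throughout.
#' @param top_fraction EWCE top-fraction.
#' @param fc_threshold DE fold-change threshold.
#' @param planted_effect,noise_sd Synthetic-mode signal and noise.
#' @param K Number of PLS components.
#' @return A named list of class `ironmap_config`.
#' @export
default_config <- function(out_dir = tempfile("ironmap_run_"), seed = 1L,
                           n_regions = 60L, n_genes = 500L,
                           n_controls = 35L, n_cases = 96L,
                           n_perm = 500L, n_boot = 200L, alpha = 0.05,
                           top_fraction = 0.2, fc_threshold = 1.5,
                           planted_effect = 2, noise_sd = 0.5, K = 2L) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), mode = "synthetic",
         n_regions = n_regions, n_genes = n_genes,
         n_controls = n_controls, n_cases = n_cases,
         n_perm = n_perm, n_boot = n_boot, alpha = alpha,
         top_fraction = top_fraction, fc_threshold = fc_threshold,
         planted_effect = planted_effect, noise_sd = noise_sd, K = K),
    class = c("ironmap_config", "list")
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [default_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An `ironmap_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop_ironmap("unknown config keys: %s", "ironmap_configuration_error",
                 paste(unknown, collapse = ", "))
  }
  cfg[names(raw)] <- raw
  validate_config(cfg)
}

validate_config <- function(cfg) {
  assert_that(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)",
              class = "ironmap_configuration_error")
  assert_that(cfg$top_fraction > 0 && cfg$top_fraction <= 1,
              "top_fraction must be in (0, 1]",
              class = "ironmap_configuration_error")
  assert_that(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
              "an explicit seed is required",
              class = "ironmap_configuration_error")
  class(cfg) <- c("ironmap_config", "list")
  cfg
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL # the hash identifies the analysis, not the paths
  fnv1a32(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}

#' Run the full synthetic-mode pipeline
#'
#' Stage order: generate -> adjust -> score -> PLS -> spin -> bootstrap ->
#' FIQT -> split -> ORA -> EWCE -> DE weighting. Each stage writes its
#' outputs (TSV/JSON, each with a header naming the stage, config hash and
#' seed) and the run ends with an atomically written `manifest.json`
#' recording the config snapshot, per-stage counts, warnings and wall-clock
#' times. Any stage error aborts with the stage name in the message.
#'
#' @param config An `ironmap_config` (see [default_config()],
#'   [read_config()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  stamp <- function(stage, seed = NA) {
    c(sprintf("stage: %s", stage), sprintf("config_hash: %s", hash),
      sprintf("seed: %s", seed))
  }
  manifest <- list(config = unclass(cfg), config_hash = hash,
                   package_version = as.character(utils::packageVersion("ironmap")),
                   stages = list(), warnings = character())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, seed, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        manifest$stages[[name]] <<- list(status = "error",
                                         message = conditionMessage(e))
        write_manifest(manifest, cfg$out_dir, partial = TRUE)
        stop_ironmap("stage '%s' failed: %s", "ironmap_stage_error",
                     name, conditionMessage(e))
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- c(
      list(status = "ok", seed = seed,
           seconds = round(proc.time()[["elapsed"]] - t0, 3)),
      attr(res, "counts") %||% list())
    res
  }
  counts <- function(x, ...) { attr(x, "counts") <- list(...); x }
  seed0 <- cfg$seed
  out <- function(f) file.path(cfg$out_dir, f)

  geom <- stage("geometry", seed0, function() {
    g <- generate_parcellation(cfg$n_regions, seed = seed0)
    write_geometry(g, out("geometry.tsv"))
    counts(g, n_regions = g$n_regions)
  })
  cohort <- stage("cohort", seed0 + 1L, function() {
    spc <- cohort_spec(n_controls = cfg$n_controls, n_cases = cfg$n_cases,
                       seed = seed0 + 1L)
    ch <- generate_cohort(spc, geom)
    write_matrix(ch$values, out("values.tsv"), id_name = "subject_id",
                 comment = stamp("cohort", seed0 + 1L))
    write_table(ch$covariates, out("subjects.tsv"),
                comment = stamp("cohort", seed0 + 1L))
    counts(ch, n_subjects = nrow(ch$values))
  })
  planted_n <- max(20L, round(0.05 * cfg$n_genes))
  expr <- stage("expression", seed0 + 2L, function() {
    spc <- expression_spec(
      n_genes = cfg$n_genes,
      planted_sets = list(planted = list(genes = seq_len(planted_n),
                                         effect = cfg$planted_effect)),
      noise_sd = cfg$noise_sd, seed = seed0 + 2L)
    X <- generate_expression(spc, geom, cohort$truth$disease_map)
    write_matrix(X, out("expression_matrix.tsv"), id_name = "region_id",
                 comment = stamp("expression", seed0 + 2L))
    counts(X, n_genes = ncol(X))
  })
  scores <- stage("score", NA, function() {
    cov <- cohort$covariates
    models <- fit_age_models(cohort$values, cov)
    adj <- age_adjust(cohort$values, models, cov)
    adj <- sex_adjust(adj, cov)
    ctrl <- adj[cov$group == "control", , drop = FALSE]
    case <- adj[cov$group == "case", , drop = FALSE]
    sc <- compute_qsm_scores(ctrl, case)
    write_table(sc, out("qsm_scores.tsv"), comment = stamp("score"))
    write_table(compare_regions(ctrl, case), out("region_stats.tsv"),
                comment = stamp("score"))
    counts(sc, n_scored = sum(!is.na(sc$score)))
  })
  spin <- stage("spin", seed0 + 3L, function() {
    sp <- spin_test(expr, scores, geom, K = cfg$K, n_perm = cfg$n_perm,
                    seed = seed0 + 3L, store_relabellings = FALSE)
    jsonlite::write_json(
      list(varexp_y = sp$observed, selected = sp$selected,
           p_selected = sp$p, p_component = sp$p_component,
           n_perm = sp$n_perm, config_hash = hash),
      out("pls_model.json"), auto_unbox = TRUE, digits = NA)
    write_table(data.frame(perm = seq_len(sp$n_perm),
                           stat = sp$null_selected),
                out("spin_null.tsv"), comment = stamp("spin", seed0 + 3L))
    counts(sp, p = sp$p, selected = sp$selected)
  })
  weights <- stage("gene_ranking", seed0 + 4L, function() {
    tbl <- rank_genes(expr, scores, K = cfg$K, n_boot = cfg$n_boot,
                      seed = seed0 + 4L)
    write_table(tbl, out("gene_weights.tsv"),
                comment = stamp("gene_ranking", seed0 + 4L))
    counts(tbl, n_significant = sum(tbl$q < cfg$alpha))
  })
  sig <- split_significant(weights, alpha = cfg$alpha)
  collection <- stage("genesets", seed0 + 5L, function() {
    planted <- attr(expr, "planted")$planted
    gl <- list(PLANTED = planted)
    others <- setdiff(colnames(expr), planted)
    dec <- local_seed(seed0 + 5L, {
      lapply(1:10, function(i) sample(others, length(planted)))
    })
    names(dec) <- sprintf("RANDOM%02d", 1:10)
    gl <- c(gl, dec)
    write_gmt(gl, out("genesets.gmt"))
    counts(as_geneset_list(gl), n_terms = length(gl))
  })
  stage("ora", NA, function() {
    for (dir in c("up", "down")) {
      if (!length(sig[[dir]])) next
      tab <- adjust_and_filter(
        ora_test(sig[[dir]], collection, weights$gene), alpha = cfg$alpha,
        min_term_size = 1L)
      write_table(tab, out(sprintf("enrichment_%s.tsv", dir)),
                  comment = stamp("ora"))
    }
    counts(list(), n_up = length(sig$up), n_down = length(sig$down))
  })
  stage("ewce", seed0 + 6L, function() {
    types <- c("ASC", "GABA", "GLU", "MG", "ODC", "OPC")
    planted <- attr(expr, "planted")$planted
    markers <- list(ASC = planted[seq_len(min(10L, length(planted)))])
    ctm <- generate_cell_specificity(cfg$n_genes, types, markers,
                                     seed = seed0 + 6L)
    write_matrix(ctm, out("cell_type_means.tsv"), id_name = "gene",
                 comment = stamp("ewce", seed0 + 6L))
    spec_mat <- compute_specificity(ctm)
    for (dir in c("up", "down")) {
      tg <- tryCatch(select_top_fraction(weights, cfg$top_fraction, dir,
                                         alpha = cfg$alpha),
                     ironmap_empty_input_error = function(e) character())
      if (length(tg) < 5L) next
      res <- ewce_test(tg, spec_mat, weights$gene, n_boot = cfg$n_boot,
                       seed = seed0 + 7L)
      write_table(res, out(sprintf("ewce_%s.tsv", dir)),
                  comment = stamp("ewce", seed0 + 7L))
    }
    counts(list(), n_cell_types = length(types))
  })
  stage("de_weighting", seed0 + 8L, function() {
    planted <- attr(expr, "planted")$planted
    de <- generate_de_lists(list(planted_pd = planted), "up",
                            seed = seed0 + 8L)
    de <- fold_change_filter(de, cfg$fc_threshold)
    res <- lapply(split(de, de$study), function(d) {
      r <- weight_permutation_test(d$gene, weights, n_perm = cfg$n_perm,
                                   seed = seed0 + 9L)
      data.frame(study = d$study[1], contrast = d$contrast[1],
                 observed = r$observed, null_mean = r$null_mean,
                 null_sd = r$null_sd, p_up = r$p_up, p_down = r$p_down,
                 n_matched = r$n_matched)
    })
    res <- do.call(rbind, res)
    write_table(res, out("de_weighting.tsv"),
                comment = stamp("de_weighting", seed0 + 9L))
    counts(res, n_lists = nrow(res))
  })
  manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 3)
  manifest$input_checksums <- file_checksums(cfg$out_dir)
  write_manifest(manifest, cfg$out_dir)
  invisible(manifest)
}

file_checksums <- function(dir) {
  fs <- sort(setdiff(list.files(dir), "manifest.json"))
  stats::setNames(
    lapply(fs, function(f) fnv1a32(readLines(file.path(dir, f), warn = FALSE))),
    fs)
}

write_manifest <- function(manifest, out_dir, partial = FALSE) {
  manifest$partial <- partial
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Command-line entry point
#'
#' `Rscript -e 'ironmap::ironmap_cli()' run --config cfg.yaml` or, with no
#' config, a default synthetic run: `ironmap_cli(c("run", "--out", dir))`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return The run manifest, invisibly.
#' @export
ironmap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: ironmap run [--config <yaml|json>] [--out <dir>] [--seed <int>]"
  if (!length(args) || args[1] != "run") {
    message(usage)
    return(invisible(NULL))
  }
  getopt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  cfg <- if (!is.null(getopt("--config"))) read_config(getopt("--config"))
         else default_config()
  if (!is.null(getopt("--out"))) cfg$out_dir <- getopt("--out")
  if (!is.null(getopt("--seed"))) cfg$seed <- as.integer(getopt("--seed"))
  invisible(run_pipeline(cfg))
}
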