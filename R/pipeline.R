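#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run in one validated
#' object. The whole configuration (including the generator settings) is
#' serialized into the results directory so a run is reproducible from its
#' manifest alone.
#'
#' @param synthetic a [synthetic_config()] driving the simulated study.
#' @param top_n query-tail size for the cross-species GSEA QC (default 200).
#' @param n_perm gene permutations for signature-level enrichment and MARINa
#'   (default 1000).
#' @param n_perm_sample permutations for per-sample activity (default 100).
#' @param weight_exponent signature-level GSEA weight exponent (default 1).
#' @param marina_weight regulon-enrichment weight exponent (default 0).
#' @param p_conserved combined-p cutoff for conserved MRs (default 1e-4).
#' @param p_cox Wald p cutoff in the Cox screen (default 0.05).
#' @param n_candidates candidate MR set size for stratification (default 8).
#' @param kmeans_restarts k-means restarts (default 100).
#' @param null_iterations random-set null iterations (default 1000).
#' @param annotation optional gene list for [annotation_filter()].
#' @param seed global seed (defaults to the synthetic config's seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), top_n = 200,
                            n_perm = 1000, n_perm_sample = 100,
                            weight_exponent = 1, marina_weight = 0, p_conserved = 1e-4,
                            p_cox = 0.05, n_candidates = 8,
                            kmeans_restarts = 100, null_iterations = 1000,
                            annotation = NULL, seed = NULL) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  cfg <- list(synthetic = synthetic,
              top_n = assert_count(top_n, "top_n"),
              n_perm = assert_count(n_perm, "n_perm"),
              n_perm_sample = assert_count(n_perm_sample, "n_perm_sample"),
              weight_exponent = weight_exponent, marina_weight = marina_weight,
              p_conserved = p_conserved, p_cox = p_cox,
              n_candidates = assert_count(n_candidates, "n_candidates"),
              kmeans_restarts = assert_count(kmeans_restarts, "kmeans_restarts"),
              null_iterations = assert_count(null_iterations, "null_iterations"),
              annotation = annotation,
              seed = assert_count(seed %||% synthetic$seed, "seed", 0))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  y$synthetic <- NULL
  if (!is.null(y$synthetic_seed)) y$synthetic_seed <- NULL
  do.call(pipeline_config, c(list(synthetic = syn), y))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$synthetic <- unclass(y$synthetic)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Principal component analysis of an expression matrix
#'
#' Exploratory QC decomposition: samples are observations, genes variables,
#' gene-centered, unscaled. Each component's sign is fixed so its
#' largest-|loading| gene loads positively, making scores platform-independent.
#'
#' @param x genes x samples matrix (>= 3 samples).
#' @param groups optional named group vector for the scores table.
#' @return list with `scores` (data.frame: sample, PC columns, group) and
#'   `variance_explained` (fraction per component).
#' @export
compute_pca <- function(x, groups = NULL) {
  if (ncol(x) < 3L) stop("PCA needs >= 3 samples", call. = FALSE)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  df <- data.frame(sample = rownames(scores), scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(groups)) df$group <- unname(groups[df$sample])
  list(scores = df, variance_explained = ve)
}

write_stage <- function(df, outdir, name) {
  utils::write.table(as.data.frame(df), file.path(outdir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full cross-species MR discovery pipeline
#'
#' Executes, on a synthetic shared-truth study generated from the
#' configuration: differential signatures for both species -> cross-species
#' GSEA QC -> MARINa MR activity per species -> Stouffer integration ->
#' conserved-MR filtering (optional annotation filter) -> per-patient
#' activity on the survival cohort -> Cox screen -> candidate selection ->
#' k-means stratification -> Kaplan-Meier/log-rank -> empirical random-set
#' null. Every table is written as TSV into `outdir` together with a JSON
#' manifest of parameters and derived stage seeds. A stage failure aborts
#' with an error naming the stage; tables already written are retained.
#'
#' @param config a [pipeline_config()].
#' @param outdir results directory (created if missing).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, outdir = tempfile("mrpipe_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    mr_log("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  manifest <- list(package_version = as.character(utils::packageVersion("mrpipe")),
                   seed = seed, parameters = list(
                     top_n = config$top_n, n_perm = config$n_perm,
                     n_perm_sample = config$n_perm_sample,
                     weight_exponent = config$weight_exponent,
                     marina_weight = config$marina_weight,
                     p_conserved = config$p_conserved, p_cox = config$p_cox,
                     n_candidates = config$n_candidates,
                     kmeans_restarts = config$kmeans_restarts,
                     null_iterations = config$null_iterations),
                   stage_seeds = list())
  note_seed <- function(tag) {
    manifest$stage_seeds[[tag]] <<- derive_seed(seed, tag)
  }

  study <- stage("simulate", generate_cross_species_study(config$synthetic))
  write_pipeline_config(config, file.path(outdir, "config.yaml"))
  write_interactome(study$interactome, file.path(outdir, "interactome_mouse.tsv"))
  write_interactome(study$human_interactome,
                    file.path(outdir, "interactome_human.tsv"))
  write_ortholog_map(study$ortholog_map, file.path(outdir, "ortholog_map.tsv"))
  write_expression(study$mouse$expr, file.path(outdir, "expression_mouse.tsv"))
  write_expression(study$human$expr, file.path(outdir, "expression_human.tsv"))
  write_labels(study$mouse$labels, file.path(outdir, "labels_mouse.tsv"))
  write_labels(study$human$labels, file.path(outdir, "labels_human.tsv"))
  write_expression(study$survival$expr, file.path(outdir, "expression_survival.tsv"))
  write_clinical(study$survival$clinical, file.path(outdir, "clinical.tsv"))
  write_truth(study$survival$truth, file.path(outdir, "planted_truth.json"))

  sig_mouse <- stage("signature_mouse",
                     welch_t_signature(study$mouse$expr, study$mouse$labels,
                                       "group1", "group2"))
  sig_human <- stage("signature_human",
                     welch_t_signature(study$human$expr, study$human$labels,
                                       "group1", "group2"))
  write_signature(sig_mouse, file.path(outdir, "signature_mouse.tsv"))
  write_signature(sig_human, file.path(outdir, "signature_human.tsv"))

  pca <- stage("pca", compute_pca(study$mouse$expr, study$mouse$labels))
  write_stage(pca$scores[, c("sample", "PC1", "PC2", "group")], outdir,
              "pca_scores_mouse.tsv")
  write_stage(data.frame(component = seq_along(pca$variance_explained),
                         variance_fraction = pca$variance_explained),
              outdir, "pca_variance_mouse.tsv")

  note_seed("gsea_qc")
  gsea <- stage("gsea_qc", {
    hum <- humanize_signature(sig_mouse, study$ortholog_map)
    two_tail_gsea(hum, sig_human, top_n = config$top_n, n_perm = config$n_perm,
                  seed = derive_seed(seed, "gsea_qc"), w = config$weight_exponent)
  })
  write_stage(data.frame(tail = c("positive", "negative"),
                         es = c(gsea$positive$es, gsea$negative$es),
                         nes = c(gsea$positive$nes, gsea$negative$nes),
                         p = c(gsea$positive$p, gsea$negative$p),
                         top_n = gsea$top_n),
              outdir, "gsea_qc.tsv")

  note_seed("marina_mouse"); note_seed("marina_human")
  mr_mouse <- stage("marina_mouse",
                    marina_activity(study$interactome, sig_mouse,
                                    n_perm = config$n_perm,
                                    seed = derive_seed(seed, "marina_mouse"),
                                    w = config$marina_weight))
  mr_human <- stage("marina_human",
                    marina_activity(study$human_interactome, sig_human,
                                    n_perm = config$n_perm,
                                    seed = derive_seed(seed, "marina_human"),
                                    w = config$marina_weight))
  write_stage(mr_mouse, outdir, "marina_mouse.tsv")
  write_stage(mr_human, outdir, "marina_human.tsv")

  conserved <- stage("integrate",
                     stouffer_integrate(mr_mouse, mr_human, study$ortholog_map))
  write_stage(conserved, outdir, "conserved_mr.tsv")
  selected <- stage("filter_conserved",
                    filter_conserved(conserved, p_threshold = config$p_conserved))
  if (!is.null(config$annotation)) {
    selected <- stage("annotation_filter",
                      annotation_filter(selected, config$annotation))
  }
  write_stage(selected, outdir, "conserved_mr_filtered.tsv")

  note_seed("activity")
  activity <- stage("activity",
                    sample_activity_matrix(study$human_interactome,
                                           study$survival$expr,
                                           n_perm = config$n_perm_sample,
                                           seed = derive_seed(seed, "activity"),
                                           w = config$marina_weight))
  write_stage(data.frame(regulator = rownames(activity), activity,
                         check.names = FALSE), outdir, "activity_matrix.tsv")

  screen <- stage("cox_screen", cox_screen(activity, study$survival$clinical))
  write_stage(screen, outdir, "cox_screen.tsv")

  candidates <- stage("select_candidates", {
    ok <- screen[!is.na(screen$p) & screen$p < config$p_cox &
                   screen$loghr > 0, , drop = FALSE]
    ok <- ok[ok$regulator %in% selected$regulator, , drop = FALSE]
    if (nrow(ok) == 0L) stop("no conserved MR passes the Cox screen")
    utils::head(ok$regulator, config$n_candidates)
  })
  writeLines(candidates, file.path(outdir, "candidate_mrs.txt"))

  note_seed("stratify"); note_seed("null")
  labels <- stage("stratify",
                  kmeans_stratify(activity[candidates, , drop = FALSE],
                                  n_restarts = config$kmeans_restarts,
                                  seed = derive_seed(seed, "stratify")))
  write_labels(stats::setNames(as.character(labels), names(labels)),
               file.path(outdir, "strata.tsv"))
  km <- stage("km_logrank", km_logrank(labels, study$survival$clinical))
  null <- stage("random_set_null",
                random_set_null(activity, study$survival$clinical,
                                observed_p = km$logrank_p,
                                target_set_size = config$n_candidates,
                                n_iter = config$null_iterations,
                                seed = derive_seed(seed, "null"),
                                n_restarts = config$kmeans_restarts,
                                candidate_set = candidates))
  sf <- summary(km$fit)
  write_stage(data.frame(group = sub("^grp=", "", as.character(sf$strata)),
                         time = sf$time, n_risk = sf$n.risk,
                         n_event = sf$n.event, survival = sf$surv),
              outdir, "km_curves.tsv")
  write_stage(data.frame(logrank_chisq = km$logrank_chisq,
                         logrank_p = km$logrank_p, hr = km$hr,
                         hr_lo = km$hr_ci[1], hr_hi = km$hr_ci[2],
                         empirical_p = null$empirical_p),
              outdir, "survival_summary.tsv")
  jsonlite::write_json(list(observed_p = null$observed_p,
                            empirical_p = null$empirical_p,
                            null_p = null$null_p,
                            n_degenerate = null$n_degenerate),
                       file.path(outdir, "null_model.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outdir = outdir, study = study, sig_mouse = sig_mouse,
                 sig_human = sig_human, pca = pca, gsea = gsea,
                 mr_mouse = mr_mouse, mr_human = mr_human,
                 conserved = conserved, selected = selected,
                 activity = activity, screen = screen,
                 candidates = candidates, labels = labels, km = km,
                 null = null, manifest = manifest))
}
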