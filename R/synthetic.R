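#' Synthetic study configuration
#'
#' Parameters of the synthetic data generator. The generator emulates the
#' study design the pipeline targets: a mouse two-group cohort (pre-metastatic
#' vs metastatic, `n_per_group` each), a human survival cohort whose hazard
#' depends on a latent per-patient activity shared by the planted regulators,
#' and a mouse-to-human ortholog map with drop-outs and one-to-many entries.
#' All randomness derives from the single `seed` by fixed sub-seeding, so any
#' stage regenerates identically in isolation.
#'
#' @param n_genes gene universe size (default 2000).
#' @param n_regulators number of regulons (default 100).
#' @param regulon_size_range inclusive target-count range (default c(20, 60)).
#' @param frac_positive_targets fraction of mode +1 edges (default 0.7).
#' @param n_planted number of truly active regulators (default 8).
#' @param activity_effect expression shift per unit mode (delta, default 1.0).
#' @param noise_sd Gaussian noise standard deviation (default 1.0).
#' @param n_per_group samples per phenotype group (default 8).
#' @param n_patients survival-cohort size (default 200).
#' @param hazard_beta log-hazard per unit latent activity (default 0.8).
#' @param baseline_rate exponential event rate at zero activity, events per
#'   time unit (default 0.02).
#' @param censor_time administrative censoring time (default 120).
#' @param ortholog_drop_frac fraction of mouse genes with no ortholog
#'   (default 0.05).
#' @param ortholog_dup_frac fraction mapped to two human ids (default 0.02).
#' @param seed global integer seed (default 1).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_regulators = 100,
                             regulon_size_range = c(20, 60),
                             frac_positive_targets = 0.7, n_planted = 8,
                             activity_effect = 1.0, noise_sd = 1.0,
                             n_per_group = 8, n_patients = 200,
                             hazard_beta = 0.8, baseline_rate = 0.02,
                             censor_time = 120, ortholog_drop_frac = 0.05,
                             ortholog_dup_frac = 0.02, seed = 1) {
  cfg <- list(n_genes = assert_count(n_genes, "n_genes", 2),
              n_regulators = assert_count(n_regulators, "n_regulators"),
              regulon_size_range = c(assert_count(regulon_size_range[1], "regulon size min"),
                                     assert_count(regulon_size_range[2], "regulon size max")),
              frac_positive_targets = assert_fraction(frac_positive_targets,
                                                      "frac_positive_targets"),
              n_planted = assert_count(n_planted, "n_planted"),
              activity_effect = activity_effect, noise_sd = noise_sd,
              n_per_group = assert_count(n_per_group, "n_per_group"),
              n_patients = assert_count(n_patients, "n_patients"),
              hazard_beta = hazard_beta, baseline_rate = baseline_rate,
              censor_time = censor_time,
              ortholog_drop_frac = assert_fraction(ortholog_drop_frac,
                                                   "ortholog_drop_frac"),
              ortholog_dup_frac = assert_fraction(ortholog_dup_frac,
                                                  "ortholog_dup_frac"),
              seed = assert_count(seed, "seed", 0))
  if (cfg$regulon_size_range[2] > cfg$n_genes - 1) {
    stop("regulon_size_range max must be below n_genes", call. = FALSE)
  }
  if (cfg$regulon_size_range[1] > cfg$regulon_size_range[2]) {
    stop("regulon_size_range must be increasing", call. = FALSE)
  }
  if (cfg$n_planted > cfg$n_regulators) {
    stop("n_planted cannot exceed n_regulators", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

mouse_gene_ids <- function(n) sprintf("mg%04d", seq_len(n))

#' Generate a synthetic signed interactome
#'
#' Draws `n_regulators` regulator genes from the universe and gives each a
#' regulon of uniformly sized target sets (within `regulon_size_range`),
#' excluding self-targets; each edge carries mode +1 with probability
#' `frac_positive_targets` (else -1) and weight 1.
#'
#' @param config a [synthetic_config()].
#' @return An `interactome` over the mouse gene universe.
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- mouse_gene_ids(config$n_genes)
  with_seed(config$seed, "interactome", {
    regulators <- sample(genes, config$n_regulators)
    sizes <- sample(seq(config$regulon_size_range[1], config$regulon_size_range[2]),
                    config$n_regulators, replace = TRUE)
    edges <- do.call(rbind, lapply(seq_along(regulators), function(i) {
      tg <- sample(setdiff(genes, regulators[i]), sizes[i])
      data.frame(regulator = regulators[i], target = tg,
                 mode = ifelse(stats::runif(sizes[i]) < config$frac_positive_targets,
                               1, -1),
                 weight = 1, stringsAsFactors = FALSE)
    }))
    # generated regulons start at the configured minimum size; a slightly
    # lower retention floor keeps regulons that lose a few targets to
    # ortholog drop-outs or signature restriction
    interactome(edges, universe = genes,
                min_regulon_size = min(15, config$regulon_size_range[1]))
  })
}

# planted regulator choice shared by all cohorts derived from one config
planted_regulators <- function(config, interactome) {
  regs <- sort(names(interactome$regulons), method = "radix")
  with_seed(config$seed, "planted", sample(regs, config$n_planted))
}

# summed mode * effect footprint of the planted regulons on the gene universe
planted_shift <- function(config, interactome, planted) {
  shift <- stats::setNames(numeric(length(interactome$universe)),
                           interactome$universe)
  for (r in planted) {
    reg <- interactome$regulons[[r]]
    shift[reg$target] <- shift[reg$target] + reg$mode * config$activity_effect
  }
  shift
}

#' Generate a two-group expression cohort with planted MR activity
#'
#' Group 1 is pure baseline noise; group 2 additionally shifts every target
#' of every planted regulator by `mode * activity_effect` (summed when a gene
#' is targeted by several planted regulators). Emulates a pre-metastatic vs
#' metastatic contrast in which the planted regulators become active.
#'
#' @param config a [synthetic_config()].
#' @param interactome from [generate_interactome()] (or a translated copy).
#' @param planted optional regulator ids; defaults to a seed-determined draw
#'   shared with the survival cohort.
#' @param tag character mixed into the noise sub-seed, so e.g. mouse and
#'   human cohorts built from one truth get independent noise.
#' @return list with `expr` (genes x samples matrix), `labels` (named vector,
#'   groups `"group1"`/`"group2"`) and `truth` (a `planted_truth`).
#' @export
generate_two_group_cohort <- function(config, interactome, planted = NULL,
                                      tag = "cohort") {
  stopifnot(inherits(config, "synthetic_config"), inherits(interactome, "interactome"))
  planted <- planted %||% planted_regulators(config, interactome)
  shift <- planted_shift(config, interactome, planted)
  genes <- interactome$universe
  n <- config$n_per_group
  samples <- c(sprintf("%s_g1_s%02d", tag, seq_len(n)),
               sprintf("%s_g2_s%02d", tag, seq_len(n)))
  expr <- with_seed(config$seed, c(tag, "two_group_noise"),
                    matrix(stats::rnorm(length(genes) * 2 * n, sd = config$noise_sd),
                           length(genes), 2 * n,
                           dimnames = list(genes, samples)))
  expr[, (n + 1):(2 * n)] <- expr[, (n + 1):(2 * n)] + shift
  labels <- stats::setNames(rep(c("group1", "group2"), each = n), samples)
  truth <- structure(list(planted_regulators = planted,
                          effect = stats::setNames(rep(config$activity_effect,
                                                       length(planted)), planted),
                          shift = shift),
                     class = "planted_truth")
  list(expr = expr, labels = labels, truth = truth)
}

#' Generate a survival cohort with activity-dependent hazard
#'
#' Each patient carries a latent activity `a_i ~ N(0, 1)` shared across the
#' planted regulators; expression is baseline noise plus
#' `mode * activity_effect * a_i` on planted targets. Event times are
#' exponential with rate `baseline_rate * exp(hazard_beta * a_i)`, censored
#' administratively at `censor_time`.
#'
#' @inheritParams generate_two_group_cohort
#' @return list with `expr`, `clinical` (a [clinical_table()]) and `truth`
#'   (includes the per-patient latent activity).
#' @export
generate_survival_cohort <- function(config, interactome, planted = NULL,
                                     tag = "surv") {
  stopifnot(inherits(config, "synthetic_config"), inherits(interactome, "interactome"))
  if (config$n_patients < 20L) {
    stop("survival cohort needs >= 20 patients", call. = FALSE)
  }
  planted <- planted %||% planted_regulators(config, interactome)
  shift <- planted_shift(config, interactome, planted)
  genes <- interactome$universe
  np <- config$n_patients
  patients <- sprintf("%s_p%03d", tag, seq_len(np))
  out <- with_seed(config$seed, c(tag, "survival"), {
    a <- stats::rnorm(np)
    expr <- matrix(stats::rnorm(length(genes) * np, sd = config$noise_sd),
                   length(genes), np, dimnames = list(genes, patients))
    expr <- expr + outer(shift, a)
    rate <- config$baseline_rate * exp(config$hazard_beta * a)
    t_event <- stats::rexp(np, rate)
    list(a = a, expr = expr, t_event = t_event)
  })
  event <- as.integer(out$t_event <= config$censor_time)
  time <- pmin(out$t_event, config$censor_time)
  clinical <- clinical_table(data.frame(sample = patients, time = time,
                                        event = event, stringsAsFactors = FALSE))
  truth <- structure(list(planted_regulators = planted,
                          effect = stats::setNames(rep(config$activity_effect,
                                                       length(planted)), planted),
                          latent_activity = stats::setNames(out$a, patients),
                          shift = shift),
                     class = "planted_truth")
  list(expr = out$expr, clinical = clinical, truth = truth)
}

#' Generate a mouse-to-human ortholog map
#'
#' Renames each mouse gene to a distinct human id, omits an exact
#' `round(ortholog_drop_frac * n)` of genes, and maps an exact
#' `round(ortholog_dup_frac * n)` of the remaining genes to two human ids
#' (one-to-many rows share the mouse id).
#'
#' @param config a [synthetic_config()].
#' @param universe character vector of mouse gene ids.
#' @return data.frame (`source_gene`, `target_gene`).
#' @export
generate_ortholog_map <- function(config, universe) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!length(universe)) stop("gene universe is empty", call. = FALSE)
  n <- length(universe)
  n_drop <- round(config$ortholog_drop_frac * n)
  with_seed(config$seed, "orthologs", {
    dropped <- if (n_drop > 0) sample(universe, n_drop) else character(0)
    kept <- setdiff(universe, dropped)
    n_dup <- round(config$ortholog_dup_frac * length(kept))
    dup <- if (n_dup > 0) sample(kept, n_dup) else character(0)
    primary <- data.frame(source_gene = kept,
                          target_gene = toupper(sub("^mg", "HG", kept)),
                          stringsAsFactors = FALSE)
    extra <- if (length(dup)) {
      data.frame(source_gene = dup,
                 target_gene = paste0(toupper(sub("^mg", "HG", dup)), "B"),
                 stringsAsFactors = FALSE)
    } else primary[0, ]
    map <- rbind(primary, extra)
    map[order(map$source_gene, map$target_gene, method = "radix"), ,
        drop = FALSE]
  })
}

#' Generate a shared-truth cross-species study
#'
#' One mouse interactome and planted regulator set drive everything: a mouse
#' two-group cohort, an ortholog map, a translated human interactome, a human
#' two-group cohort with independent noise, and a human survival cohort. This
#' is the full synthetic study the pipeline's end-to-end tests run on.
#'
#' @param config a [synthetic_config()].
#' @return list with `interactome` (mouse), `human_interactome`,
#'   `ortholog_map`, `planted` (mouse ids), `planted_human` (translated ids),
#'   `mouse` and `human` two-group cohorts, and `survival` (human cohort).
#' @export
generate_cross_species_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  net <- generate_interactome(config)
  planted <- planted_regulators(config, net)
  map <- generate_ortholog_map(config, net$universe)
  # planted regulators must survive translation for the truth to be shared
  lut <- map[!duplicated(map$source_gene), ]
  missing <- setdiff(planted, lut$source_gene)
  if (length(missing)) {
    map <- rbind(map, data.frame(source_gene = missing,
                                 target_gene = toupper(sub("^mg", "HG", missing)),
                                 stringsAsFactors = FALSE))
    map <- map[order(map$source_gene, map$target_gene, method = "radix"), ,
               drop = FALSE]
  }
  hnet <- translate_interactome(net, map)
  lut <- stats::setNames(map$target_gene[!duplicated(map$source_gene)],
                         map$source_gene[!duplicated(map$source_gene)])
  planted_h <- unname(lut[planted])
  mouse <- generate_two_group_cohort(config, net, planted, tag = "mouse")
  human <- generate_two_group_cohort(config, hnet, planted_h, tag = "human")
  surv <- generate_survival_cohort(config, hnet, planted_h, tag = "human")
  list(interactome = net, human_interactome = hnet, ortholog_map = map,
       planted = planted, planted_human = planted_h,
       mouse = mouse, human = human, survival = surv)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("Planted truth: %d regulators (%s)\n",
              length(x$planted_regulators),
              paste(utils::head(x$planted_regulators, 8), collapse = ", ")))
  if (!is.null(x$latent_activity)) {
    cat(sprintf("  latent activity over %d patients (sd %.2f)\n",
                length(x$latent_activity), stats::sd(x$latent_activity)))
  }
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic study configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = "-")))
  }
  invisible(x)
}
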