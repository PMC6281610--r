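#' Read / validate a clinical table
#'
#' @param x data.frame with columns `sample`, `time` (> 0) and `event`
#'   (0 = censored, 1 = endpoint occurred).
#' @return The validated data.frame (class `clinical_table`).
#' @export
clinical_table <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("sample", "time", "event") %in% names(x))) {
    stop("clinical table needs columns sample, time, event", call. = FALSE)
  }
  if (anyDuplicated(x$sample)) stop("duplicate sample ids", call. = FALSE)
  if (!all(is.finite(x$time) & x$time > 0)) stop("times must be > 0", call. = FALSE)
  if (!all(x$event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  class(x) <- c("clinical_table", "data.frame")
  x
}

match_clinical <- function(activity, clinical) {
  shared <- intersect(colnames(activity), clinical$sample)
  if (!length(shared)) stop("no shared samples between activity and clinical table",
                            call. = FALSE)
  list(activity = activity[, shared, drop = FALSE],
       clinical = clinical[match(shared, clinical$sample), , drop = FALSE])
}

#' Univariate Cox screen of MR activities
#'
#' Fits one proportional-hazards model per regulator with its continuous
#' per-sample activity as the only covariate, reporting the log hazard ratio
#' per activity unit and the Wald test. Non-converged or constant-activity
#' fits are flagged, never silently dropped.
#'
#' @param activity regulators x samples activity matrix
#'   (see [sample_activity_matrix()]).
#' @param clinical a [clinical_table()].
#' @param min_samples,min_events minimum cohort size (defaults 20 and 5);
#'   survival screens are unstable below these.
#' @return A `cox_screen_table`: data.frame with `regulator`, `loghr`, `se`,
#'   `wald_z`, `p`, `converged`.
#' @export
cox_screen <- function(activity, clinical, min_samples = 20, min_events = 5) {
  clinical <- clinical_table(clinical)
  mc <- match_clinical(activity, clinical)
  act <- mc$activity; cl <- mc$clinical
  if (ncol(act) < min_samples) {
    stop(sprintf("need >= %d samples (got %d)", min_samples, ncol(act)),
         call. = FALSE)
  }
  if (sum(cl$event) == 0) stop("clinical table has zero events", call. = FALSE)
  if (sum(cl$event) < min_events) {
    stop(sprintf("need >= %d events (got %d)", min_events, sum(cl$event)),
         call. = FALSE)
  }
  srv <- survival::Surv(cl$time, cl$event)
  rows <- lapply(rownames(act), function(reg) {
    a <- act[reg, ]
    if (!all(is.finite(a)) || stats::sd(a) == 0) {
      return(data.frame(regulator = reg, loghr = NA_real_, se = NA_real_,
                        wald_z = NA_real_, p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    fit <- tryCatch({
      f <- survival::coxph(srv ~ a)
      s <- summary(f)
      data.frame(regulator = reg, loghr = unname(stats::coef(f)),
                 se = s$coefficients[1, "se(coef)"],
                 wald_z = s$coefficients[1, "z"],
                 p = s$coefficients[1, "Pr(>|z|)"],
                 converged = is.finite(stats::coef(f)),
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      # retry quietly; coxph warnings (e.g. monotone likelihood) flag the row
      fit <- suppressWarnings(tryCatch({
        f <- survival::coxph(srv ~ a)
        data.frame(regulator = reg, loghr = unname(stats::coef(f)),
                   se = sqrt(diag(stats::vcov(f)))[1],
                   wald_z = unname(stats::coef(f)) / sqrt(diag(stats::vcov(f)))[1],
                   p = 2 * stats::pnorm(-abs(unname(stats::coef(f)) /
                                               sqrt(diag(stats::vcov(f)))[1])),
                   converged = FALSE, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(regulator = reg, loghr = NA_real_, se = NA_real_,
                   wald_z = NA_real_, p = NA_real_, converged = FALSE,
                   stringsAsFactors = FALSE)
      }))
    }
    fit
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$regulator, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("cox_screen_table", "data.frame")
  out
}

#' @export
print.cox_screen_table <- function(x, ...) {
  cat(sprintf("Cox screen: %d regulators, %d with Wald p < 0.05, %d flagged\n",
              nrow(x), sum(x$p < 0.05, na.rm = TRUE), sum(!x$converged)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

#' Two-group patient stratification by k-means on MR activity
#'
#' Clusters patients into two groups in the activity space of a candidate MR
#' set (Euclidean k-means, best of `n_restarts` starts by within-cluster sum
#' of squares). The cluster with the larger mean activity, averaged over the
#' MRs, is labeled `"high"`.
#'
#' @param activity activity matrix restricted to the candidate MRs
#'   (regulators x samples, >= 1 row, >= 2 columns).
#' @param n_restarts k-means restarts (default 100).
#' @param seed integer seed (k-means initialization).
#' @return Named factor (levels `high`, `low`), one label per sample.
#' @export
kmeans_stratify <- function(activity, n_restarts = 100, seed = 1) {
  m <- t(as.matrix(activity))  # samples x MRs
  if (nrow(m) < 2L) stop("need >= 2 samples to stratify", call. = FALSE)
  if (nrow(unique(m)) < 2L) {
    stop("all patients identical in activity space; clustering is degenerate",
         call. = FALSE)
  }
  km <- with_seed(seed, "kmeans_stratify",
                  stats::kmeans(m, centers = 2, nstart = n_restarts))
  center_mean <- rowMeans(km$centers)
  high_cluster <- which.max(center_mean)
  lab <- factor(ifelse(km$cluster == high_cluster, "high", "low"),
                levels = c("high", "low"))
  names(lab) <- rownames(m)
  lab
}

#' Kaplan-Meier comparison of two patient groups
#'
#' Standard two-group log-rank test plus a hazard ratio (high versus low)
#' with 95% confidence interval from a proportional-hazards fit on the group
#' indicator. Kaplan-Meier curves are retained for plotting.
#'
#' @param labels named factor from [kmeans_stratify()] (levels high/low).
#' @param clinical a [clinical_table()] covering the labeled samples.
#' @return An `mr_stratification`: list with `logrank_chisq`, `logrank_p`,
#'   `hr`, `hr_ci` (length-2), `n` (per group), `n_events`, `fit` (survfit),
#'   `labels`.
#' @export
km_logrank <- function(labels, clinical) {
  clinical <- clinical_table(clinical)
  cl <- clinical[match(names(labels), clinical$sample), , drop = FALSE]
  if (anyNA(cl$sample)) stop("labels contain samples absent from the clinical table",
                             call. = FALSE)
  grp <- factor(labels, levels = c("low", "high"))
  if (any(table(grp) == 0)) stop("both groups must be nonempty", call. = FALSE)
  if (sum(cl$event) == 0) stop("no events in the clinical table", call. = FALSE)
  srv <- survival::Surv(cl$time, cl$event)
  sd <- survival::survdiff(srv ~ grp)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  cox <- suppressWarnings(survival::coxph(srv ~ grp))
  hr <- unname(exp(stats::coef(cox)))
  ci <- unname(exp(stats::confint(cox)))
  fit <- survival::survfit(srv ~ grp)
  structure(list(logrank_chisq = chisq, logrank_p = p,
                 hr = hr, hr_ci = c(ci[1], ci[2]),
                 n = table(grp), n_events = sum(cl$event),
                 fit = fit, labels = labels),
            class = "mr_stratification")
}

#' @export
print.mr_stratification <- function(x, ...) {
  cat(sprintf("Two-group survival stratification (%d high / %d low, %d events)\n",
              x$n[["high"]], x$n[["low"]], x$n_events))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g\n",
              x$logrank_chisq, x$logrank_p))
  cat(sprintf("  hazard ratio (high vs low) = %.3f [%.3f, %.3f]\n",
              x$hr, x$hr_ci[1], x$hr_ci[2]))
  invisible(x)
}

#' @export
plot.mr_stratification <- function(x, col = c("blue", "red"), ...) {
  graphics::plot(x$fit, col = col, xlab = "Time", ylab = "Survival probability",
                 ...)
  graphics::legend("bottomleft", legend = c("low activity", "high activity"),
                   col = col, lty = 1, bty = "n")
  invisible(x)
}

#' Empirical random-MR-set null for a survival stratification
#'
#' Asks how specific the observed stratification is to the candidate MR set:
#' each iteration draws an equally sized random MR set from the pool, repeats
#' k-means stratification and the log-rank test, and records the null p-value.
#' The empirical p is `(1 + #\{null p <= observed p\}) / (n_iter + 1)`
#' ("reached or outperformed" is inclusive). Degenerate iterations (e.g. a
#' single cluster) are conservatively scored p = 1 and counted.
#'
#' When `candidate_set` is supplied the pool defaults to every *other* MR in
#' the activity matrix: random sets overlapping the candidates would re-test
#' the candidates' own signal rather than the specificity of the set, so the
#' exclusion makes the null a genuine "could other MRs do as well" question.
#' Set `pool = "all"` to draw from the full matrix instead.
#'
#' @param activity activity matrix over the full candidate pool.
#' @param clinical a [clinical_table()].
#' @param observed_p the log-rank p of the candidate set ([km_logrank()]).
#' @param target_set_size random-set size (default 8).
#' @param n_iter iterations (default 1000).
#' @param seed integer seed.
#' @param n_restarts k-means restarts per iteration (default 100).
#' @param candidate_set regulator ids of the observed candidate set.
#' @param pool `"exclude_candidates"` (default) or `"all"`.
#' @return An `empirical_null`: list with `empirical_p`, `observed_p`,
#'   `null_p` (length `n_iter`), `n_degenerate`, `pool_size`.
#' @export
random_set_null <- function(activity, clinical, observed_p, target_set_size = 8,
                            n_iter = 1000, seed = 1, n_restarts = 100,
                            candidate_set = NULL,
                            pool = c("exclude_candidates", "all")) {
  pool_choice <- match.arg(pool)
  clinical <- clinical_table(clinical)
  pool <- rownames(activity)
  if (pool_choice == "exclude_candidates" && !is.null(candidate_set)) {
    pool <- setdiff(pool, candidate_set)
  }
  mr_log(sprintf("random_set_null: pool of %d regulators (%s)", length(pool),
                 pool_choice))
  if (length(pool) <= target_set_size) {
    stop("MR pool must be larger than the target set size", call. = FALSE)
  }
  picks <- with_seed(seed, "random_set_null",
                     lapply(seq_len(n_iter),
                            function(i) sample(pool, target_set_size)))
  n_degenerate <- 0L
  null_p <- vapply(seq_len(n_iter), function(i) {
    tryCatch({
      lab <- kmeans_stratify(activity[picks[[i]], , drop = FALSE],
                             n_restarts = n_restarts,
                             seed = derive_seed(seed, paste0("null_iter_", i)))
      km_logrank(lab, clinical)$logrank_p
    }, error = function(e) {
      n_degenerate <<- n_degenerate + 1L
      1
    })
  }, numeric(1))
  if (n_degenerate > 0) {
    mr_log(sprintf("random_set_null: %d degenerate iteration(s) scored p = 1",
                   n_degenerate))
  }
  emp <- (1 + sum(null_p <= observed_p)) / (n_iter + 1)
  structure(list(empirical_p = emp, observed_p = observed_p, null_p = null_p,
                 n_degenerate = n_degenerate, pool_size = length(pool),
                 target_set_size = target_set_size),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("Random-MR-set null: %d sets of %d from a pool of %d\n",
              length(x$null_p), x$target_set_size, x$pool_size))
  cat(sprintf("  observed log-rank p = %.4g, empirical p = %.4g\n",
              x$observed_p, x$empirical_p))
  if (x$n_degenerate > 0) {
    cat(sprintf("  %d degenerate iteration(s) scored p = 1\n", x$n_degenerate))
  }
  invisible(x)
}
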