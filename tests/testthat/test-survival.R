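test_that("km_logrank equals the observed-minus-expected oracle on toy tables", {
  # frozen hand case: A events at 1, 2; B events at 3, 4 (no censoring)
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36 -> chisq = 49/17
  cl <- clinical_table(data.frame(sample = paste0("s", 1:4),
                                  time = c(1, 2, 3, 4), event = 1))
  lab <- factor(c("high", "high", "low", "low"), levels = c("high", "low"))
  names(lab) <- cl$sample
  res <- km_logrank(lab, cl)
  expect_equal(res$logrank_chisq, 49 / 17, tolerance = 1e-10)
  ora <- oracle_logrank(cl$time, cl$event, lab)
  expect_equal(res$logrank_chisq, ora$chisq, tolerance = 1e-10)
  expect_equal(res$logrank_p, ora$p, tolerance = 1e-10)
})

test_that("km_logrank equals the oracle across random toys with censoring", {
  set.seed(20)
  for (rep in 1:30) {
    n <- sample(4:6, 1)
    cl <- clinical_table(data.frame(sample = paste0("s", 1:n),
                                    time = sample(1:8, n, replace = TRUE),
                                    event = rbinom(n, 1, 0.7)))
    if (sum(cl$event) == 0) next
    g <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    lab <- factor(g, levels = c("high", "low")); names(lab) <- cl$sample
    ora <- oracle_logrank(cl$time, cl$event, lab)
    if (!is.finite(ora$chisq)) next          # no variance (e.g. single subject at risk)
    res <- suppressWarnings(km_logrank(lab, cl))
    expect_equal(res$logrank_chisq, ora$chisq, tolerance = 1e-8)
  }
})

test_that("identical groups give zero log-rank statistic and HR 1 within CI", {
  cl <- clinical_table(data.frame(sample = paste0("s", 1:8),
                                  time = rep(c(2, 4, 6, 8), 2),
                                  event = rep(c(1, 1, 0, 1), 2)))
  lab <- factor(rep(c("high", "low"), each = 4), levels = c("high", "low"))
  names(lab) <- c(paste0("s", 1:4), paste0("s", 5:8))
  res <- suppressWarnings(km_logrank(lab, cl))
  expect_equal(res$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(res$logrank_p, 1, tolerance = 1e-10)
  expect_true(res$hr_ci[1] <= 1 && 1 <= res$hr_ci[2])
})

test_that("a group censored before any event still contributes risk sets only", {
  cl <- clinical_table(data.frame(sample = paste0("s", 1:6),
                                  time = c(0.5, 0.5, 0.5, 2, 3, 4),
                                  event = c(0, 0, 0, 1, 1, 1)))
  lab <- factor(c("high", "high", "high", "low", "low", "low"),
                levels = c("high", "low"))
  names(lab) <- cl$sample
  res <- suppressWarnings(km_logrank(lab, cl))
  # every event time has only one group at risk: O-E and its variance are
  # both zero, and the statistic degenerates to 0 (no evidence either way)
  expect_equal(res$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(res$logrank_p, 1)
})

test_that("kmeans stratification recovers separated blobs and orients labels", {
  set.seed(31)
  act <- cbind(matrix(rnorm(3 * 10, mean = 3, sd = 0.3), 3, 10),
               matrix(rnorm(3 * 10, mean = -3, sd = 0.3), 3, 10))
  dimnames(act) <- list(paste0("R", 1:3), paste0("p", 1:20))
  lab <- kmeans_stratify(act, n_restarts = 10, seed = 1)
  expect_equal(unname(lab[1:10]), factor(rep("high", 10), levels = c("high", "low")))
  expect_equal(unname(lab[11:20]), factor(rep("low", 10), levels = c("high", "low")))
  # negating the matrix swaps the labels
  lab2 <- kmeans_stratify(-act, n_restarts = 10, seed = 1)
  expect_equal(as.character(lab2), ifelse(lab == "high", "low", "high"))
  expect_identical(lab, kmeans_stratify(act, n_restarts = 10, seed = 1))
  flat <- act; flat[] <- 1
  expect_error(kmeans_stratify(flat), "degenerate")
})

test_that("cox screen recovers a planted hazard and flags degenerate rows", {
  cfg <- synthetic_config(n_genes = 300, n_regulators = 10, n_planted = 2,
                          n_patients = 120, seed = 12)
  net <- generate_interactome(cfg)
  sv <- generate_survival_cohort(cfg, net)
  # true latent activity as covariate: strong positive log-HR
  act <- rbind(truth = sv$truth$latent_activity,
               noise = rnorm(120), flatrow = rep(1, 120))
  colnames(act) <- sv$clinical$sample
  scr <- cox_screen(act, sv$clinical)
  tr <- scr[scr$regulator == "truth", ]
  expect_gt(tr$loghr, 0)
  expect_lt(tr$p, 1e-6)
  # per-unit log hazard ratio estimates the generative beta
  expect_equal(tr$loghr, 0.8, tolerance = 0.25)
  expect_false(scr$converged[scr$regulator == "flatrow"])
  expect_gt(scr$p[scr$regulator == "noise"], 0.001)
  cl0 <- sv$clinical; cl0$event <- 0
  expect_error(cox_screen(act, cl0), "zero events")
})

test_that("random-set null respects the add-one rule and pool exclusion", {
  set.seed(17)
  act <- matrix(rnorm(20 * 40), 20, 40,
                dimnames = list(paste0("R", 1:20), paste0("p", 1:40)))
  cl <- clinical_table(data.frame(sample = colnames(act),
                                  time = rexp(40, 0.1) + 0.1,
                                  event = rbinom(40, 1, 0.8)))
  null <- quiet(random_set_null(act, cl, observed_p = 0, target_set_size = 4,
                                n_iter = 30, seed = 2, n_restarts = 5))
  expect_equal(null$empirical_p, 1 / 31)     # observed beats every draw
  expect_equal(length(null$null_p), 30)
  null2 <- quiet(random_set_null(act, cl, observed_p = 1, target_set_size = 4,
                                 n_iter = 30, seed = 2, n_restarts = 5))
  expect_equal(null2$empirical_p, 1)         # observed outperformed by all
  # observed at the null median lands near 0.5
  null3 <- quiet(random_set_null(act, cl, observed_p = median(null$null_p),
                                 target_set_size = 4, n_iter = 30, seed = 2,
                                 n_restarts = 5))
  expect_gt(null3$empirical_p, 0.3)
  expect_lt(null3$empirical_p, 0.7)
  # candidate exclusion shrinks the pool
  excl <- quiet(random_set_null(act, cl, observed_p = 0, target_set_size = 4,
                                n_iter = 5, seed = 2, n_restarts = 5,
                                candidate_set = paste0("R", 1:5)))
  expect_equal(excl$pool_size, 15)
  expect_error(quiet(random_set_null(act[1:4, ], cl, observed_p = 0.5,
                                     target_set_size = 4, n_iter = 5, seed = 1)),
               "pool must be larger")
})
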