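test_that("marina sign semantics: coherent regulons are active, mode swap flips", {
  # symmetric signature; regulon's positive targets at the top, negative at
  # the bottom -> mode adjustment stacks all targets on top -> active
  ids <- sprintf("g%02d", 1:20)
  scores <- setNames(c(10, 9, 8, 7, 3, 2.5, 2, 1.5, 1, 0.5,
                       -0.5, -1, -1.5, -2, -2.5, -3, -7, -8, -9, -10), ids)
  edges <- data.frame(regulator = "R",
                      target = c(ids[1:3], ids[18:20]),
                      mode = c(1, 1, 1, -1, -1, -1), weight = 1)
  net <- interactome(edges, universe = c(ids, "R"), min_regulon_size = 2)
  sig <- gene_signature(scores)
  act <- marina_activity(net, sig, n_perm = 500, seed = 9, w = 0)
  expect_gt(act$nes, 0)
  expect_equal(act$n_pos, 3)
  expect_equal(act$n_neg, 3)
  # swap every mode: same (n_pos, n_neg) split and a mirror-symmetric
  # signature, so the observed ES negates exactly and NES flips sign
  edges2 <- edges; edges2$mode <- -edges2$mode
  net2 <- interactome(edges2, universe = c(ids, "R"), min_regulon_size = 2)
  act2 <- marina_activity(net2, sig, n_perm = 500, seed = 9, w = 0)
  expect_equal(act2$es, -act$es, tolerance = 1e-12)
  expect_lt(act2$nes, 0)
  expect_equal(act2$nes, -act$nes, tolerance = 0.2)
})

test_that("marina NES and p equal exhaustive enumeration on a 10-gene universe", {
  set.seed(7)
  ids <- sprintf("G%02d", 1:10)
  scores <- setNames(rnorm(10), ids)
  sig <- gene_signature(scores)
  ranked <- sig$gene
  for (case in list(list(t = ranked[c(1, 2, 9)], m = c(1, 1, -1)),
                    list(t = ranked[c(3, 5, 8, 10)], m = c(1, -1, 1, -1)),
                    list(t = ranked[c(2, 4)], m = c(1, 1)))) {
    edges <- data.frame(regulator = "R1", target = case$t, mode = case$m,
                        weight = 1)
    net <- interactome(edges, universe = c(ids, "R1"), min_regulon_size = 1)
    for (w in c(0, 1)) {
      act <- marina_activity(net, sig, n_perm = "exhaustive", seed = 1, w = w)
      ora <- oracle_marina_exhaustive(scores, ids, case$t,
                                      case$t[case$m < 0], w)
      expect_equal(act$es, ora$es, tolerance = 1e-12)
      expect_equal(act$nes, ora$nes, tolerance = 1e-12)
      expect_equal(act$p, ora$p, tolerance = 1e-12)
    }
  }
})

test_that("marina is deterministic and order-independent via the cached null", {
  cfg <- synthetic_config(n_genes = 300, n_regulators = 10,
                          regulon_size_range = c(15, 25), seed = 3)
  net <- generate_interactome(cfg)
  coh <- generate_two_group_cohort(cfg, net)
  sig <- welch_t_signature(coh$expr, coh$labels, "group1", "group2")
  a1 <- marina_activity(net, sig, n_perm = 200, seed = 5)
  a2 <- marina_activity(net, sig, n_perm = 200, seed = 5)
  expect_identical(a1$nes, a2$nes)
  # scoring a sub-interactome gives the same rows (null keyed by size/seed)
  sub_edges <- interactome_edges(net)
  sub_edges <- sub_edges[sub_edges$regulator %in% names(net$regulons)[3], ]
  sub <- interactome(sub_edges, universe = net$universe, min_regulon_size = 15)
  a3 <- marina_activity(sub, sig, n_perm = 200, seed = 5)
  reg <- names(net$regulons)[3]
  expect_equal(a3$nes[a3$regulator == reg], a1$nes[a1$regulator == reg])
})

test_that("per-sample activity matrix tracks planted activity and is reproducible", {
  cfg <- synthetic_config(n_genes = 400, n_regulators = 12, n_planted = 3,
                          n_patients = 30, seed = 10)
  net <- generate_interactome(cfg)
  sv <- generate_survival_cohort(cfg, net)
  m1 <- quiet(sample_activity_matrix(net, sv$expr, n_perm = 50, seed = 2))
  m2 <- quiet(sample_activity_matrix(net, sv$expr, n_perm = 50, seed = 2))
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(12L, 30L))
  expect_true(all(is.finite(m1)))
  # planted regulators' inferred activity correlates with the latent truth
  a <- sv$truth$latent_activity
  for (r in sv$truth$planted_regulators) {
    expect_gt(cor(m1[r, ], a), 0.5)
  }
  # non-planted regulators do not systematically track it
  others <- setdiff(rownames(m1), sv$truth$planted_regulators)
  rho <- vapply(others, function(r) cor(m1[r, ], a), numeric(1))
  expect_lt(median(abs(rho)), 0.5)
})

test_that("stouffer integration matches the closed form and flags discordance", {
  mk <- function(reg, nes) data.frame(regulator = reg, nes = nes,
                                      p = 0.01, degenerate = FALSE)
  tab <- stouffer_integrate(mk(c("A", "B", "C"), c(1.96, 3, 0)),
                            mk(c("A", "B", "C"), c(1.96, -3, 0)))
  a <- tab[tab$regulator == "A", ]
  expect_equal(a$z_combined, 2 * 1.96 / sqrt(2), tolerance = 1e-12)
  expect_equal(a$p_combined, 2 * pnorm(-2 * 1.96 / sqrt(2)), tolerance = 1e-12)
  expect_equal(round(a$z_combined, 4), 2.7719)
  expect_equal(round(a$p_combined, 5), 0.00557)
  expect_true(a$concordant)
  b <- tab[tab$regulator == "B", ]
  expect_equal(b$z_combined, 0)
  expect_equal(b$p_combined, 1)
  expect_false(b$concordant)
  expect_error(stouffer_integrate(mk("A", 1), mk("Z", 1)), "shared")
})

test_that("stouffer translates mouse regulators and keeps the max-|NES| ortholog", {
  mouse <- data.frame(regulator = c("m1", "m2"), nes = c(2, -4), p = 0.01,
                      degenerate = FALSE)
  human <- data.frame(regulator = "h1", nes = 3, p = 0.01, degenerate = FALSE)
  map <- data.frame(source_gene = c("m1", "m2"), target_gene = c("h1", "h1"))
  tab <- stouffer_integrate(mouse, human, map)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$nes_mouse, -4)   # larger magnitude wins the collision
  expect_false(tab$concordant)
})

test_that("conserved-MR filtering applies threshold, concordance and direction", {
  tab <- stouffer_integrate(
    data.frame(regulator = letters[1:6], nes = c(5, 4.5, 4, -4.5, 3.8, 0.5),
               p = 0.001, degenerate = FALSE),
    data.frame(regulator = letters[1:6], nes = c(5, 4.8, -4, -4.6, 3.9, 0.4),
               p = 0.001, degenerate = FALSE))
  kept <- quiet(filter_conserved(tab))
  # a, b, e pass p < 1e-4 concordant activated; c discordant; d repressed
  expect_setequal(kept$regulator, c("a", "b", "e"))
  rep_side <- quiet(filter_conserved(tab, direction = "repressed"))
  expect_setequal(rep_side$regulator, "d")
  loose <- quiet(filter_conserved(tab, require_concordance = FALSE,
                                  direction = "both"))
  expect_setequal(loose$regulator, c("a", "b", "d", "e"))
  ann <- quiet(annotation_filter(kept, c("a", "e", "zzz")))
  expect_setequal(ann$regulator, c("a", "e"))
  expect_equal(nrow(quiet(annotation_filter(kept, "none"))), 0)
})
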