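#' MARINa-style master regulator activity on a signature
#'
#' Scores each regulon's differential activity in a ranked signature. For one
#' regulon the signature is first mode-adjusted: scores of the regulon's
#' negative (repressed) targets are negated and the signature re-ranked, so
#' that a regulator whose positive targets are overexpressed and/or negative
#' targets underexpressed pushes all its targets toward the top. The combined
#' target set is then scored with the weighted running-sum enrichment, and
#' significance comes from gene permutations that preserve the regulon's
#' (n_pos, n_neg) split: each null draw picks random genes, negates a random
#' n_neg of them against the unadjusted signature, and re-ranks. NES > 0 means
#' the regulator is active in the phenotype contrast, NES < 0 repressed.
#'
#' Null distributions depend only on (regulon size, n_neg) and are cached per
#' signature with seeds derived from those two numbers, so results do not
#' depend on the order regulons are scored in.
#'
#' @param x an `interactome` (restricted internally to the signature).
#' @param sig a [gene_signature()].
#' @param n_perm gene permutations per null (default 1000); `"exhaustive"`
#'   enumerates every possible placement (tiny universes only).
#' @param seed integer seed.
#' @param w weight exponent on |score| (default 0, the classic unweighted
#'   Kolmogorov-Smirnov form: regulon membership, not target score magnitude,
#'   carries the evidence, and the unweighted null is tight enough for the
#'   downstream conserved-MR filter).
#' @return An `mr_activity_table`: data.frame with one row per regulon
#'   (`regulator`, `nes`, `p`, `es`, `n_pos`, `n_neg`, `degenerate`) plus a
#'   `leading_edges` attribute (named list of leading-target sets).
#' @export
marina_activity <- function(x, sig, n_perm = 1000, seed = 1, w = 0) {
  stopifnot(inherits(x, "interactome"), inherits(sig, "gene_signature"))
  x <- restrict_to_signature(x, sig)
  exhaustive <- identical(n_perm, "exhaustive")
  scores <- signature_scores(sig)
  genes <- sig$gene
  v_sorted <- sig$score
  n <- length(genes)
  null_cache <- new.env(parent = emptyenv())
  res <- vector("list", length(x$regulons))
  led <- vector("list", length(x$regulons))
  for (j in seq_along(x$regulons)) {
    reg <- names(x$regulons)[j]
    r <- x$regulons[[j]]
    neg_t <- r$target[r$mode < 0]
    n_pos <- sum(r$mode > 0)
    n_neg <- length(neg_t)
    k <- n_pos + n_neg
    # observed: mode-adjusted signature, re-ranked, combined-set enrichment
    adj <- scores
    adj[neg_t] <- -adj[neg_t]
    adj_sig <- gene_signature(adj)
    obs <- enrichment_score(adj_sig, r$target, w)
    key <- sprintf("k%d_n%d", k, n_neg)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- marina_null(sig, k, n_neg, n_perm,
                                       derive_seed(seed, key), w,
                                       exhaustive = exhaustive)
    }
    null_es <- null_cache[[key]]
    mu <- mean(null_es); sd0 <- stats::sd(null_es)
    degenerate <- !is.finite(sd0) || sd0 == 0
    nes <- if (degenerate) NA_real_ else (obs$es - mu) / sd0
    p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (length(null_es) + 1)
    idx <- seq_len(n)
    keep <- if (obs$es >= 0) obs$hits & idx <= obs$extremum_index
            else obs$hits & idx >= obs$extremum_index
    led[[j]] <- adj_sig$gene[keep]
    res[[j]] <- data.frame(regulator = reg, nes = nes, p = p, es = obs$es,
                           n_pos = n_pos, n_neg = n_neg,
                           degenerate = degenerate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  names(led) <- out$regulator
  out <- out[order(-abs(ifelse(is.na(out$nes), 0, out$nes)),
                   out$regulator, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "leading_edges") <- led
  attr(out, "n_perm") <- if (exhaustive) NA_integer_ else n_perm
  class(out) <- c("mr_activity_table", "data.frame")
  out
}

# Null ES draws for the split-preserving MARINa permutation. The stochastic
# path uses the vectorized O(k log k)-per-draw engine; the exhaustive path
# (tiny universes) evaluates every placement by explicit re-ranking and a
# full running sum, so ties resolve exactly as in the observed statistic.
marina_null <- function(sig, k, n_neg, n_perm, seed, w, exhaustive = FALSE) {
  v_sorted <- sig$score
  ids <- sig$gene
  n <- length(v_sorted)
  if (exhaustive) {
    n_states <- choose(n, k) * max(1, choose(k, n_neg))
    if (n_states > 2e5) {
      stop(sprintf("exhaustive null has %.3g states; only feasible on tiny universes",
                   n_states), call. = FALSE)
    }
    pos_sets <- utils::combn(n, k)
    neg_choices <- if (n_neg > 0) utils::combn(k, n_neg) else matrix(0L, 0, 1)
    out <- numeric(ncol(pos_sets) * ncol(neg_choices))
    col <- 0L
    for (a in seq_len(ncol(pos_sets))) {
      set <- pos_sets[, a]
      for (b in seq_len(ncol(neg_choices))) {
        col <- col + 1L
        neg_idx <- set[neg_choices[, b]]
        adj <- v_sorted
        adj[neg_idx] <- -adj[neg_idx]
        o <- rank_order(adj, ids)
        hits <- o %in% set
        s <- abs(adj[o])^w
        inc <- numeric(n)
        sh <- sum(s[hits])
        inc[hits] <- if (sh == 0) 1 / k else s[hits] / sh
        inc[!hits] <- -1 / (n - k)
        run <- cumsum(inc)
        out[col] <- run[which.max(abs(run))]
      }
    }
    return(out)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  idx <- sample_positions(n, k, n_perm)
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv())
  null_es_engine(v_sorted, idx, n_neg = n_neg, w = w)
}

#' @export
print.mr_activity_table <- function(x, ...) {
  cat(sprintf("MR activity: %d regulons (%s permutations)\n", nrow(x),
              format(attr(x, "n_perm") %||% NA)))
  cat(sprintf("  active (NES > 0): %d, repressed (NES < 0): %d, degenerate: %d\n",
              sum(x$nes > 0, na.rm = TRUE), sum(x$nes < 0, na.rm = TRUE),
              sum(x$degenerate)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

#' Per-sample MR activity matrix
#'
#' Applies [marina_activity()] to each sample's cohort z-score signature
#' (see [single_sample_signatures()]), yielding a regulators x samples matrix
#' of NES values: each entry is that sample's inferred activity of that
#' regulator, positive for active, negative for repressed.
#'
#' @param x an `interactome`.
#' @param expr expression matrix (genes x samples, >= 3 samples).
#' @param n_perm permutations per sample signature (default 100; per-sample
#'   signatures are scored many times, so a lighter null is the default).
#' @param seed integer seed.
#' @param w weight exponent (default 0, as in [marina_activity()]).
#' @return Numeric matrix (regulators x samples) with class `mr_activity_matrix`.
#' @export
sample_activity_matrix <- function(x, expr, n_perm = 100, seed = 1, w = 0) {
  ss <- single_sample_signatures(expr)
  x <- restrict_to_signature(x, ss$genes)
  cols <- lapply(seq_along(ss$samples), function(j) {
    sig <- as_signature(ss, j)
    act <- marina_activity(x, sig, n_perm = n_perm,
                           seed = derive_seed(seed, paste0("sample_", ss$samples[j])),
                           w = w)
    stats::setNames(act$nes, act$regulator)
  })
  regs <- sort(names(x$regulons), method = "radix")
  m <- vapply(cols, function(cc) cc[regs], numeric(length(regs)))
  dimnames(m) <- list(regs, ss$samples)
  class(m) <- c("mr_activity_matrix", class(m))
  m
}
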