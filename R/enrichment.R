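#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the signature's descending ranking and accumulates a running sum:
#' each query gene ("hit") adds `|score|^w` normalized by the sum over all
#' hits, each non-query gene ("miss") subtracts `1/(N - |S|)`. The enrichment
#' score (ES) is the running-sum value of largest absolute magnitude; on ties
#' the first occurrence in rank order wins. `w = 1` is the standard weighted
#' GSEA statistic; `w = 0` reduces to the classic Kolmogorov-Smirnov form.
#'
#' @param sig a [gene_signature()].
#' @param query character vector of gene ids; must overlap the signature but
#'   not contain all of it.
#' @param w weight exponent on |score| for hit increments (default 1).
#' @return list with `es`, `running_sum` (per-rank values), `extremum_index`
#'   (1-based rank of the extremum) and `hits` (logical per rank).
#' @export
enrichment_score <- function(sig, query, w = 1) {
  stopifnot(inherits(sig, "gene_signature"))
  hits <- sig$gene %in% query
  n <- nrow(sig)
  k <- sum(hits)
  if (k == 0L) stop("query is disjoint from the signature", call. = FALSE)
  if (k == n) stop("query covers the whole signature", call. = FALSE)
  s <- abs(sig$score)^w
  denom_hit <- sum(s[hits])
  inc <- numeric(n)
  if (denom_hit == 0) {
    # all hit scores exactly zero under w > 0: fall back to equal hit weights
    inc[hits] <- 1 / k
  } else {
    inc[hits] <- s[hits] / denom_hit
  }
  inc[!hits] <- -1 / (n - k)
  running <- cumsum(inc)
  i <- which.max(abs(running))  # first occurrence on ties
  list(es = running[i], running_sum = running, extremum_index = i, hits = hits)
}

#' Leading-edge genes of an enrichment
#'
#' The query genes that drive the enrichment: for positive ES, query genes at
#' ranks up to the running-sum extremum; for negative ES, query genes at or
#' after it.
#'
#' @inheritParams enrichment_score
#' @return Character vector of leading-edge gene ids.
#' @export
leading_edge <- function(sig, query, w = 1) {
  es <- enrichment_score(sig, query, w)
  idx <- seq_len(nrow(sig))
  keep <- if (es$es >= 0) es$hits & idx <= es$extremum_index
          else es$hits & idx >= es$extremum_index
  sig$gene[keep]
}

# Vectorized null-ES engine.
#
# v: signature scores sorted descending (the base ranking).
# idx: k x P matrix of sampled positions into v (each column one permutation).
# n_neg: number of leading rows of idx whose scores are negated before
#   re-ranking (the MARINa split-preserving null); 0 for plain gene permutation.
# Returns the ES per permutation without materializing any re-ranked list:
# between hits the running sum decreases linearly, so its extrema lie at hit
# positions (after the jump) or just before a hit, and both are computable
# from the hit ranks alone in O(k log k) per permutation.
null_es_engine <- function(v, idx, n_neg, w) {
  n <- length(v)
  k <- nrow(idx)
  P <- ncol(idx)
  d <- n - k
  V <- matrix(v[idx], k, P)
  A <- V
  if (n_neg > 0) A[seq_len(n_neg), ] <- -V[seq_len(n_neg), , drop = FALSE]
  # sort adjusted values descending within each column
  o <- order(rep(seq_len(P), each = k), -as.vector(A), method = "radix")
  As <- matrix(as.vector(A)[o], k, P)
  # rank of each sorted hit in the re-ranked list: genes not in the query keep
  # their relative order, so position = (# non-query genes above) + hit index
  vu <- sort(v)                       # ascending, for fast total counts
  gt_all <- n - matrix(findInterval(as.vector(As), vu), k, P)  # # v > As
  gt_samp <- matrix(0L, k, P)
  for (i in seq_len(k)) {
    gt_samp[i, ] <- .colSums(V > rep(As[i, ], each = k), k, P)
  }
  h <- (gt_all - gt_samp) + row(As)
  s <- abs(As)^w
  W <- .colSums(s, k, P)
  W[W == 0] <- NA_real_  # degenerate all-zero-score draws
  cs <- s
  if (k > 1) for (i in 2:k) cs[i, ] <- cs[i - 1, ] + s[i, ]
  cs <- sweep(cs, 2, W, "/")
  val_at <- cs - (h - row(As)) / d
  cs0 <- rbind(0, cs[-k, , drop = FALSE])
  val_before <- cs0 - (h - 1 - (row(As) - 1)) / d
  stacked <- rbind(val_before, val_at)
  stacked[is.na(stacked)] <- 0
  pick <- max.col(t(abs(stacked)), ties.method = "first")
  stacked[cbind(pick, seq_len(P))]
}

# draw a k x P matrix of distinct positions per column
sample_positions <- function(n, k, P) {
  vapply(seq_len(P), function(p) sample.int(n, k), integer(k))
}

#' Gene-permutation normalized enrichment score
#'
#' Estimates a null ES distribution from `n_perm` random query sets of the
#' same size drawn uniformly without replacement from the signature's genes.
#' NES is the permutation z-score `(ES_obs - mean_null) / sd_null`; the
#' two-sided p-value uses the add-one rule
#' `p = (1 + #\{|ES_null| >= |ES_obs|\}) / (n_perm + 1)`, so p is never zero
#' and is floored at `1/(n_perm + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of gene permutations (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param keep_running keep the observed running sum (for plots).
#' @return An `mr_enrichment` object: `es`, `nes`, `p`, `leading_edge`,
#'   `n_perm`, `n_hits`, and optionally `running_sum`.
#' @export
permutation_nes <- function(sig, query, n_perm = 1000, seed = 1, w = 1,
                            keep_running = FALSE) {
  obs <- enrichment_score(sig, query, w)
  n <- nrow(sig)
  k <- sum(obs$hits)
  v <- sig$score  # already sorted descending
  idx <- with_seed(seed, "permutation_nes", sample_positions(n, k, n_perm))
  null_es <- null_es_engine(v, idx, n_neg = 0L, w = w)
  sd_null <- stats::sd(null_es)
  if (!is.finite(sd_null) || sd_null == 0) {
    stop("degenerate permutation null (zero variance)", call. = FALSE)
  }
  nes <- (obs$es - mean(null_es)) / sd_null
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  le_idx <- seq_len(n)
  keep <- if (obs$es >= 0) obs$hits & le_idx <= obs$extremum_index
          else obs$hits & le_idx >= obs$extremum_index
  structure(list(es = obs$es, nes = nes, p = p,
                 leading_edge = sig$gene[keep],
                 n_perm = n_perm, n_hits = k,
                 running_sum = if (keep_running) obs$running_sum),
            class = "mr_enrichment")
}

#' @export
print.mr_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment: ES = %.4f, NES = %.3f, p = %.4g (%d hits, %d permutations)\n",
              x$es, x$nes, x$p, x$n_hits, x$n_perm))
  cat(sprintf("Leading edge: %d genes\n", length(x$leading_edge)))
  invisible(x)
}

#' Two-tail signature-versus-signature GSEA
#'
#' Tests whether a query signature recapitulates a reference signature using
#' its two tails separately: the `top_n` highest-scoring query genes as the
#' positive (overexpressed) query set and the `top_n` lowest-scoring as the
#' negative (underexpressed) set, each scored by [permutation_nes()] against
#' the reference. Both signatures are first restricted to their shared gene
#' universe; `top_n` shrinks with a warning if the universe is small.
#'
#' @param reference,query [gene_signature()] objects.
#' @param top_n query-tail size (default 200).
#' @inheritParams permutation_nes
#' @return list with elements `positive` and `negative` (`mr_enrichment`),
#'   plus `top_n` and `n_shared`.
#' @export
two_tail_gsea <- function(reference, query, top_n = 200, n_perm = 1000,
                          seed = 1, w = 1) {
  shared <- intersect(reference$gene, query$gene)
  if (length(shared) < 10L) {
    stop("fewer than 10 genes shared between signatures", call. = FALSE)
  }
  if (length(shared) < 2 * top_n) {
    top_n <- floor(length(shared) / 2)
    warning(sprintf("shared universe supports only top_n = %d", top_n),
            call. = FALSE)
  }
  ref <- gene_signature(signature_scores(reference)[shared],
                        metadata = attr(reference, "metadata"))
  qr <- gene_signature(signature_scores(query)[shared],
                       metadata = attr(query, "metadata"))
  pos_set <- utils::head(qr$gene, top_n)
  neg_set <- utils::tail(qr$gene, top_n)
  list(positive = permutation_nes(ref, pos_set, n_perm, derive_seed(seed, "pos"),
                                  w, keep_running = TRUE),
       negative = permutation_nes(ref, neg_set, n_perm, derive_seed(seed, "neg"),
                                  w, keep_running = TRUE),
       top_n = top_n, n_shared = length(shared))
}

#' Leading-edge overlap test
#'
#' Quantifies agreement between two leading edges as `|A intersect B|` over
#' the smaller set (configurable to the union) and tests association with a
#' chi-square on the 2x2 membership table over the universe (no continuity
#' correction).
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @param denominator `"min"` (default) or `"union"`.
#' @return list with `overlap` (fraction), `statistic`, `p.value`, `table`.
#' @export
leading_edge_overlap_test <- function(set_a, set_b, universe,
                                      denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!length(set_a) || !length(set_b)) stop("both sets must be nonempty", call. = FALSE)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  a <- universe %in% set_a
  b <- universe %in% set_b
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
  ov <- sum(a & b) / switch(denominator,
                            min = min(sum(a), sum(b)),
                            union = sum(a | b))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(overlap = ov, statistic = unname(ct$statistic),
       p.value = ct$p.value, table = tab)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then gene ids. Duplicate
#' set names and empty sets are rejected.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0L)) stop("GMT contains an empty gene set", call. = FALSE)
  stats::setNames(sets, nm)
}

#' Pathway enrichment over a gene-set collection
#'
#' Runs [permutation_nes()] of every collection set against the signature and
#' flags sets by enrichment sign and a p-value threshold. Sets with fewer than
#' `min_overlap` genes in the signature are skipped with a warning.
#'
#' @inheritParams permutation_nes
#' @param gmt named list of gene sets (see [read_gmt()]).
#' @param p_threshold significance flag threshold (default 0.05).
#' @param min_overlap minimum set-signature overlap (default 5).
#' @return data.frame, one row per scored set: `set`, `size`, `n_overlap`,
#'   `es`, `nes`, `p`, `direction`, `significant`.
#' @export
pathway_enrichment <- function(sig, gmt, n_perm = 1000, seed = 1,
                               p_threshold = 0.05, min_overlap = 5, w = 1) {
  ov <- vapply(gmt, function(s) sum(s %in% sig$gene), integer(1))
  usable <- ov >= min_overlap & ov < nrow(sig)
  if (!any(ov > 0)) stop("no gene set overlaps the signature", call. = FALSE)
  if (any(!usable)) {
    warning(sprintf("skipping %d set(s) with < %d signature genes",
                    sum(!usable), min_overlap), call. = FALSE)
  }
  rows <- lapply(names(gmt)[usable], function(nm) {
    r <- permutation_nes(sig, gmt[[nm]], n_perm, derive_seed(seed, nm), w)
    data.frame(set = nm, size = length(gmt[[nm]]), n_overlap = r$n_hits,
               es = r$es, nes = r$nes, p = r$p,
               direction = if (r$nes >= 0) "positive" else "negative",
               significant = r$p < p_threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, -abs(out$nes)), ]
}
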