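# Independent oracles used across the suite. Each is a transparent,
# brute-force restatement of the statistic it checks, kept free of any
# package internals beyond the public gene_signature container.

# Running-sum enrichment by explicit loop over the ranking.
oracle_enrichment <- function(scores, ids, query, w) {
  o <- order(-scores, ids, method = "radix")
  sc <- scores[o]
  id <- ids[o]
  hits <- id %in% query
  n <- length(sc)
  k <- sum(hits)
  wts <- abs(sc)^w
  denom <- sum(wts[hits])
  inc <- numeric(n)
  for (i in seq_len(n)) {
    inc[i] <- if (hits[i]) {
      if (denom == 0) 1 / k else wts[i] / denom
    } else {
      -1 / (n - k)
    }
  }
  run <- cumsum(inc)
  best <- 1
  for (i in seq_len(n)) if (abs(run[i]) > abs(run[best])) best <- i
  list(es = run[best], index = best, running = run)
}

# MARINa observed/null statistic for one (set, negated-subset) placement:
# negate, re-rank, run the full running sum.
oracle_mode_adjusted_es <- function(scores, ids, query, neg_query, w) {
  adj <- scores
  adj[ids %in% neg_query] <- -adj[ids %in% neg_query]
  oracle_enrichment(adj, ids, query, w)$es
}

# Exhaustive MARINa NES/p: enumerate every placement of a (n_pos, n_neg)
# regulon over the universe.
oracle_marina_exhaustive <- function(scores, ids, target_ids, neg_ids, w) {
  k <- length(target_ids)
  n_neg <- length(neg_ids)
  obs <- oracle_mode_adjusted_es(scores, ids, target_ids, neg_ids, w)
  nulls <- c()
  for (set in utils::combn(length(ids), k, simplify = FALSE)) {
    genes <- ids[set]
    if (n_neg == 0) {
      nulls <- c(nulls, oracle_mode_adjusted_es(scores, ids, genes, character(0), w))
    } else {
      for (neg in utils::combn(k, n_neg, simplify = FALSE)) {
        nulls <- c(nulls, oracle_mode_adjusted_es(scores, ids, genes, genes[neg], w))
      }
    }
  }
  list(es = obs, nes = (obs - mean(nulls)) / sd(nulls),
       p = (1 + sum(abs(nulls) >= abs(obs))) / (length(nulls) + 1))
}

# Two-group log-rank by explicit observed-minus-expected and hypergeometric
# variance at each distinct event time.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# small deterministic fixtures -----------------------------------------------

toy_signature <- function(scores = c(5, 4, 3, 2, 1),
                          ids = paste0("g", seq_along(scores))) {
  gene_signature(setNames(scores, ids))
}

toy_interactome <- function() {
  edges <- expand.grid(regulator = c("R1", "R2"),
                       target = sprintf("t%02d", 1:25),
                       stringsAsFactors = FALSE)
  edges$mode <- rep(c(1, -1), length.out = nrow(edges))
  edges$weight <- 1
  interactome(edges, universe = c(sprintf("t%02d", 1:25), "R1", "R2"),
              min_regulon_size = 20)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
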