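#' Construct a ranked gene signature
#'
#' A gene signature is the universal currency between pipeline stages: a map
#' from gene id to a signed score (a Welch t-statistic or a z-score), held in
#' descending score order with ties broken lexicographically by gene id so the
#' ranking is total and reproducible across platforms.
#'
#' @param score named numeric vector of signed, finite scores; names are gene ids.
#' @param p optional named numeric vector of per-gene two-sided p-values.
#' @param metadata optional list of provenance fields (test name, group sizes).
#' @return A `gene_signature`: a data.frame with columns `gene`, `score` and
#'   optionally `p`, ordered by decreasing score.
#' @export
gene_signature <- function(score, p = NULL, metadata = list()) {
  if (length(score) < 2L) stop("a signature needs at least 2 genes", call. = FALSE)
  genes <- names(score)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop("scores must be named by unique gene ids", call. = FALSE)
  }
  if (!all(is.finite(score))) stop("signature scores must be finite", call. = FALSE)
  o <- rank_order(score, genes)
  out <- data.frame(gene = genes[o], score = unname(score[o]),
                    stringsAsFactors = FALSE)
  if (!is.null(p)) out$p <- unname(p[genes][o])
  attr(out, "metadata") <- metadata
  class(out) <- c("gene_signature", "data.frame")
  out
}

#' @export
print.gene_signature <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("Gene signature: %d genes%s\n", nrow(x),
              if (!is.null(md$test)) paste0(" (", md$test, ")") else ""))
  cat("Top of ranking:\n")
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  cat("Bottom of ranking:\n")
  print.data.frame(utils::tail(as.data.frame(x), 5), row.names = FALSE)
  invisible(x)
}

# named score vector from a signature, in rank order
signature_scores <- function(sig) {
  stats::setNames(sig$score, sig$gene)
}

#' Differential expression signature by Welch's t-test
#'
#' Ranks genes by the unequal-variance two-sample t-statistic between two
#' phenotype groups. The sign convention is `group_b` minus `group_a`: positive
#' scores mean higher expression in `group_b`. Groups smaller than `min_n`
#' samples are refused because the t statistic is unstable below that size.
#'
#' Genes whose pooled standard error is zero cannot carry a finite statistic
#' and are dropped with a warning (both the 0/0 equal-constant case and the
#' zero-variance unequal-mean case).
#'
#' @param x numeric matrix of normalized expression, genes in rows (rownames
#'   are gene ids), samples in columns (colnames are sample ids).
#' @param labels named character vector mapping sample id to group label.
#' @param group_a,group_b the two group labels to contrast.
#' @param min_n minimum samples per group (default 5).
#' @return A [gene_signature()] whose scores are Welch t-statistics, with
#'   two-sided p-values and group sizes in the metadata.
#' @export
welch_t_signature <- function(x, labels, group_a, group_b, min_n = 5) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  unknown <- setdiff(names(labels), colnames(x))
  if (length(unknown)) {
    stop("labeled samples absent from matrix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sa <- names(labels)[labels == group_a]
  sb <- names(labels)[labels == group_b]
  if (!length(sa)) stop("unknown group label: ", group_a, call. = FALSE)
  if (!length(sb)) stop("unknown group label: ", group_b, call. = FALSE)
  if (length(sa) < min_n || length(sb) < min_n) {
    stop(sprintf("each group needs >= %d samples (got %d and %d)",
                 min_n, length(sa), length(sb)), call. = FALSE)
  }
  xa <- x[, sa, drop = FALSE]
  xb <- x[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warning(sprintf("dropping %d gene(s) with zero variance in both groups",
                    sum(degenerate)), call. = FALSE)
  }
  keep <- !degenerate
  tstat <- (mb[keep] - ma[keep]) / sqrt(se2[keep])
  # Welch-Satterthwaite degrees of freedom
  df <- se2[keep]^2 / (va[keep]^2 / (na^2 * (na - 1)) + vb[keep]^2 / (nb^2 * (nb - 1)))
  pval <- 2 * stats::pt(-abs(tstat), df)
  gene_signature(tstat, p = pval,
                 metadata = list(test = "welch_t", group_a = group_a,
                                 group_b = group_b, n_a = na, n_b = nb))
}

#' Translate a signature across species through an ortholog map
#'
#' Each mapped target-space gene inherits the score of its source gene. When
#' several source genes map to one target gene the score of largest absolute
#' value is kept; source genes absent from the map are dropped. Counts of
#' dropped and collapsed genes are logged.
#'
#' @param sig a [gene_signature()] in source (e.g. mouse) gene space.
#' @param map two-column data.frame (`source_gene`, `target_gene`); a source
#'   gene may appear in several rows (one-to-many orthology).
#' @return A [gene_signature()] in target (e.g. human) gene space.
#' @export
humanize_signature <- function(sig, map) {
  stopifnot(inherits(sig, "gene_signature"))
  map <- as.data.frame(map)
  if (ncol(map) < 2L || nrow(map) == 0L) {
    stop("ortholog map must be a nonempty two-column table", call. = FALSE)
  }
  names(map)[1:2] <- c("source_gene", "target_gene")
  hit <- map$source_gene %in% sig$gene
  m <- map[hit, , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("no signature gene is present in the ortholog map", call. = FALSE)
  }
  src_score <- signature_scores(sig)
  sc <- src_score[m$source_gene]
  has_p <- "p" %in% names(sig)
  if (has_p) pp <- stats::setNames(sig$p, sig$gene)[m$source_gene]
  # many-to-one: keep max |score|; ties broken by larger score then source id
  o <- order(m$target_gene, -abs(sc), -sc, m$source_gene, method = "radix")
  first <- !duplicated(m$target_gene[o])
  keep <- o[first]
  n_dropped <- length(unique(sig$gene)) - length(unique(m$source_gene))
  n_collapsed <- nrow(m) - length(keep)
  mr_log(sprintf("humanize: %d source genes unmapped, %d mappings collapsed (max |score|), %d target genes out",
                 n_dropped, n_collapsed, length(keep)))
  gene_signature(stats::setNames(unname(sc[keep]), m$target_gene[keep]),
                 p = if (has_p) stats::setNames(unname(pp[keep]), m$target_gene[keep]),
                 metadata = c(attr(sig, "metadata"),
                              list(humanized = TRUE, n_unmapped = n_dropped,
                                   n_collapsed = n_collapsed)))
}

#' Per-sample z-score signatures
#'
#' Builds one signature per sample by z-scoring each gene across the cohort:
#' `z_ij = (x_ij - mean_i) / sd_i` with the sample (n-1) standard deviation.
#' These per-sample signatures feed per-patient MR activity scoring. Genes
#' constant across the cohort carry no ranking information and are dropped
#' with a warning.
#'
#' @param x expression matrix, genes in rows, samples (>= 3) in columns.
#' @return A `sample_signatures` object: the z-matrix plus accessors; use
#'   [as_signature()] to extract one sample's [gene_signature()].
#' @export
single_sample_signatures <- function(x) {
  if (ncol(x) < 3L) stop("per-sample signatures need >= 3 samples", call. = FALSE)
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  drop <- sd == 0
  if (any(drop)) {
    warning(sprintf("dropping %d constant gene(s) from per-sample signatures",
                    sum(drop)), call. = FALSE)
  }
  z <- (x[!drop, , drop = FALSE] - mu[!drop]) / sd[!drop]
  structure(list(z = z, genes = rownames(z), samples = colnames(z)),
            class = "sample_signatures")
}

#' Extract one sample's signature
#' @param ss a `sample_signatures` object from [single_sample_signatures()].
#' @param sample sample id or column index.
#' @return A [gene_signature()].
#' @export
as_signature <- function(ss, sample) {
  stopifnot(inherits(ss, "sample_signatures"))
  gene_signature(stats::setNames(ss$z[, sample], ss$genes),
                 metadata = list(test = "cohort_zscore", sample = sample))
}

#' @export
print.sample_signatures <- function(x, ...) {
  cat(sprintf("Per-sample z-score signatures: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  invisible(x)
}
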