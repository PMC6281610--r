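#' Construct an interactome (collection of signed regulons)
#'
#' A regulon is a regulator together with its transcriptional targets, each
#' carrying a mode (+1 activated, -1 repressed) and a confidence weight in
#' (0, 1]. An interactome is a named collection of regulons over one gene
#' universe, the input to MR activity inference.
#'
#' @param edges data.frame with columns `regulator`, `target`, `mode` (+1/-1)
#'   and `weight` (in (0, 1]).
#' @param universe character vector of all gene ids; defaults to the genes
#'   present in `edges`.
#' @param min_regulon_size regulons with fewer targets are dropped (logged).
#' @return An `interactome` object.
#' @export
interactome <- function(edges, universe = NULL, min_regulon_size = 20) {
  edges <- as.data.frame(edges)
  req <- c("regulator", "target", "mode", "weight")
  if (!all(req %in% names(edges))) {
    stop("edges must have columns regulator, target, mode, weight", call. = FALSE)
  }
  if (!all(edges$mode %in% c(-1, 1))) stop("mode must be +1 or -1", call. = FALSE)
  if (!all(is.finite(edges$weight) & edges$weight > 0 & edges$weight <= 1)) {
    stop("weights must lie in (0, 1]", call. = FALSE)
  }
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (regulator, target) edges: ",
         paste(utils::head(edges$regulator[duplicated(key)], 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$regulator == edges$target)) {
    stop("a regulator may not target itself", call. = FALSE)
  }
  universe <- universe %||% sort(unique(c(edges$regulator, edges$target)))
  if (!all(edges$target %in% universe)) {
    stop("all targets must belong to the gene universe", call. = FALSE)
  }
  sizes <- table(edges$regulator)
  small <- names(sizes)[sizes < min_regulon_size]
  if (length(small)) {
    mr_log(sprintf("interactome: dropping %d regulon(s) below %d targets",
                   length(small), min_regulon_size))
    edges <- edges[!edges$regulator %in% small, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("no regulon meets the minimum size", call. = FALSE)
  regs <- split(edges[c("target", "mode", "weight")], edges$regulator)
  regs <- regs[sort(names(regs), method = "radix")]
  structure(list(regulons = regs, universe = universe,
                 min_regulon_size = min_regulon_size),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  sz <- vapply(x$regulons, nrow, integer(1))
  cat(sprintf("Interactome: %d regulons over %d genes\n",
              length(x$regulons), length(x$universe)))
  cat(sprintf("Regulon sizes: min %d, median %s, max %d\n",
              min(sz), format(stats::median(sz)), max(sz)))
  frac_pos <- sum(vapply(x$regulons, function(r) sum(r$mode > 0), numeric(1))) / sum(sz)
  cat(sprintf("Positive-mode edges: %.1f%%\n", 100 * frac_pos))
  invisible(x)
}

#' @export
summary.interactome <- function(object, ...) {
  sz <- vapply(object$regulons, nrow, integer(1))
  list(n_regulons = length(object$regulons),
       n_genes = length(object$universe),
       size_summary = summary(sz))
}

#' Read an interactome from a four-column TSV
#'
#' Expected dialect: header `regulator  target  mode  weight`, one edge per
#' row, mode in \{+1, -1\}, weight in (0, 1]. Malformed rows are reported with
#' their line number; duplicate edges are an error.
#'
#' @param path TSV file path.
#' @param min_regulon_size passed to [interactome()].
#' @return An `interactome`.
#' @export
read_interactome <- function(path, min_regulon_size = 20) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target", "mode", "weight") %in% names(edges))) {
    stop("interactome file must have header: regulator, target, mode, weight",
         call. = FALSE)
  }
  edges$mode <- suppressWarnings(as.numeric(edges$mode))
  edges$weight <- suppressWarnings(as.numeric(edges$weight))
  bad_mode <- which(!edges$mode %in% c(-1, 1))
  if (length(bad_mode)) {
    stop(sprintf("malformed mode at line %d of %s", bad_mode[1] + 1L, path),
         call. = FALSE)
  }
  bad_w <- which(!is.finite(edges$weight) | edges$weight <= 0 | edges$weight > 1)
  if (length(bad_w)) {
    stop(sprintf("malformed weight at line %d of %s", bad_w[1] + 1L, path),
         call. = FALSE)
  }
  key <- paste(edges$regulator, edges$target, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate edge at line %d of %s", dup[1] + 1L, path),
         call. = FALSE)
  }
  interactome(edges, min_regulon_size = min_regulon_size)
}

#' Write an interactome as TSV
#' @param x an `interactome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(x, path) {
  edges <- interactome_edges(x)
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Edge table of an interactome
#' @param x an `interactome`.
#' @return data.frame with columns regulator, target, mode, weight.
#' @export
interactome_edges <- function(x) {
  stopifnot(inherits(x, "interactome"))
  do.call(rbind, lapply(names(x$regulons), function(r) {
    cbind(data.frame(regulator = r, stringsAsFactors = FALSE),
          x$regulons[[r]], row.names = NULL)
  }))
}

#' Restrict an interactome to a signature's gene space
#'
#' Drops targets absent from the signature; regulons falling below the
#' interactome's minimum size are removed (logged). Required before
#' enrichment so hit/miss increments are well defined.
#'
#' @param x an `interactome`.
#' @param sig a [gene_signature()] (or character vector of gene ids).
#' @return A restricted `interactome`.
#' @export
restrict_to_signature <- function(x, sig) {
  stopifnot(inherits(x, "interactome"))
  genes <- if (inherits(sig, "gene_signature")) sig$gene else as.character(sig)
  regs <- lapply(x$regulons, function(r) r[r$target %in% genes, , drop = FALSE])
  sz <- vapply(regs, nrow, integer(1))
  keep <- sz >= x$min_regulon_size
  if (!all(keep)) {
    mr_log(sprintf("restrict_to_signature: dropping %d regulon(s) below %d targets",
                   sum(!keep), x$min_regulon_size))
  }
  if (!any(keep)) {
    stop("no regulon retains enough targets within the signature", call. = FALSE)
  }
  structure(list(regulons = regs[keep],
                 universe = intersect(x$universe, genes),
                 min_regulon_size = x$min_regulon_size),
            class = "interactome")
}

#' Translate an interactome into another gene space
#'
#' Renames regulators and targets through an ortholog map. Genes with several
#' orthologs use the first mapping (map row order); unmapped targets are
#' dropped, unmapped regulators lose their regulon. Used to carry a mouse
#' interactome into human gene space for a shared-truth synthetic pair.
#'
#' @param x an `interactome`.
#' @param map two-column data.frame (`source_gene`, `target_gene`).
#' @return A translated `interactome`.
#' @export
translate_interactome <- function(x, map) {
  stopifnot(inherits(x, "interactome"))
  map <- as.data.frame(map)
  names(map)[1:2] <- c("source_gene", "target_gene")
  map1 <- map[!duplicated(map$source_gene), , drop = FALSE]
  lut <- stats::setNames(map1$target_gene, map1$source_gene)
  edges <- interactome_edges(x)
  edges$regulator <- lut[edges$regulator]
  edges$target <- lut[edges$target]
  edges <- edges[!is.na(edges$regulator) & !is.na(edges$target), , drop = FALSE]
  # many-to-one orthology can merge edges or create self-loops; keep first, drop loops
  edges <- edges[!duplicated(paste(edges$regulator, edges$target, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[edges$regulator != edges$target, , drop = FALSE]
  if (nrow(edges) == 0L) stop("translation removed every edge", call. = FALSE)
  universe <- unique(unname(lut[intersect(x$universe, names(lut))]))
  interactome(edges, universe = universe, min_regulon_size = x$min_regulon_size)
}
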