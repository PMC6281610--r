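# Plain-TSV readers/writers for every pipeline artifact. All writers use a
# fixed dialect (tab separator, no quoting, '.'-decimal, full precision) so
# identical inputs produce byte-identical files.

#' Write / read an expression matrix TSV
#'
#' Rows are genes (first column `gene`), remaining columns samples.
#' @param x genes x samples numeric matrix with dimnames.
#' @param path file path.
#' @return `path` invisibly (writer); the matrix (reader).
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("expression TSV must start with a 'gene' column",
                                   call. = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in expression TSV",
                                   call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (!all(is.finite(m))) stop("expression values must be finite", call. = FALSE)
  m
}

#' Write / read sample group labels
#' @param labels named character vector (sample -> group).
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample = names(labels), group = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df$group), df$sample)
}

#' Write / read a clinical table
#' @param clinical a [clinical_table()].
#' @param path file path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical)[c("sample", "time", "event")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read an ortholog map
#' @param map data.frame (`source_gene`, `target_gene`).
#' @param path file path.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map[c("source_gene", "target_gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_gene", "target_gene") %in% names(df))) {
    stop("ortholog map needs columns source_gene, target_gene", call. = FALSE)
  }
  df
}

#' Write / read a gene signature TSV (`gene`, `score`, optional `p`)
#' @param sig a [gene_signature()].
#' @param path file path.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_signature(stats::setNames(df$score, df$gene),
                 p = if ("p" %in% names(df)) stats::setNames(df$p, df$gene))
}

#' Write planted truth as JSON
#' @param truth a `planted_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(planted_regulators = truth$planted_regulators,
                            effect = as.list(truth$effect),
                            latent_activity = if (!is.null(truth$latent_activity))
                              as.list(truth$latent_activity)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
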