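#' Stouffer integration of mouse and human MR lists
#'
#' Combines per-species MR activity into one conserved-MR table. Each species
#' contributes its signed NES as a z-score; the combined evidence is
#' `z_combined = (z_mouse + z_human) / sqrt(2)` with equal species weights,
#' and `p_combined` is the two-sided normal tail of `z_combined`. A regulator
#' is flagged concordant when its NES carries the same sign in both species.
#' Mouse regulator ids are translated into human space through the ortholog
#' map before intersection; one-to-many orthology is resolved by keeping the
#' mouse row of largest |NES| per human id.
#'
#' @param mouse,human `mr_activity_table`s from [marina_activity()].
#' @param ortholog_map optional two-column data.frame (`source_gene`,
#'   `target_gene`) translating mouse regulator ids; omit when both tables
#'   already share a gene space.
#' @return A `conserved_mr_table`: data.frame with per-regulator mouse and
#'   human NES/p, species z-scores, `z_combined`, `p_combined` and
#'   `concordant`, ordered by decreasing |z_combined|.
#' @export
stouffer_integrate <- function(mouse, human, ortholog_map = NULL) {
  m <- as.data.frame(mouse)[!mouse$degenerate, c("regulator", "nes", "p")]
  h <- as.data.frame(human)[!human$degenerate, c("regulator", "nes", "p")]
  if (!is.null(ortholog_map)) {
    map <- as.data.frame(ortholog_map)
    names(map)[1:2] <- c("source_gene", "target_gene")
    m <- merge(m, map, by.x = "regulator", by.y = "source_gene")
    m$regulator <- m$target_gene
    m$target_gene <- NULL
    # one-to-many then many-to-one: keep largest |NES| per human id
    o <- order(m$regulator, -abs(m$nes), method = "radix")
    m <- m[o[!duplicated(m$regulator[o])], , drop = FALSE]
  }
  names(m)[2:3] <- c("nes_mouse", "p_mouse")
  names(h)[2:3] <- c("nes_human", "p_human")
  tab <- merge(m, h, by = "regulator")
  if (nrow(tab) == 0L) {
    stop("no regulator shared between the mouse and human tables", call. = FALSE)
  }
  tab$z_mouse <- tab$nes_mouse
  tab$z_human <- tab$nes_human
  tab$z_combined <- (tab$z_mouse + tab$z_human) / sqrt(2)
  tab$p_combined <- 2 * stats::pnorm(-abs(tab$z_combined))
  tab$concordant <- sign(tab$nes_mouse) == sign(tab$nes_human)
  tab <- tab[order(-abs(tab$z_combined), tab$regulator, method = "radix"), ]
  rownames(tab) <- NULL
  class(tab) <- c("conserved_mr_table", "data.frame")
  tab
}

#' @export
print.conserved_mr_table <- function(x, ...) {
  cat(sprintf("Conserved MR table: %d regulators (%d concordant)\n",
              nrow(x), sum(x$concordant)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

#' Filter the conserved-MR table
#'
#' Retains regulators whose combined evidence passes a p-value threshold,
#' optionally requiring cross-species directional concordance and a single
#' activity direction (activated MRs are therapeutic-inhibition candidates).
#'
#' @param tab a `conserved_mr_table`.
#' @param p_threshold combined p cutoff (default 1e-4).
#' @param require_concordance drop regulators whose NES signs disagree
#'   between species (default TRUE).
#' @param direction `"activated"` (combined z > 0, default), `"repressed"`,
#'   or `"both"`.
#' @return The filtered `conserved_mr_table` (possibly empty; logged).
#' @export
filter_conserved <- function(tab, p_threshold = 1e-4, require_concordance = TRUE,
                             direction = c("activated", "repressed", "both")) {
  direction <- match.arg(direction)
  if (nrow(tab) == 0L) stop("empty conserved-MR table", call. = FALSE)
  keep <- tab$p_combined < p_threshold
  if (require_concordance) keep <- keep & tab$concordant
  keep <- keep & switch(direction,
                        activated = tab$z_combined > 0,
                        repressed = tab$z_combined < 0,
                        both = TRUE)
  out <- tab[keep, , drop = FALSE]
  mr_log(sprintf("filter_conserved: %d of %d regulators pass (p < %g, %s%s)",
                 nrow(out), nrow(tab), p_threshold, direction,
                 if (require_concordance) ", concordant" else ""))
  rownames(out) <- NULL
  class(out) <- c("conserved_mr_table", "data.frame")
  out
}

#' Membership filter against an annotation gene list
#'
#' Restricts a conserved-MR table to regulators present in a user-supplied
#' annotation set (e.g. a curated list of epigenetic regulators).
#'
#' @param tab a `conserved_mr_table`.
#' @param annotation nonempty character vector of gene ids.
#' @return The filtered `conserved_mr_table`.
#' @export
annotation_filter <- function(tab, annotation) {
  if (!length(annotation)) stop("annotation set is empty", call. = FALSE)
  out <- tab[tab$regulator %in% annotation, , drop = FALSE]
  mr_log(sprintf("annotation_filter: %d of %d regulators annotated",
                 nrow(out), nrow(tab)))
  rownames(out) <- NULL
  class(out) <- c("conserved_mr_table", "data.frame")
  out
}
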