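#' Coverage statistics of a supermatrix
#'
#' @param aln an [aa_alignment].
#' @return A `coverage_stats` list: `per_taxon_missing` (fractions, named),
#'   `per_column_present` (counts), `overall_coverage` (percentage of
#'   non-missing cells).
#' @export
coverage_stats <- function(aln) {
  m <- is.na(unclass(aln))
  structure(list(
    per_taxon_missing = rowMeans(m),
    per_column_present = colSums(!m),
    overall_coverage = 100 * mean(!m)),
    class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf("coverage: %.1f%% of cells observed; per-taxon missing %.1f%%-%.1f%%\n",
              x$overall_coverage, 100 * min(x$per_taxon_missing),
              100 * max(x$per_taxon_missing)))
  invisible(x)
}

#' Filter columns by taxon coverage
#'
#' Keeps the positions at which data are available from at least
#' `min_fraction` of all taxa (inclusive). The taxon set is unchanged; a
#' provenance map from kept columns back to original 1-based indices is
#' attached.
#'
#' @param aln an [aa_alignment].
#' @param min_fraction required fraction of non-missing taxa per column,
#'   in (0, 1].
#' @return filtered [aa_alignment] with attribute `kept_columns`.
#' @export
position_coverage_filter <- function(aln, min_fraction = 0.5) {
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]")
  present <- colSums(!is.na(unclass(aln)))
  keep <- which(present >= min_fraction * n_taxa(aln))
  if (length(keep) == 0L)
    stop("coverage filter at min_fraction = ", min_fraction,
         " removes all columns")
  out <- .subset_alignment(aln, cols = keep)
  attr(out, "kept_columns") <- keep
  out
}

#' Gene admission rule
#'
#' Admits per-gene alignments that are at least `min_length` positions
#' long and contain at least `min_taxa` taxa with at least one observed
#' residue (both thresholds inclusive).
#'
#' @param gene_alignments list of [aa_alignment] objects.
#' @param min_length minimum alignment length (default 100).
#' @param min_taxa minimum number of taxa with data (default 25).
#' @return list with `admitted` (the passing alignments), `report`
#'   (data.frame: gene, n_columns, n_taxa_with_data, admitted).
#' @export
gene_admission_filter <- function(gene_alignments, min_length = 100L,
                                  min_taxa = 25L) {
  if (length(gene_alignments) == 0L)
    return(list(admitted = list(),
                report = data.frame(gene = integer(0), n_columns = integer(0),
                                    n_taxa_with_data = integer(0),
                                    admitted = logical(0))))
  nc <- vapply(gene_alignments, n_columns, 0L)
  ntx <- vapply(gene_alignments, function(a)
    sum(rowSums(!is.na(unclass(a))) > 0L), 0L)
  ok <- nc >= min_length & ntx >= min_taxa
  nm <- names(gene_alignments)
  if (is.null(nm)) nm <- as.character(seq_along(gene_alignments))
  list(admitted = gene_alignments[ok],
       report = data.frame(gene = nm, n_columns = nc,
                           n_taxa_with_data = ntx, admitted = ok))
}

#' Shared-missing-data overlap matrix
#'
#' `o(i, j)` is the fraction of columns missing in both taxon i and taxon
#' j; the diagonal is each taxon's own missing fraction. Strong off-
#' diagonal structure (taxa sharing the same absent genes) can create
#' artifactual attraction in tree inference, which is what the companion
#' clustering ([cluster_overlap()]) screens for.
#'
#' @param aln an [aa_alignment].
#' @return list with `o` (symmetric matrix in `[0,1]`) and `density`
#'   (histogram of the off-diagonal entries, class `histogram`).
#' @export
shared_missing_overlap <- function(aln) {
  miss <- is.na(unclass(aln)) + 0
  o <- tcrossprod(miss) / n_columns(aln)
  dimnames(o) <- list(taxon_labels(aln), taxon_labels(aln))
  off <- o[lower.tri(o)]
  dens <- graphics::hist(off, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  list(o = o, density = dens)
}

#' Cluster taxa by shared-missingness overlap
#'
#' Hierarchical clustering of the overlap matrix on distance `1 - o`
#' (average linkage by default); the leaf order is the canonical ordering
#' for heat-map display on both axes.
#'
#' @param o overlap matrix (or the list from [shared_missing_overlap()]).
#' @param linkage `"average"` (UPGMA), `"complete"` or `"single"`.
#' @return list with `hclust` (the dendrogram), `order` (leaf order),
#'   `labels_ordered`.
#' @export
cluster_overlap <- function(o, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.list(o) && !is.null(o$o)) o <- o$o
  if (nrow(o) < 3L) stop("need at least 3 taxa to cluster")
  hc <- stats::hclust(stats::as.dist(1 - o), method = linkage)
  list(hclust = hc, order = hc$order, labels_ordered = hc$labels[hc$order])
}

#' Heat map of the overlap matrix in dendrogram order
#'
#' @param o overlap matrix or [shared_missing_overlap()] result.
#' @param clustering optionally a [cluster_overlap()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot_overlap_heatmap <- function(o, clustering = NULL, ...) {
  if (is.list(o) && !is.null(o$o)) o <- o$o
  if (is.null(clustering)) clustering <- cluster_overlap(o)
  ord <- clustering$order
  om <- o[ord, ord]
  n <- nrow(om)
  graphics::image(seq_len(n), seq_len(n), t(om[n:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "shared missing data (dendrogram order)", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(om), las = 2,
                 cex.axis = 0.5)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(om)), las = 2,
                 cex.axis = 0.5)
  invisible(om)
}

#' Missing data mapped on the tree
#'
#' Recodes the matrix as presence (1) / absence (0) of data, reconstructs
#' ancestral presence by parsimony with ACCTRAN on the rooted tree, and
#' reports per node the percentage of columns reconstructed as absent.
#' Tip values equal the observed per-taxon missing percentages. Root-state
#' ties are resolved to "present" (a gene is ancestrally present and lost
#' along lineages); all other ties follow the ACCTRAN rule of pulling
#' changes rootward.
#'
#' @param aln an [aa_alignment].
#' @param phy a rooted [ape::phylo] matching the alignment's taxa.
#' @return A `branch_missingness` list: `per_node_missing_pct` (named by
#'   ape node id), `tree` (the input tree with `node.label` set to the
#'   internal-node percentages), `states` (nodes x columns, 1 = absent,
#'   2 = present).
#' @export
missing_on_tree <- function(aln, phy) {
  if (!ape::is.rooted(phy))
    stop("tree is not rooted; root it first with root_with_outgroup()")
  .check_labels_match(aln, phy)
  m <- unclass(aln)[phy$tip.label, , drop = FALSE]
  # binary alphabet: 1 = absent, 2 = present; tie preference: present first
  states <- matrix(ifelse(is.na(m), 1L, 2L), nrow(m), ncol(m))
  assign_mat <- .acctran_assign(states, phy, S = 2L, tie_rank = c(2L, 1L))
  pct <- 100 * rowMeans(assign_mat == 1L)
  names(pct) <- as.character(seq_along(pct))
  annotated <- phy
  annotated$node.label <- sprintf("%.1f",
                                  pct[as.character(root_node(phy):max(phy$edge))])
  structure(list(per_node_missing_pct = pct, tree = annotated,
                 states = assign_mat),
            class = "branch_missingness")
}

#' @export
print.branch_missingness <- function(x, ...) {
  cat("branch_missingness: per-node %missing in [",
      sprintf("%.1f", min(x$per_node_missing_pct)), ", ",
      sprintf("%.1f", max(x$per_node_missing_pct)), "]\n", sep = "")
  invisible(x)
}

#' Colour-graded tree plot of per-branch missingness
#'
#' @param x a `branch_missingness` result.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot_missing_tree <- function(x, ...) {
  phy <- x$tree
  pct <- x$per_node_missing_pct
  child_pct <- pct[as.character(phy$edge[, 2L])]
  pal <- grDevices::hcl.colors(101, "Blue-Red")
  cols <- pal[pmin(100L, pmax(0L, round(child_pct))) + 1L]
  ape::plot.phylo(phy, edge.color = cols, ...)
  invisible(x)
}
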