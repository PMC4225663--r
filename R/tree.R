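#' Read a rooted (or rootable) tree from a Newick file
#'
#' Wraps [ape::read.tree()]. Internal support labels are kept as
#' `node.label` annotations; a basal bifurcation is kept as read.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("tree format error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("tree format error: unreadable Newick in ", path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  if (anyDuplicated(phy$tip.label))
    stop("tree format error: duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  phy
}

#' Write a tree to Newick
#' @param phy an [ape::phylo] object.
#' @param path output path.
#' @export
write_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Root a tree on the branch subtending an outgroup
#'
#' @param phy an [ape::phylo] object (rooted or unrooted).
#' @param outgroup character vector of tip labels; must be a proper,
#'   non-empty subset of the tips separable by a single branch.
#' @return A rooted [ape::phylo] with unchanged tip set.
#' @export
root_with_outgroup <- function(phy, outgroup) {
  outgroup <- as.character(outgroup)
  if (length(outgroup) == 0L) stop("outgroup is empty")
  unknown <- setdiff(outgroup, phy$tip.label)
  if (length(unknown))
    stop("unknown outgroup tip label(s): ", paste(unknown, collapse = ", "))
  if (length(outgroup) >= length(phy$tip.label))
    stop("outgroup must be a proper subset of the tips")
  if (!ape::is.monophyletic(phy, outgroup))
    stop("outgroup is not separable by a single branch ",
         "(not monophyletic in the unrooted sense)")
  rooted <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  stopifnot(setequal(rooted$tip.label, phy$tip.label))
  rooted
}

#' Specify a focal clade by name and tip set
#'
#' @param name clade name used in reports (e.g. a hypothesis name).
#' @param tips non-empty character vector of tip labels.
#' @return A `clade_spec` object.
#' @export
clade_spec <- function(name, tips) {
  tips <- unique(as.character(tips))
  if (length(tips) == 0L) stop("clade tips must be non-empty")
  structure(list(name = as.character(name), tips = tips),
            class = "clade_spec")
}

#' Resolve a clade to its MRCA node
#'
#' Finds the most recent common ancestor of `spec$tips` and reports
#' whether the clade is exactly monophyletic on the tree (the MRCA's tip
#' set equals the requested tips). A non-monophyletic query whose MRCA is
#' the root triggers a warning: the root has no stem branch, so
#' stem-branch analyses are impossible for it.
#'
#' @param phy a rooted [ape::phylo].
#' @param spec a [clade_spec()] (or character vector of tips).
#' @return list with `node` (ape node id), `monophyletic` (logical),
#'   `tips_found` (tips actually under the MRCA).
#' @export
resolve_clade <- function(phy, spec) {
  if (is.character(spec)) spec <- clade_spec("clade", spec)
  unknown <- setdiff(spec$tips, phy$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  root <- n_tips(phy) + 1L
  if (length(spec$tips) == 1L) {
    node <- match(spec$tips, phy$tip.label)
  } else {
    node <- ape::getMRCA(phy, spec$tips)
  }
  under <- tips_under(phy, node)
  mono <- setequal(under, spec$tips)
  if (!mono && node == root)
    warning("clade '", spec$name, "' is not monophyletic and its MRCA is ",
            "the root: a stem-branch analysis is impossible")
  list(node = node, monophyletic = mono, tips_found = under)
}

# ---- small tree helpers used across modules ----

n_tips <- function(phy) length(phy$tip.label)

root_node <- function(phy) n_tips(phy) + 1L

#' @noRd
tips_under <- function(phy, node) {
  nt <- n_tips(phy)
  if (node <= nt) return(phy$tip.label[node])
  kids <- .children_list(phy)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v <= nt) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  phy$tip.label[out]
}

.children_list <- function(phy) {
  n_nodes <- max(phy$edge)
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1L]]] <- c(kids[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  kids
}

.parent_vec <- function(phy) {
  par <- rep(NA_integer_, max(phy$edge))
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

# internal nodes in postorder (children before parents), root last
.postorder_nodes <- function(phy) {
  e <- ape::reorder.phylo(phy, "postorder")$edge
  unique(e[, 1L])
}

# internal nodes in preorder (root first)
.preorder_nodes <- function(phy) rev(.postorder_nodes(phy))

#' Stable internal node labels
#'
#' Gives each internal node a reproducible label built from its preorder
#' index and a short hash of its sorted tip set, so reports can be
#' compared across runs and across tools that renumber nodes.
#'
#' @param phy a rooted [ape::phylo].
#' @return named character vector indexed by ape node id.
#' @export
node_labels <- function(phy) {
  pre <- .preorder_nodes(phy)
  labs <- vapply(seq_along(pre), function(i) {
    tips <- sort(tips_under(phy, pre[i]))
    h <- sum(utf8ToInt(paste(tips, collapse = "|")) *
               (seq_len(nchar(paste(tips, collapse = "|"))) %% 97L))
    sprintf("N%02d_%04x", i, h %% 65536L)
  }, character(1))
  names(labs) <- as.character(pre)
  labs
}

# unrooted bipartition set as canonical strings (used by tests too)
#' @noRd
bipartitions <- function(phy) {
  nt <- n_tips(phy)
  all_tips <- sort(phy$tip.label)
  res <- character(0)
  for (node in setdiff(unique(phy$edge[, 2L]), seq_len(nt))) {
    side <- sort(tips_under(phy, node))
    if (length(side) <= 1L || length(side) >= nt - 1L) next
    other <- setdiff(all_tips, side)
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    res <- c(res, key)
  }
  sort(unique(res))
}

.check_labels_match <- function(aln, phy) {
  if (!setequal(taxon_labels(aln), phy$tip.label))
    stop("label mismatch between alignment and tree; alignment-only: ",
         paste(setdiff(taxon_labels(aln), phy$tip.label), collapse = ", "),
         "; tree-only: ",
         paste(setdiff(phy$tip.label, taxon_labels(aln)), collapse = ", "))
  invisible(TRUE)
}
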