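## Parsimony engine: Fitch/Hartigan counting and Sankoff-based ACCTRAN
## assignment on a fixed rooted tree. Polytomies are handled natively
## (Hartigan's k-ary generalization of Fitch counting; Sankoff transitions
## are k-ary sums). Missing tips contribute the full state set at no cost;
## a column that is entirely missing scores 0 and reconstructs as missing
## everywhere.

.BIG <- 1000000L

.colmins <- function(M) do.call(pmin, asplit(M, 1L))

# tip state-set (logical S x nc) / tip cost (integer S x nc)
.tip_set <- function(states_row, S) {
  nc <- length(states_row)
  M <- matrix(FALSE, S, nc)
  obs <- !is.na(states_row)
  M[cbind(states_row[obs], which(obs))] <- TRUE
  M[, !obs] <- TRUE
  M
}

.tip_cost <- function(states_row, S) {
  nc <- length(states_row)
  M <- matrix(.BIG, S, nc)
  obs <- !is.na(states_row)
  M[cbind(states_row[obs], which(obs))] <- 0L
  M[, !obs] <- 0L
  M
}

# Hartigan downpass minimum-change count, chunked over columns.
# states: taxa x columns integer matrix (1..S, NA missing), rows in
# phy tip order.
.hartigan_length <- function(states, phy, S, chunk = 4096L) {
  nt <- n_tips(phy)
  nc <- ncol(states)
  kids <- .children_list(phy)
  post <- .postorder_nodes(phy)
  out <- integer(nc)
  for (lo in seq(1L, nc, by = chunk)) {
    hi <- min(lo + chunk - 1L, nc)
    idx <- lo:hi
    sets <- vector("list", max(phy$edge))
    cost <- integer(hi - lo + 1L)
    for (v in post) {
      ch <- kids[[v]]
      cnt <- matrix(0L, S, length(idx))
      for (c in ch) {
        cs <- if (c <= nt) .tip_set(states[c, idx], S) else sets[[c]]
        cnt <- cnt + cs
        if (c > nt) sets[c] <- list(NULL)  # free
      }
      K <- .colmins(-cnt)  # = -max
      K <- -K
      cost <- cost + (length(ch) - K)
      sets[[v]] <- cnt == rep(K, each = S)
    }
    out[idx] <- cost
  }
  out
}

#' Per-column parsimony change counts (Fitch/Hartigan)
#'
#' Minimum number of state changes per alignment column on a fixed tree,
#' under unordered (Fitch) parsimony with Hartigan's generalization for
#' polytomies. Missing tips are unconstrained and cost nothing; fully
#' missing columns score 0.
#'
#' @param aln an [aa_alignment].
#' @param phy an [ape::phylo] with tip set equal to the alignment's taxa.
#' @return list with `per_column` (integer vector) and `total`.
#' @export
fitch_length <- function(aln, phy) {
  .check_labels_match(aln, phy)
  states <- .encode_alignment(aln)[phy$tip.label, , drop = FALSE]
  per_col <- .hartigan_length(states, phy, S = length(AA_ALPHABET))
  list(per_column = per_col, total = sum(per_col))
}

# ACCTRAN assignment via Sankoff downpass + greedy preorder resolution.
# Among most-parsimonious reconstructions, changes are pulled rootward:
# processing nodes preorder, a change is placed on the current stem branch
# whenever some MPR consistent with the decisions made so far allows it.
# Remaining ties are broken by tie_rank (lower rank preferred); default is
# state order, i.e. alphabetical for the amino-acid alphabet.
.acctran_assign <- function(states, phy, S, tie_rank = seq_len(S),
                            chunk = 4096L) {
  nt <- n_tips(phy)
  nc <- ncol(states)
  n_nodes <- max(phy$edge)
  kids <- .children_list(phy)
  par <- .parent_vec(phy)
  post <- .postorder_nodes(phy)
  pre <- rev(post)
  root <- root_node(phy)
  assign_mat <- matrix(NA_integer_, n_nodes, nc)
  assign_mat[seq_len(nt), ] <- states

  # per-node "entire subtree missing" flags
  allmiss <- matrix(FALSE, n_nodes, nc)
  allmiss[seq_len(nt), ] <- is.na(states)
  for (v in post) {
    am <- rep(TRUE, nc)
    for (c in kids[[v]]) am <- am & allmiss[c, ]
    allmiss[v, ] <- am
  }

  rankrow <- matrix(tie_rank, S, 1L)

  for (lo in seq(1L, nc, by = chunk)) {
    hi <- min(lo + chunk - 1L, nc)
    idx <- lo:hi
    m <- length(idx)
    cost <- vector("list", n_nodes)
    for (v in post) {
      cv <- matrix(0L, S, m)
      for (c in kids[[v]]) {
        cc <- if (c <= nt) .tip_cost(states[c, idx], S) else cost[[c]]
        minc <- .colmins(cc)
        cv <- cv + pmin(cc, rep(minc + 1L, each = S))
      }
      cv <- pmin(cv, .BIG)
      cost[[v]] <- cv
    }
    # root: among minimal-cost states pick the best tie_rank
    cr <- cost[[root]]
    mr <- .colmins(cr)
    cand <- ifelse(cr == rep(mr, each = S), rankrow[, rep(1L, m)], Inf)
    pick <- max.col(-t(cand), ties.method = "first")
    assign_mat[root, idx] <- as.integer(pick)
    for (v in pre) {
      if (v == root) next
      if (v <= nt) next
      x <- assign_mat[par[v], idx]
      cv <- cost[[v]]
      cc <- cv + 1L
      ok <- !is.na(x)
      if (any(ok)) cc[cbind(x[ok], which(ok))] <- cv[cbind(x[ok], which(ok))]
      mv <- .colmins(cc)
      ism <- cc == rep(mv, each = S)
      # prefer a state different from the parent (accelerate the change)
      diffm <- ism
      if (any(ok)) diffm[cbind(x[ok], which(ok))] <- FALSE
      cand <- ifelse(diffm, rankrow[, rep(1L, m)], Inf)
      sel <- max.col(-t(cand), ties.method = "first")
      has_diff <- colSums(diffm) > 0L
      res <- ifelse(has_diff, as.integer(sel), x)
      assign_mat[v, idx] <- res
    }
  }
  assign_mat[allmiss] <- NA_integer_
  assign_mat
}

#' ACCTRAN ancestral-state reconstruction
#'
#' Reconstructs a single most-parsimonious assignment of states to every
#' internal node of a rooted tree, resolving ambiguity with accelerated
#' transformation (ACCTRAN): among most-parsimonious reconstructions,
#' changes are placed as close to the root as possible. Ties remaining
#' after the ACCTRAN criterion (including the root state) are broken by
#' alphabetical state order. Nodes whose entire subtree is unobserved at a
#' column are reconstructed as missing there.
#'
#' @param aln an [aa_alignment].
#' @param phy a rooted [ape::phylo]; an unrooted tree is an error
#'   (use [root_with_outgroup()] first).
#' @return An `ancestral_recon` object: list with `tree`, `states`
#'   (nodes x columns integer matrix over [AA_ALPHABET], tips included),
#'   `alphabet`, `per_column_changes`, `total_changes`.
#' @export
acctran_reconstruct <- function(aln, phy) {
  if (!ape::is.rooted(phy))
    stop("tree is not rooted; root it first with root_with_outgroup()")
  .check_labels_match(aln, phy)
  S <- length(AA_ALPHABET)
  states <- .encode_alignment(aln)[phy$tip.label, , drop = FALSE]
  assign_mat <- .acctran_assign(states, phy, S)
  per_col <- .count_changes(assign_mat, phy)
  structure(list(tree = phy, states = assign_mat, alphabet = AA_ALPHABET,
                 per_column_changes = per_col,
                 total_changes = sum(per_col)),
            class = "ancestral_recon")
}

# change count per column implied by an assignment (branches with a
# missing endpoint contribute nothing: an unobserved subtree always has a
# zero-cost completion copying the parent state)
.count_changes <- function(assign_mat, phy) {
  nc <- ncol(assign_mat)
  per_col <- integer(nc)
  for (i in seq_len(nrow(phy$edge))) {
    a <- assign_mat[phy$edge[i, 1L], ]
    b <- assign_mat[phy$edge[i, 2L], ]
    per_col <- per_col + (!is.na(a) & !is.na(b) & a != b)
  }
  per_col
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("ancestral_recon: ", length(x$tree$tip.label), " tips, ",
      ncol(x$states), " columns, parsimony length ", x$total_changes,
      "\n", sep = "")
  invisible(x)
}

#' Columns carrying an apomorphy for a focal node
#'
#' A column is an apomorphy of the focal clade when the reconstructed
#' state at the clade's MRCA differs from the reconstructed state at its
#' direct ancestor and neither is missing. Each qualifying column is
#' reported with its (ancestor -> derived) state pair; column indices are
#' 1-based.
#'
#' @param recon an `ancestral_recon` from [acctran_reconstruct()].
#' @param clade_node ape node id of an internal, non-root node.
#' @param clade_name optional label for reports.
#' @return An `apomorphy_table`: data.frame with `column`,
#'   `ancestor_state`, `derived_state`; attributes `clade_name`, `node`,
#'   `count`.
#' @export
extract_apomorphies <- function(recon, clade_node, clade_name = NULL) {
  phy <- recon$tree
  nt <- n_tips(phy)
  if (clade_node <= nt)
    stop("focal node must be internal (got a tip)")
  if (clade_node == root_node(phy))
    stop("the root has no stem branch; apomorphies are undefined for it")
  par <- .parent_vec(phy)[clade_node]
  a <- recon$states[par, ]
  d <- recon$states[clade_node, ]
  keep <- !is.na(a) & !is.na(d) & a != d
  tab <- data.frame(column = which(keep),
                    ancestor_state = recon$alphabet[a[keep]],
                    derived_state = recon$alphabet[d[keep]],
                    stringsAsFactors = FALSE)
  structure(tab,
            clade_name = if (is.null(clade_name)) paste0("node", clade_node)
                         else clade_name,
            node = clade_node, count = nrow(tab),
            class = c("apomorphy_table", "data.frame"))
}

#' Positional distribution of apomorphies along the alignment
#'
#' Bins apomorphy columns along the alignment and reports a one-sample
#' Kolmogorov-Smirnov statistic of the column positions against the
#' uniform distribution on `[1, n_columns]`. The KS number is a
#' screening diagnostic: apomorphies concentrated in a short stretch of
#' the alignment (large KS) suggest contamination or misassigned
#' orthologs rather than genuine signal.
#'
#' @param table an `apomorphy_table`.
#' @param n_columns total alignment width.
#' @param n_bins number of bins (>= 2).
#' @return list with `counts` (per bin), `breaks`, `ks_statistic`.
#' @export
apomorphy_distribution <- function(table, n_columns, n_bins = 20L) {
  if (nrow(table) == 0L) stop("empty apomorphy table")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  pos <- table$column
  breaks <- seq(0, n_columns, length.out = n_bins + 1L)
  bin <- pmin(pmax(ceiling(pos / n_columns * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  # one-sample KS against U(0, n_columns), standard D_n formula
  u <- sort(pos) / n_columns
  n <- length(u)
  d_plus <- max(seq_len(n) / n - u)
  d_minus <- max(u - (seq_len(n) - 1L) / n)
  list(counts = counts, breaks = breaks,
       ks_statistic = max(d_plus, d_minus))
}
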