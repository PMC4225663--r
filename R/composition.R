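#' Amino-acid composition of a sequence
#'
#' Counts residues over the 20 canonical states; missing cells are
#' skipped.
#'
#' @param seq character vector of states (NA = missing), a single string,
#'   or a row of an [aa_alignment].
#' @return A `composition_vector`: named integer vector of length 20 with
#'   attribute `n_valid` (total residues counted).
#' @export
composition_counts <- function(seq) {
  if (length(seq) == 1L && !is.na(seq) && nchar(seq) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1L]]
  seq <- toupper(as.character(seq))
  seq[seq %in% .MISSING_SYMBOLS] <- NA_character_
  idx <- match(seq, AA_ALPHABET)
  if (any(!is.na(seq) & is.na(idx)))
    stop("illegal residue in sequence: ",
         paste(unique(seq[!is.na(seq) & is.na(idx)]), collapse = ", "))
  counts <- tabulate(idx, nbins = length(AA_ALPHABET))
  names(counts) <- AA_ALPHABET
  structure(counts, n_valid = sum(counts),
            class = c("composition_vector", "integer"))
}

#' @noRd
.comp_add <- function(a, b) {
  out <- unclass(a) + unclass(b)
  structure(out, n_valid = attr(a, "n_valid") + attr(b, "n_valid"),
            class = c("composition_vector", "integer"))
}

#' Chi-square test of compositional homogeneity
#'
#' Tests one sequence's amino-acid composition against a pooled
#' composition, following the TREE-PUZZLE convention: expected counts are
#' `e_i = n_focal * pool_i / n_pool`; the statistic sums
#' `(o_i - e_i)^2 / e_i` over states with `e_i > 0`; degrees of freedom
#' are fixed at 19 even when states are absent from the pool; the p-value
#' is the upper tail of the chi-square distribution.
#'
#' @param focal a `composition_vector` for the tested sequence.
#' @param pool a `composition_vector` for the pooled subset (which, by the
#'   convention used here, includes the focal sequence itself).
#' @param focal_label label carried into the result.
#' @return A `comp_test` object: list with `chi2`, `df`, `p`,
#'   `focal_label`, `subset_size` (the focal sequence's residue count).
#' @export
chi_square_homogeneity <- function(focal, pool, focal_label = "focal") {
  n_f <- attr(focal, "n_valid")
  n_p <- attr(pool, "n_valid")
  if (is.null(n_f)) n_f <- sum(focal)
  if (is.null(n_p)) n_p <- sum(pool)
  if (n_f == 0L) stop("zero-length focal sequence")
  if (n_p == 0L) stop("empty pool")
  e <- n_f * unclass(pool) / n_p
  o <- unclass(focal)
  keep <- e > 0
  chi2 <- sum((o[keep] - e[keep])^2 / e[keep])
  df <- length(AA_ALPHABET) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 focal_label = focal_label, subset_size = n_f),
            class = "comp_test")
}

#' @export
print.comp_test <- function(x, ...) {
  cat(sprintf("comp_test [%s]: chi2 = %.3f, df = %d, p = %.4g (%.2f%%), n = %d\n",
              x$focal_label, x$chi2, x$df, x$p, 100 * x$p, x$subset_size))
  invisible(x)
}

#' Node-based compositional-bias evaluation
#'
#' The central diagnostic: does the reconstructed ancestral sequence of a
#' focal clade deviate in amino-acid composition, at the columns that
#' carry apomorphies for that clade, from the pooled composition of the
#' subset? The subset comprises all terminal taxa restricted to the
#' apomorphy columns plus the two reconstructed ancestral rows (the
#' clade's MRCA and its direct ancestor), and both ancestral rows are
#' tested against the pooled composition of the whole subset.
#'
#' A clade that is not monophyletic on the supplied tree is refused:
#' supply a topology in which the group is constrained to be monophyletic
#' (tree inference is outside this package's scope).
#'
#' @param aln an [aa_alignment].
#' @param phy a rooted [ape::phylo].
#' @param clade a [clade_spec()] (or character vector of tips).
#' @param per_taxon if `TRUE`, also test every terminal against the
#'   subset pool.
#' @param recon optionally, a precomputed [acctran_reconstruct()] result
#'   for `aln`/`phy` (lets several clades share one reconstruction).
#' @return A `node_bias_report`: list with `clade_name`, `node`,
#'   `apomorphy_count`, `apomorphies` (the table), `test_focal`,
#'   `test_ancestor`, and optionally `per_taxon_tests`.
#' @export
node_bias_evaluation <- function(aln, phy, clade, per_taxon = FALSE,
                                 recon = NULL) {
  if (is.character(clade)) clade <- clade_spec("clade", clade)
  res <- resolve_clade(phy, clade)
  if (!res$monophyletic)
    stop("clade '", clade$name, "' is not monophyletic on the supplied ",
         "tree; supply a topology constrained for its monophyly ",
         "(tree inference is external to this package)")
  if (res$node == root_node(phy))
    stop("clade '", clade$name, "' spans the whole tree (root); ",
         "no stem branch to test")
  if (is.null(recon)) recon <- acctran_reconstruct(aln, phy)
  apo <- extract_apomorphies(recon, res$node, clade_name = clade$name)
  if (nrow(apo) == 0L)
    stop("no apomorphies for node of clade '", clade$name, "'")
  cols <- apo$column
  par <- .parent_vec(phy)[res$node]

  term <- unclass(aln)[, cols, drop = FALSE]
  focal_row <- recon$alphabet[recon$states[res$node, cols]]
  anc_row <- recon$alphabet[recon$states[par, cols]]

  term_comps <- lapply(seq_len(nrow(term)),
                       function(i) composition_counts(term[i, ]))
  comp_focal <- composition_counts(focal_row)
  comp_anc <- composition_counts(anc_row)
  pool <- Reduce(.comp_add, c(term_comps, list(comp_focal, comp_anc)))

  out <- list(
    clade_name = clade$name,
    node = res$node,
    apomorphy_count = attr(apo, "count"),
    apomorphies = apo,
    test_focal = chi_square_homogeneity(comp_focal, pool,
                                        focal_label = clade$name),
    test_ancestor = chi_square_homogeneity(
      comp_anc, pool,
      focal_label = paste0("ancestor(", clade$name, ")")))
  if (per_taxon) {
    tt <- lapply(seq_along(term_comps), function(i)
      chi_square_homogeneity(term_comps[[i]], pool,
                             focal_label = rownames(term)[i]))
    out$per_taxon_tests <- tt[order(vapply(tt, `[[`, 0, "p"))]
  }
  structure(out, class = "node_bias_report")
}

#' @export
print.node_bias_report <- function(x, ...) {
  cat("Node-based compositional bias evaluation\n")
  cat("  clade:            ", x$clade_name, " (node ", x$node, ")\n", sep = "")
  cat("  no. of autapomorphies:", x$apomorphy_count, "\n")
  cat(sprintf("  p (clade ancestor):   %.2f%%\n", 100 * x$test_focal$p))
  cat(sprintf("  p (direct ancestor):  %.2f%%\n", 100 * x$test_ancestor$p))
  invisible(x)
}

#' Per-taxon compositional deviation screen
#'
#' Tests every taxon's full-row composition against the pooled
#' composition of the whole alignment, the screen used to flag taxa with
#' strongly deviating composition. Results are sorted by ascending
#' p-value.
#'
#' @param aln an [aa_alignment].
#' @return list of `comp_test`, sorted by p ascending; names are taxon
#'   labels.
#' @export
per_taxon_composition_screen <- function(aln) {
  m <- unclass(aln)
  comps <- lapply(seq_len(nrow(m)), function(i) composition_counts(m[i, ]))
  pool <- Reduce(.comp_add, comps)
  tests <- lapply(seq_along(comps), function(i)
    chi_square_homogeneity(comps[[i]], pool, focal_label = rownames(m)[i]))
  names(tests) <- rownames(m)
  tests[order(vapply(tests, `[[`, 0, "p"))]
}
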