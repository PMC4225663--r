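#' Default amino-acid equilibrium frequencies
#'
#' Typical average proteome composition (values in the range reported for
#' broad protein databases), normalized to sum to 1. Used as the root and
#' background composition of the simulator.
#'
#' @return named numeric vector over [AA_ALPHABET].
#' @export
default_aa_frequencies <- function() {
  f <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
         G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
         M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
         S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)
  f / sum(f)
}

#' Simulation specification
#'
#' Collects the parameters of the nonstationary simulator. Defaults give
#' a small but realistic phylogenomic regime: 16 taxa, 20 gene blocks of
#' 80-160 columns (about 2,400 positions), a Yule tree of unit birth
#' rate, resampling rate 0.3 per unit branch length (expected root-to-tip
#' substitution opportunity of about 0.7 per site, typical of deep
#' phylogenomic supermatrices), a compositional shift
#' of total-variation magnitude `shift_delta` planted on the stem of
#' `shift_clade`, and per-taxon-per-gene block dropout with probability
#' 0.5 (EST-style supermatrices with roughly 50% missing cells
#' concentrated in gene-sized blocks).
#'
#' @param n_taxa number of tips (>= 3).
#' @param n_genes number of gene blocks.
#' @param gene_length_range integer range for gene lengths.
#' @param birth_rate Yule birth rate.
#' @param base_frequencies 20-simplex over [AA_ALPHABET].
#' @param shift_clade tip labels of the clade carrying the shift, or
#'   `NULL` to let the simulator designate a clade of roughly a quarter
#'   of the taxa (also used, with `shift_delta = 0`, as the focal clade
#'   of null benchmarks).
#' @param shift_delta total-variation distance between base and shifted
#'   frequencies (0 = homogeneous null).
#' @param substitution_rate resampling rate per unit branch length.
#' @param missing_block_prob probability a taxon lacks a given gene.
#' @param seed integer seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_taxa = 16L, n_genes = 20L,
                     gene_length_range = c(80L, 160L), birth_rate = 1,
                     base_frequencies = default_aa_frequencies(),
                     shift_clade = NULL, shift_delta = 0.25,
                     substitution_rate = 0.3, missing_block_prob = 0.5,
                     seed = 1L) {
  stopifnot(n_taxa >= 3L, n_genes >= 1L, birth_rate > 0,
            substitution_rate >= 0, shift_delta >= 0,
            missing_block_prob >= 0, missing_block_prob <= 1)
  if (abs(sum(base_frequencies) - 1) > 1e-9)
    stop("base_frequencies must sum to 1")
  structure(list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 birth_rate = birth_rate,
                 base_frequencies = base_frequencies,
                 shift_clade = shift_clade, shift_delta = shift_delta,
                 substitution_rate = substitution_rate,
                 missing_block_prob = missing_block_prob,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a Yule tree
#'
#' Pure-birth tree: starting from the two daughters of the root, each
#' lineage splits at rate `birth_rate`; after the split that reaches
#' `n_taxa` lineages, all pendant branches are extended by a final
#' `Exp(n_taxa * birth_rate)` waiting time so every tip branch is
#' positive. Expected root height is `sum_{k=2}^{n} 1/(k * birth_rate)`.
#' Deterministic given `seed`.
#'
#' @param n_taxa number of tips (>= 3).
#' @param birth_rate per-lineage splitting rate.
#' @param seed integer seed.
#' @return a rooted binary [ape::phylo] with tip labels `t1..tn`.
#' @export
generate_tree <- function(n_taxa, birth_rate = 1, seed = 1L) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  set.seed(as.integer(seed))
  len <- c(0, 0)            # accumulated branch length per created lineage
  kids <- list(NULL, NULL)  # children indices once a lineage splits
  active <- c(1L, 2L)
  k <- 2L
  while (k < n_taxa) {
    t <- stats::rexp(1L, rate = k * birth_rate)
    len[active] <- len[active] + t
    i <- active[sample.int(k, 1L)]
    j <- length(len) + c(1L, 2L)
    len <- c(len, 0, 0)
    kids[[i]] <- j
    kids[j[1L]] <- list(NULL)
    kids[j[2L]] <- list(NULL)
    active <- c(setdiff(active, i), j)
    k <- k + 1L
  }
  t <- stats::rexp(1L, rate = n_taxa * birth_rate)
  len[active] <- len[active] + t

  tip_counter <- 0L
  to_newick <- function(i) {
    if (is.null(kids[[i]])) {
      tip_counter <<- tip_counter + 1L
      sprintf("t%d:%.12g", tip_counter, len[i])
    } else {
      sprintf("(%s,%s):%.12g", to_newick(kids[[i]][1L]),
              to_newick(kids[[i]][2L]), len[i])
    }
  }
  nwk <- sprintf("(%s,%s);", to_newick(1L), to_newick(2L))
  ape::read.tree(text = nwk)
}

# shifted simplex at total-variation distance delta from base, along a
# Dirichlet(1) perturbation direction (drawn from the current RNG
# stream); directions too close to base to realize delta are redrawn
.shifted_frequencies <- function(base, delta) {
  if (delta <= 0) return(base)
  for (i in 1:1000) {
    u <- stats::rexp(length(base))
    u <- u / sum(u)
    tv <- 0.5 * sum(abs(u - base))
    if (tv >= delta) return((1 - delta / tv) * base + (delta / tv) * u)
  }
  stop("cannot realize shift_delta = ", delta, " by simplex mixing")
}

.tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# default designated clade: internal node whose tip count is closest to
# n/4 (ties: deepest preorder first), never the root or a child subtree
# spanning >= n-1 tips
.pick_focal_clade <- function(phy) {
  nt <- n_tips(phy)
  target <- max(2L, round(nt / 4))
  cand <- setdiff(unique(phy$edge[, 1L]), root_node(phy))
  sizes <- vapply(cand, function(v) length(tips_under(phy, v)), 0L)
  ok <- sizes >= 2L & sizes <= nt - 2L
  cand <- cand[ok]; sizes <- sizes[ok]
  cand[order(abs(sizes - target), cand)][1L]
}

#' Simulate a nonstationary amino-acid alignment on a tree
#'
#' Root sequence drawn from `base_frequencies`; along each branch of
#' length `t`, each site independently keeps its state with probability
#' `exp(-rate * t)` and is otherwise redrawn from the branch's
#' equilibrium frequencies (an F81-style process, adequate because the
#' downstream diagnostics test composition, not exchangeabilities). On
#' the stem branch of the shift clade and on all branches inside it the
#' equilibrium frequencies switch to the shifted simplex, making the
#' process nonstationary in composition.
#'
#' @param phy a rooted binary [ape::phylo] (e.g. from [generate_tree()]).
#' @param spec a [sim_spec()]. `spec$n_taxa` must match the tree.
#' @return list with `alignment` (an [aa_alignment], no missing data yet),
#'   `truth` (a `truth_record` list: tree, shifted node and tips, base and
#'   shifted frequencies, realized TV distance, ancestral state matrix,
#'   gene boundaries, spec and seed).
#' @export
simulate_alignment <- function(phy, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (n_tips(phy) != spec$n_taxa)
    stop("tree tip count does not match spec$n_taxa")
  set.seed(spec$seed + 1L)
  S <- length(AA_ALPHABET)
  glens <- if (spec$gene_length_range[1L] == spec$gene_length_range[2L])
    rep(spec$gene_length_range[1L], spec$n_genes)
  else
    sample(spec$gene_length_range[1L]:spec$gene_length_range[2L],
           spec$n_genes, replace = TRUE)
  nc <- sum(glens)
  gene_end <- cumsum(glens)
  gene_start <- c(1L, gene_end[-spec$n_genes] + 1L)

  if (is.null(spec$shift_clade) || length(spec$shift_clade) == 0L) {
    shift_node <- .pick_focal_clade(phy)
    shift_tips <- tips_under(phy, shift_node)
  } else {
    shift_tips <- spec$shift_clade
    res <- resolve_clade(phy, clade_spec("shift", shift_tips))
    if (!res$monophyletic)
      stop("shift_clade is not monophyletic on the tree")
    shift_node <- res$node
    if (shift_node == root_node(phy))
      stop("shift_clade must not span the whole tree")
  }
  pi_base <- spec$base_frequencies
  pi_shift <- .shifted_frequencies(pi_base, spec$shift_delta)

  # branches inside the shifted clade (stem included)
  in_shift <- rep(FALSE, max(phy$edge))
  in_shift[shift_node] <- TRUE
  pre <- .preorder_nodes(phy)
  par <- .parent_vec(phy)
  for (i in seq_len(nrow(phy$edge))) {
    v <- phy$edge[i, 2L]
    if (!in_shift[v] && in_shift[par[v]]) in_shift[v] <- TRUE
  }
  # edge table is not guaranteed preorder; propagate until fixed point
  repeat {
    new <- in_shift | (!is.na(par) & in_shift[ifelse(is.na(par), 1L, par)])
    new[shift_node] <- TRUE
    new[root_node(phy)] <- FALSE
    if (identical(new, in_shift)) break
    in_shift <- new
  }
  in_shift[shift_node] <- TRUE

  states <- matrix(NA_integer_, max(phy$edge), nc)
  rt <- root_node(phy)
  states[rt, ] <- sample.int(S, nc, replace = TRUE, prob = pi_base)
  post <- ape::reorder.phylo(phy, "postorder")
  edges <- post$edge
  el <- post$edge.length
  for (i in rev(seq_len(nrow(edges)))) {  # preorder traversal
    p <- edges[i, 1L]; v <- edges[i, 2L]
    t <- el[i]
    freq <- if (in_shift[v]) pi_shift else pi_base
    keep <- stats::runif(nc) < exp(-spec$substitution_rate * t)
    child <- states[p, ]
    nres <- sum(!keep)
    if (nres > 0L)
      child[!keep] <- sample.int(S, nres, replace = TRUE, prob = freq)
    states[v, ] <- child
  }
  mat <- matrix(AA_ALPHABET[states[seq_len(n_tips(phy)), ]],
                n_tips(phy), nc)
  rownames(mat) <- phy$tip.label
  aln <- aa_alignment(mat)
  truth <- structure(list(
    tree = ape::write.tree(phy),
    shift_node = shift_node,
    shift_tips = shift_tips,
    base_frequencies = pi_base,
    shifted_frequencies = pi_shift,
    realized_tv = .tv_distance(pi_base, pi_shift),
    ancestral_states = states[(n_tips(phy) + 1L):max(phy$edge), ,
                              drop = FALSE],
    gene_start = gene_start, gene_end = gene_end,
    spec = unclass(spec), seed = spec$seed), class = "truth_record")
  list(alignment = aln, truth = truth)
}

#' Inject gene-block missingness
#'
#' For every taxon and every gene block, the whole block is set to
#' missing with probability `missing_block_prob` (block dropout, not
#' per-cell erosion, reproducing the taxon-clustered missingness
#' structure that overlap clustering is designed to detect).
#'
#' @param aln an [aa_alignment].
#' @param gene_start,gene_end 1-based inclusive gene boundaries
#'   partitioning the columns.
#' @param missing_block_prob dropout probability in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `alignment`, `mask` (taxa x genes logical, TRUE =
#'   dropped), `realized_coverage` (percent observed cells).
#' @export
inject_missingness <- function(aln, gene_start, gene_end,
                               missing_block_prob, seed = 1L) {
  if (missing_block_prob < 0 || missing_block_prob > 1)
    stop("missing_block_prob must be in [0, 1]")
  stopifnot(length(gene_start) == length(gene_end),
            gene_start[1L] == 1L,
            all(gene_end >= gene_start),
            gene_end[length(gene_end)] == n_columns(aln))
  set.seed(as.integer(seed) + 2L)
  ng <- length(gene_start)
  mask <- matrix(stats::runif(n_taxa(aln) * ng) < missing_block_prob,
                 n_taxa(aln), ng,
                 dimnames = list(taxon_labels(aln), NULL))
  m <- unclass(aln)
  for (g in seq_len(ng)) {
    drop <- which(mask[, g])
    if (length(drop)) m[drop, gene_start[g]:gene_end[g]] <- NA_character_
  }
  out <- m
  class(out) <- c("aa_alignment", "matrix", "array")
  list(alignment = out, mask = mask,
       realized_coverage = 100 * mean(!is.na(out)))
}

#' One-call benchmark generation
#'
#' Runs tree generation, sequence simulation and missingness injection
#' for a named preset and (optionally) writes alignment, tree, truth
#' record and gene-boundary table to disk. Presets:
#' \describe{
#'   \item{null_homogeneous}{default regime with `shift_delta = 0`; the
#'     designated focal clade is recorded in the truth record.}
#'   \item{planted_shift}{default regime, TV shift 0.25 on the focal
#'     stem.}
#'   \item{planted_block_missing}{no compositional shift; one gene block
#'     is additionally dropped from all tips of the focal clade, planting
#'     a shared-missingness cluster.}
#'   \item{paperlike}{58 taxa, 196 genes of 100-320 columns (about
#'     41,000 positions), block dropout 0.5 (about 50% coverage), TV
#'     shift 0.2.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param outdir optional directory; when given, writes
#'   `alignment.fasta`, `tree.nwk`, `truth.json` and `genes.tsv`
#'   (columns gene, start, end; half-open 0-based).
#' @return list with `alignment`, `tree`, `truth`, `mask`,
#'   `realized_coverage` (invisibly if `outdir` is given).
#' @export
make_benchmark <- function(name = c("null_homogeneous", "planted_shift",
                                    "planted_block_missing", "paperlike"),
                           seed = 1L, outdir = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    null_homogeneous = sim_spec(shift_delta = 0, seed = seed),
    planted_shift = sim_spec(shift_delta = 0.25, seed = seed),
    planted_block_missing = sim_spec(shift_delta = 0,
                                     missing_block_prob = 0.3,
                                     seed = seed),
    paperlike = sim_spec(n_taxa = 58L, n_genes = 196L,
                         gene_length_range = c(100L, 320L),
                         shift_delta = 0.2, seed = seed))
  phy <- generate_tree(spec$n_taxa, spec$birth_rate, seed = spec$seed)
  sim <- simulate_alignment(phy, spec)
  inj <- inject_missingness(sim$alignment, sim$truth$gene_start,
                            sim$truth$gene_end, spec$missing_block_prob,
                            seed = spec$seed)
  aln <- inj$alignment
  mask <- inj$mask
  if (name == "planted_block_missing") {
    # force the focal clade to share a run of absent gene blocks (a
    # quarter of the columns), on top of the lighter 0.3 background
    # dropout, so the planted overlap stands out from random sharing
    gset <- seq_len(max(1L, spec$n_genes %/% 4L))
    tips <- sim$truth$shift_tips
    m <- unclass(aln)
    for (g in gset)
      m[tips, sim$truth$gene_start[g]:sim$truth$gene_end[g]] <- NA_character_
    class(m) <- c("aa_alignment", "matrix", "array")
    aln <- m
    mask[tips, gset] <- TRUE
  }
  truth <- sim$truth
  truth$missing_mask <- mask
  out <- list(alignment = aln, tree = phy, truth = truth, mask = mask,
              realized_coverage = 100 * mean(!is.na(unclass(aln))))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_alignment(aln, file.path(outdir, "alignment.fasta"))
    write_tree(phy, file.path(outdir, "tree.nwk"))
    tj <- unclass(truth)
    tj$ancestral_states <- apply(tj$ancestral_states, 1L, function(r)
      paste(AA_ALPHABET[r], collapse = ""))
    tj$missing_mask <- apply(mask, 1L, function(r)
      paste(as.integer(r), collapse = ""))
    jsonlite::write_json(tj, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    genes <- data.frame(gene = sprintf("g%03d", seq_along(truth$gene_start)),
                        start = truth$gene_start - 1L,
                        end = truth$gene_end)
    utils::write.table(genes, file.path(outdir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
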