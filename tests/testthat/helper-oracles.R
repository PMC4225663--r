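# Independent oracles used across the suite. These stay deliberately
# dumb: exhaustive enumeration and direct formula transcription, never
# sharing code with the implementation they check.

# random rooted tree with ape, deterministic
rand_rooted_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}

# random alignment over a limited state set with missing cells
rand_alignment <- function(n_taxa, n_cols, seed, n_states = 6L,
                           p_missing = 0.2) {
  set.seed(seed)
  states <- AA_ALPHABET[seq_len(n_states)]
  m <- matrix(sample(states, n_taxa * n_cols, replace = TRUE),
              n_taxa, n_cols)
  m[matrix(runif(n_taxa * n_cols) < p_missing, n_taxa, n_cols)] <- NA
  rownames(m) <- paste0("t", seq_len(n_taxa))
  class(m) <- c("aa_alignment", "matrix", "array")
  m
}

# Exhaustive parsimony oracle for one column: enumerate every assignment
# of observed states to the internal nodes; returns the minimum change
# count and all optimal assignments (columns = internal nodes in id
# order). Missing tips are unconstrained (their terminal edge costs 0).
enum_parsimony <- function(phy, tip_states) {
  nt <- length(phy$tip.label)
  internal <- (nt + 1L):max(phy$edge)
  obs <- sort(unique(tip_states[!is.na(tip_states)]))
  if (length(obs) == 0L)
    return(list(min = 0L, assignments = NULL))
  grid <- as.matrix(expand.grid(rep(list(obs), length(internal)),
                                KEEP.OUT.ATTRS = FALSE))
  cost <- integer(nrow(grid))
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    sp <- if (p <= nt) rep(tip_states[p], nrow(grid)) else grid[, p - nt]
    sv <- if (v <= nt) rep(tip_states[v], nrow(grid)) else grid[, v - nt]
    cost <- cost + (!is.na(sp) & !is.na(sv) & sp != sv)
  }
  mn <- min(cost)
  list(min = mn, assignments = grid[cost == mn, , drop = FALSE])
}

# is a (possibly NA-containing) internal assignment consistent with some
# enumerated most-parsimonious assignment?
is_mpr_member <- function(enum, internal_states) {
  if (is.null(enum$assignments)) return(all(is.na(internal_states)))
  ok <- rep(TRUE, nrow(enum$assignments))
  for (j in seq_along(internal_states)) {
    if (is.na(internal_states[j])) next
    ok <- ok & enum$assignments[, j] == internal_states[j]
  }
  any(ok)
}

# KS oracle: stats::ks.test against the uniform on (0, 1]
ks_oracle <- function(positions, n_columns) {
  suppressWarnings(unname(
    stats::ks.test(positions / n_columns, "punif")$statistic))
}

# chi-square upper-tail oracle by numerical integration
chisq_upper_oracle <- function(x, df) {
  if (x <= 0) return(1)
  stats::integrate(function(t) stats::dchisq(t, df), x, Inf,
                   rel.tol = 1e-10)$value
}

# tiny alignment from named sequence strings
toy_aln <- function(...) aa_alignment(c(...))
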