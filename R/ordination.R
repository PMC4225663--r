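#' Compositional distance matrix between taxa
#'
#' Pairwise distance `d(i,j) = 1/2 * sum_a (c_i(a) - c_j(a))^2`, where
#' `c_i(a)` is the count of residue `a` in taxon i's row (missing cells
#' skipped). By default the distance operates on raw counts, so rows with
#' very different numbers of observed residues can dominate; set
#' `normalize = TRUE` to use relative frequencies instead.
#'
#' @param aln an [aa_alignment] with at least 2 taxa.
#' @param normalize use per-row frequencies rather than raw counts.
#' @return symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
compositional_distance_matrix <- function(aln, normalize = FALSE) {
  if (n_taxa(aln) < 2L) stop("need at least 2 taxa")
  m <- unclass(aln)
  C <- t(vapply(seq_len(nrow(m)),
                function(i) as.numeric(composition_counts(m[i, ])),
                numeric(length(AA_ALPHABET))))
  if (normalize) {
    tot <- rowSums(C)
    tot[tot == 0] <- 1
    C <- C / tot
  }
  G <- tcrossprod(C)
  sq <- diag(G)
  d <- 0.5 * (outer(sq, sq, "+") - 2 * G)
  d[d < 0] <- 0  # numeric guard
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# Kruskal primary-tie monotone (isotonic) regression of configuration
# distances delta on the rank order of the dissimilarities d: order pairs
# by (d, delta) so tied dissimilarities are free to follow the current
# configuration, then pool adjacent violators (stats::isoreg).
.disparities <- function(dvec, delta) {
  ord <- order(dvec, delta)
  fit <- stats::isoreg(delta[ord])$yf
  out <- numeric(length(delta))
  out[ord] <- fit
  out
}

.stress1 <- function(delta, dhat) sqrt(sum((delta - dhat)^2) / sum(delta^2))

# one SMACOF run from a given start; stops when stress-1 improves by less
# than tol (the update that fails to improve is discarded, so the stress
# trace is non-increasing by construction)
.nmds_once <- function(d, X, max_iter = 500L, tol = 1e-7) {
  n <- nrow(X)
  lower <- lower.tri(d)
  dvec <- d[lower]
  cfg_dist <- function(X) as.matrix(stats::dist(X))
  D <- cfg_dist(X)
  delta <- D[lower]
  dhat <- .disparities(dvec, delta)
  stress <- .stress1(delta, dhat)
  trace <- stress
  for (it in seq_len(max_iter)) {
    # Guttman transform with current disparities
    Dhat <- matrix(0, n, n)
    Dhat[lower] <- dhat
    Dhat <- Dhat + t(Dhat)
    W <- D
    B <- ifelse(W > 0, -Dhat / pmax(W, .Machine$double.eps), 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n
    Dn <- cfg_dist(Xn)
    deltan <- Dn[lower]
    dhatn <- .disparities(dvec, deltan)
    stressn <- .stress1(deltan, dhatn)
    if (!is.finite(stressn) || stressn > stress - tol) {
      if (is.finite(stressn) && stressn < stress) {
        X <- Xn; D <- Dn; delta <- deltan; dhat <- dhatn
        stress <- stressn; trace <- c(trace, stressn)
      }
      break
    }
    X <- Xn; D <- Dn; delta <- deltan; dhat <- dhatn
    stress <- stressn
    trace <- c(trace, stressn)
  }
  list(coords = X, stress = stress, trace = trace)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal
#' stress-1, `sqrt(sum((delta - dhat)^2) / sum(delta^2))`, where `dhat`
#' is the primary-tie isotonic fit of the configuration distances `delta`
#' to the rank order of the input dissimilarities. Optimization is
#' iterative majorization (SMACOF) with disparities refreshed every
#' iteration; the first start is the classical-scaling configuration, the
#' remaining restarts are random. Deterministic given `(seed,
#' n_restarts)`.
#'
#' @param d symmetric dissimilarity matrix (e.g. from
#'   [compositional_distance_matrix()]).
#' @param k embedding dimension, `< nrow(d)`.
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of starts (first is classical scaling).
#' @param max_iter,tol per-run convergence controls.
#' @return An `nmds_embedding`: list with `coords` (n x k, rownames =
#'   labels), `stress`, `stress_trace` (best run), `seed`, `n_restarts`.
#' @export
nmds <- function(d, k = 2L, seed = 1L, n_restarts = 50L,
                 max_iter = 500L, tol = 1e-7) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of objects")
  if (all(d[lower.tri(d)] == 0)) stop("all dissimilarities are zero")
  labels <- rownames(d)
  best <- NULL
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts)) {
    X0 <- if (r == 1L) {
      cmd <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k))
      if (ncol(cmd) < k)
        cmd <- cbind(cmd, matrix(0, n, k - ncol(cmd)))
      cmd + matrix(stats::rnorm(n * k, sd = 1e-8), n, k)
    } else {
      matrix(stats::rnorm(n * k), n, k)
    }
    run <- .nmds_once(d, X0, max_iter = max_iter, tol = tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  coords <- best$coords
  rownames(coords) <- labels
  structure(list(coords = coords, stress = best$stress,
                 stress_trace = best$trace, seed = seed,
                 n_restarts = n_restarts),
            class = "nmds_embedding")
}

#' @export
print.nmds_embedding <- function(x, ...) {
  cat("nmds_embedding: ", nrow(x$coords), " objects in ",
      ncol(x$coords), " dimensions, stress-1 = ",
      formatC(x$stress, digits = 5, format = "g"), "\n", sep = "")
  invisible(x)
}

#' Scatter plot of an NMDS embedding with optional group hulls
#'
#' @param x an `nmds_embedding`.
#' @param groups optional named factor/character vector (names = labels).
#' @param ... passed to [graphics::plot()].
#' @export
plot.nmds_embedding <- function(x, groups = NULL, ...) {
  co <- x$coords
  graphics::plot(co[, 1L], co[, 2L], xlab = "NMDS1", ylab = "NMDS2",
                 main = sprintf("NMDS (stress-1 = %.4f)", x$stress), ...)
  if (!is.null(groups)) {
    g <- factor(groups[rownames(co)])
    cols <- seq_along(levels(g)) + 1L
    graphics::points(co[, 1L], co[, 2L], col = cols[as.integer(g)],
                     pch = 19)
    for (lv in seq_along(levels(g))) {
      pts <- co[as.integer(g) == lv, , drop = FALSE]
      if (nrow(pts) >= 3L) {
        h <- grDevices::chull(pts)
        graphics::polygon(pts[h, 1L], pts[h, 2L], border = cols[lv])
      }
    }
    graphics::legend("topright", legend = levels(g), col = cols, pch = 19,
                     bty = "n")
  } else {
    graphics::text(co[, 1L], co[, 2L], labels = rownames(co), pos = 3,
                   cex = 0.7)
  }
  invisible(x)
}
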