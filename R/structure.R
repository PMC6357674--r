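# Population-structure machinery: centered-crossproduct genomic relationship
# matrix, its eigendecomposition as PCA, Euclidean genotype distances,
# neighbor-joining clustering, and PC-geography correlations.

#' Genomic relationship matrix
#'
#' Centered-score relationship (VanRaden-style): over polymorphic sites k
#' with alternate-allele frequency `p_k`, `W` holds `dosage - 2 p_k` with
#' missing calls imputed at the site mean `2 p_k`, and
#' `A = W W' / (2 sum p_k (1 - p_k))`.
#'
#' @param gm `geno_matrix`.
#' @return Symmetric n x n matrix with sample ids as dimnames and the number
#'   of polymorphic sites used as attribute `n_sites_used`.
#' @export
relationship_matrix <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (n_samples(gm) < 2) stop("need at least 2 samples")
  af <- .allele_freq(gm$calls)
  poly <- !is.na(af$freq) & af$freq > 0 & af$freq < 1
  if (!any(poly)) stop("no polymorphic sites")
  p <- af$freq[poly]
  X <- gm$calls[, poly, drop = FALSE]
  W <- sweep(X, 2, 2 * p)
  W[is.na(W)] <- 0  # missing imputed at the site mean
  A <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  attr(A, "n_sites_used") <- sum(poly)
  A
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition of the symmetric relationship matrix; sample scores are
#' eigenvectors scaled by the square root of their (non-negative part of the)
#' eigenvalue, and `variance_explained_i = lambda_i / sum(max(lambda_j, 0))`.
#'
#' @param A Symmetric relationship matrix (e.g. [relationship_matrix()]).
#' @param n_components Number of leading components to report.
#' @return List with `eigenvalues` (descending), `scores` (n x k, columns
#'   `PC1..PCk`), `vectors` (raw eigenvectors) and `variance_explained`.
#' @export
relationship_pca <- function(A, n_components = 3) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8) {
    stop("relationship matrix must be symmetric")
  }
  ee <- eigen((A + t(A)) / 2, symmetric = TRUE)
  k <- min(n_components, ncol(A))
  lam <- ee$values
  scores <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(lam[seq_len(k)], 0)), k)
  dimnames(scores) <- list(rownames(A), paste0("PC", seq_len(k)))
  vectors <- ee$vectors[, seq_len(k), drop = FALSE]
  dimnames(vectors) <- dimnames(scores)
  list(eigenvalues = lam, scores = scores, vectors = vectors,
       variance_explained = lam[seq_len(k)] / sum(pmax(lam, 0)))
}

#' Euclidean genotype distances with missing-data rescaling
#'
#' Pairwise-complete Euclidean distance over dosages:
#' `d(i, j) = sqrt((m / m_obs) * sum over co-non-missing sites (x_i - x_j)^2)`
#' where `m` is the total site count and `m_obs` the number of co-observed
#' sites for the pair — the conventional behaviour of the base distance
#' routine, which without the rescaling would bias missing-heavy pairs short.
#'
#' @param gm `geno_matrix`.
#' @return A `stats::dist` object.
#' @export
euclidean_distance <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (n_samples(gm) < 2) stop("need at least 2 samples")
  d <- stats::dist(gm$calls, method = "euclidean")
  if (anyNA(d)) {
    dm <- as.matrix(d)
    bad <- which(is.na(dm) & upper.tri(dm), arr.ind = TRUE)[1, ]
    stop("no co-observed sites for sample pair ",
         rownames(dm)[bad[1]], " / ", colnames(dm)[bad[2]])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining; negative branch lengths (a known NJ artifact)
#' are clamped to zero with the count recorded as attribute
#' `n_clamped_edges`.
#'
#' @param D `dist` object or symmetric distance matrix with labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!inherits(D, "dist")) D <- stats::as.dist(as.matrix(D))
  if (attr(D, "Size") < 3) stop("neighbor joining needs at least 3 samples")
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    warning("clamped ", sum(neg), " negative branch length(s) to zero")
    tr$edge.length[neg] <- 0
  }
  attr(tr, "n_clamped_edges") <- sum(neg)
  tr
}

#' Write a tree in Newick format
#' @param tree `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Correlations between principal components and geography
#'
#' Pearson correlations, pairwise-complete, between the requested PC scores
#' and passport longitude / latitude / altitude.
#'
#' @param pca Result of [relationship_pca()].
#' @param passport Passport data frame ([read_passport()]).
#' @param components Integer vector of components (default 2 and 3, the
#'   within-lineage axes once PC1 has absorbed the lineage split).
#' @param samples Optional sample ids to restrict to (e.g. one lineage).
#' @return Data frame with `component`, `variable`, `r` and `n` (complete
#'   pairs); fewer than 3 complete pairs gives `NA` with a warning.
#' @export
pc_geo_correlation <- function(pca, passport, components = c(2, 3),
                               samples = NULL) {
  scores <- pca$scores
  samples <- samples %||% rownames(scores)
  scores <- scores[intersect(samples, rownames(scores)), , drop = FALSE]
  idx <- match(rownames(scores), passport$id)
  out <- list()
  for (comp in components) {
    if (comp > ncol(scores)) stop("component ", comp, " not available")
    for (v in c("longitude", "latitude", "altitude")) {
      x <- scores[, comp]
      y <- passport[[v]][idx]
      ok <- !is.na(x) & !is.na(y)
      r <- if (sum(ok) >= 3) stats::cor(x[ok], y[ok]) else {
        warning("fewer than 3 complete pairs for PC", comp, " vs ", v)
        NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(component = comp, variable = v,
                                            r = r, n = sum(ok))
    }
  }
  do.call(rbind, out)
}
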