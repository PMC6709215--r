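as_weights <- function(C) {
  W <- if (inherits(C, "connectivity_matrix")) C$weights else as.matrix(C)
  if (nrow(W) != ncol(W)) stop("connectivity matrix must be square")
  W
}

#' Weighted degree imbalance per node
#'
#' For each node i, weighted outdegree minus weighted indegree,
#' `sum_j c_ij - sum_j c_ji`. A positive imbalance marks a "source" node
#' whose signal temporally leads others; negative marks a "sink". Over any
#' matrix the imbalances sum to zero.
#'
#' @param C A `connectivity_matrix` or square numeric matrix with zero
#'   diagonal.
#' @return data.frame with `node`, `outdegree_w`, `indegree_w`,
#'   `degree_imbalance`.
#' @export
degree_imbalance <- function(C) {
  W <- as_weights(C)
  data.frame(node = seq_len(nrow(W)),
             outdegree_w = rowSums(W),
             indegree_w = colSums(W),
             degree_imbalance = rowSums(W) - colSums(W))
}

pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Degree of asymmetry of a directed weighted graph
#'
#' Largest-modulus eigenvalue (the spectral norm) of the skew-symmetric part
#' `(L - t(L)) / 2` of the out-degree Laplacian `L = D_out - W`. Because the
#' diagonal cancels, this equals the spectral norm of `(t(W) - W) / 2`; it
#' is zero exactly when the weight matrix is symmetric, and is invariant
#' under adding any symmetric matrix to `W`.
#'
#' @inheritParams degree_imbalance
#' @return Nonnegative scalar.
#' @export
degree_of_asymmetry <- function(C) {
  W <- as_weights(C)
  S <- (t(W) - W) / 2
  if (all(S == 0)) return(0)
  norm(S, type = "2")
}

#' Battery of global network measures
#'
#' Computes 20 scalar summaries of a nonnegative directed weighted network:
#' mean/variance of weighted outdegree; spectral and Frobenius norms;
#' mean/variance of neighbor weighted outdegree (weighted mean of
#' out-neighbors' outdegrees, weights = edge weights; nodes without
#' out-edges excluded); mean/variance of betweenness, PageRank (damping
#' 0.85), shortest path length and harmonic closeness (path measures use
#' edge length 1/weight; unreachable pairs contribute 0 to harmonic
#' closeness and are excluded from path means); assortative mixing (Pearson
#' correlation over edges of source vs target total weighted degree);
#' s-metric (sum over edges of the product of endpoint total degrees);
#' degree of asymmetry; and mean/variance/max of the spectrum of the
#' symmetric part of the Laplacian. Variances are population variances.
#'
#' @inheritParams degree_imbalance
#' @return Named numeric vector of length 20; path-based entries are `NA`
#'   when undefined (e.g. an edgeless matrix).
#' @export
global_measures <- function(C) {
  W <- as_weights(C)
  if (any(W < 0)) stop("global measures assume nonnegative weights")
  n <- nrow(W)
  outd <- rowSums(W); ind <- colSums(W); totd <- outd + ind
  edges <- which(W > 0, arr.ind = TRUE)

  # neighbor weighted outdegree
  nbr <- vapply(seq_len(n), function(i) {
    w <- W[i, ]
    if (sum(w) == 0) return(NA_real_)
    sum(w * outd) / sum(w)
  }, numeric(1))

  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  has_edges <- igraph::ecount(g) > 0
  inv_w <- if (has_edges) 1 / igraph::E(g)$weight else numeric(0)
  btw <- if (has_edges) igraph::betweenness(g, directed = TRUE,
                                            weights = inv_w)
         else rep(NA_real_, n)
  pr <- igraph::page_rank(g, damping = 0.85,
                          weights = if (has_edges) igraph::E(g)$weight
                                    else NULL)$vector
  D <- if (has_edges) igraph::distances(g, mode = "out", weights = inv_w)
       else matrix(Inf, n, n)
  offd <- D[row(D) != col(D)]
  spl <- offd[is.finite(offd)]
  harm <- rowSums(ifelse(is.finite(D) & row(D) != col(D), 1 / D, 0)) /
    max(1, n - 1)

  assort <- if (nrow(edges) >= 2) {
    s <- totd[edges[, 1]]; t <- totd[edges[, 2]]
    if (stats::sd(s) == 0 || stats::sd(t) == 0) NA_real_ else stats::cor(s, t)
  } else NA_real_
  smet <- if (nrow(edges)) sum(totd[edges[, 1]] * totd[edges[, 2]]) else 0

  Lap <- diag(outd) - W
  sym_spec <- eigen((Lap + t(Lap)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values

  c(mean_outdegree = mean(outd),
    var_outdegree = pop_var(outd),
    spectral_norm = if (all(W == 0)) 0 else norm(W, type = "2"),
    frobenius_norm = norm(W, type = "F"),
    mean_neighbor_outdegree = if (all(is.na(nbr))) NA_real_
                              else mean(nbr, na.rm = TRUE),
    var_neighbor_outdegree = pop_var(nbr),
    mean_betweenness = mean(btw),
    var_betweenness = pop_var(btw),
    mean_pagerank = mean(pr),
    var_pagerank = pop_var(pr),
    mean_shortest_path = if (length(spl)) mean(spl) else NA_real_,
    var_shortest_path = if (length(spl)) pop_var(spl) else NA_real_,
    mean_harmonic_closeness = mean(harm),
    var_harmonic_closeness = pop_var(harm),
    assortative_mixing = assort,
    s_metric = smet,
    degree_of_asymmetry = degree_of_asymmetry(W),
    mean_laplacian_sym_spectrum = mean(sym_spec),
    var_laplacian_sym_spectrum = pop_var(sym_spec),
    max_laplacian_sym_spectrum = max(sym_spec))
}

#' Frobenius distance between two matrices
#'
#' `sqrt(sum((A - B)^2))` over all elements: the matrix-space metric used to
#' compare connectivity matrices across recordings and days.
#'
#' @param A,B Matrices (or `connectivity_matrix` objects) of equal shape.
#' @return Nonnegative scalar, 0 iff `A == B`.
#' @export
frobenius_distance <- function(A, B) {
  A <- if (inherits(A, "connectivity_matrix")) A$weights else as.matrix(A)
  B <- if (inherits(B, "connectivity_matrix")) B$weights else as.matrix(B)
  if (!identical(dim(A), dim(B))) stop("shape mismatch")
  sqrt(sum((A - B)^2))
}

#' Classical (Torgerson) MDS embedding of a distance matrix
#'
#' Double-centers the squared distances and eigendecomposes, keeping the
#' top-`k` positive-eigenvalue axes. The goodness of the embedding is the
#' Pearson correlation R between the input distances and the pairwise
#' Euclidean distances of the embedded points.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param k Embedding dimension (default 3; reduced if fewer positive
#'   eigenvalues exist).
#' @return Object of class `embedding_result`: `coordinates` (items x k),
#'   `R`, `R2`, `eigenvalues`.
#' @export
mds_embed <- function(D, k = 3) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  stopifnot(all(D >= 0), all(abs(diag(D)) < 1e-12))
  fit <- stats::cmdscale(D, k = min(k, nrow(D) - 1), eig = TRUE)
  X <- fit$points
  if (is.null(dim(X)) || ncol(X) == 0)
    stop("no positive eigenvalues: nothing to embed")
  emb <- as.matrix(dist(X))
  lower <- lower.tri(D)
  R <- if (stats::sd(D[lower]) == 0 || stats::sd(emb[lower]) == 0) {
    # constant distances: correlation is undefined; a configuration that
    # reproduces them exactly is a perfect embedding
    if (max(abs(D[lower] - emb[lower])) <= 1e-8 * max(D, 1)) 1 else NA_real_
  } else stats::cor(D[lower], emb[lower])
  structure(list(coordinates = X, R = R, R2 = R^2, eigenvalues = fit$eig),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result> ", nrow(x$coordinates), " items in ",
      ncol(x$coordinates), "-D; R = ", round(x$R, 4),
      " (R^2 = ", round(x$R2, 4), ")\n", sep = "")
  invisible(x)
}

#' Strongest percentage of directed connections
#'
#' Returns the `ceiling(pct/100 * n*(n-1))` largest off-diagonal weights as
#' an edge list. Zero-weight connections are never returned; ties are broken
#' by (source, target) index order.
#'
#' @inheritParams degree_imbalance
#' @param pct Percentage of the `n*(n-1)` possible directed connections
#'   (default 5).
#' @return data.frame with `source`, `target`, `weight`, sorted by
#'   decreasing weight.
#' @export
top_edges <- function(C, pct = 5) {
  stopifnot(pct > 0, pct <= 100)
  W <- as_weights(C)
  n <- nrow(W)
  k <- ceiling(pct / 100 * n * (n - 1))
  idx <- which(row(W) != col(W) & W > 0, arr.ind = TRUE)
  el <- data.frame(source = idx[, 1], target = idx[, 2],
                   weight = W[idx])
  el <- el[order(-el$weight, el$source, el$target), , drop = FALSE]
  rownames(el) <- NULL
  head(el, k)
}

#' Fraction of contralateral connections among the strongest edges
#'
#' Each node has one directed connection to its mirror-image (contralateral)
#' electrode. This returns the fraction of those `n` connections that appear
#' in the strongest `pct` percent of all connections ([top_edges()]). In a
#' mirror-symmetric network this fraction is high; focal symmetry breaking
#' pulls it down.
#'
#' @inheritParams degree_imbalance
#' @param layout An `electrode_layout` providing the pairing.
#' @param pct Percentage passed to [top_edges()].
#' @return Fraction in [0, 1].
#' @export
contralateral_top_fraction <- function(C, layout, pct = 5) {
  W <- as_weights(C)
  pair <- layout$contralateral_pair
  if (length(pair) != nrow(W) || anyNA(pair))
    stop("layout pairing undefined for this matrix")
  te <- top_edges(W, pct)
  in_top <- paste(te$source, te$target) |> unique()
  mean(paste(seq_len(nrow(W)), pair) %in% in_top)
}

#' Elementwise median of a list of matrices
#'
#' @param matrices Non-empty list of equal-shape matrices (or
#'   `connectivity_matrix` objects).
#' @return Matrix of elementwise medians.
#' @export
median_matrix <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  Ws <- lapply(matrices, function(m)
    if (inherits(m, "connectivity_matrix")) m$weights else as.matrix(m))
  d <- dim(Ws[[1]])
  if (!all(vapply(Ws, function(w) identical(dim(w), d), logical(1))))
    stop("shape mismatch")
  arr <- array(unlist(Ws), dim = c(d, length(Ws)))
  apply(arr, c(1, 2), stats::median)
}
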