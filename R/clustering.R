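# Hierarchical clustering of SR profiles, Cluster 3.0 style.
#
# Reimplements the relevant slice of Eisen's Cluster 3.0: gene-wise
# distances (uncentered correlation by default), agglomerative
# average-linkage tree building, and CDT/GTR output readable by Java
# TreeView. The tree is represented like stats::hclust (merge matrix with
# negative leaf codes, non-decreasing heights) plus the induced leaf order.

#' Pairwise distance matrix over SR profiles
#'
#' @param srt an [sr_table].
#' @param genes genes to include (default: all in `srt`); order is kept.
#' @param metric `"uncentered"` (Cluster 3.0 default; 1 - uncentered
#'   correlation `sum(xy)/sqrt(sum(x^2) sum(y^2))`), `"centered"`
#'   (1 - Pearson correlation) or `"euclidean"`.
#' @return symmetric matrix with zero diagonal, dimnames = genes.
#' @export
sr_distance_matrix <- function(srt, genes = NULL,
                               metric = c("uncentered", "centered", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(srt, "sr_table"))
  if (is.null(genes)) genes <- srt$genes
  if (length(genes) < 2L)
    tsr_stop("need at least 2 genes to build a distance matrix", "invalid_config")
  x <- srt$sr[genes, , drop = FALSE]
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(x, method = "euclidean")),
    centered = {
      v <- apply(x, 1L, stats::sd)
      if (any(v == 0))
        tsr_stop(paste0("zero-variance SR vector under centered correlation: ",
                        paste(genes[v == 0], collapse = ", ")),
                 "undefined_distance")
      1 - stats::cor(t(x))
    },
    uncentered = {
      nrm <- sqrt(rowSums(x^2))
      if (any(nrm == 0))
        tsr_stop(paste0("all-zero SR vector under uncentered correlation: ",
                        paste(genes[nrm == 0], collapse = ", ")),
                 "undefined_distance")
      1 - tcrossprod(x / nrm)
    })
  diag(d) <- 0
  d[d < 0] <- 0   # clip correlation round-off below zero
  dimnames(d) <- list(genes, genes)
  d
}

#' Agglomerative average-linkage tree
#'
#' Standard UPGMA agglomeration on a precomputed distance matrix: repeatedly
#' join the two closest clusters, with inter-cluster distance the
#' size-weighted mean of member distances. Ties are broken deterministically
#' towards the pair containing the smallest original leaf index.
#'
#' @param dist symmetric numeric distance matrix with zero diagonal and
#'   dimnames giving the leaf labels.
#' @return object of class `cluster_tree`: `labels`, `merge` (hclust-coded
#'   (n-1) x 2 matrix), `height` (joining distances, non-decreasing),
#'   `similarity` (`1 - height`, written to GTR files), `order` (leaf
#'   permutation induced by the dendrogram).
#' @export
average_linkage_tree <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    tsr_stop("dist must be a square matrix", "invalid_distance")
  if (max(abs(dist - t(dist))) > 1e-8 || any(abs(diag(dist)) > 1e-12))
    tsr_stop("dist must be symmetric with zero diagonal", "invalid_distance")
  n <- nrow(dist)
  if (n < 2L) tsr_stop("need >= 2 leaves", "invalid_distance")
  labels <- rownames(dist)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- dist
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  code <- -seq_len(n)          # hclust coding: -leaf or +merge index
  minleaf <- seq_len(n)        # smallest original leaf per cluster slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    act <- which(active)
    # scan active pairs in minleaf order; strict '<' keeps the first
    # (smallest-leaf) pair among ties
    act <- act[order(minleaf[act])]
    best <- Inf; bi <- bj <- 0L
    for (a in seq_len(length(act) - 1L)) for (b in (a + 1L):length(act)) {
      i <- act[a]; j <- act[b]
      if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
    }
    i <- bi; j <- bj
    merge[m, ] <- c(code[i], code[j])
    height[m] <- best
    # Lance-Williams average-linkage update into slot i
    for (l in which(active)) {
      if (l == i || l == j) next
      d[i, l] <- d[l, i] <- (size[i] * d[i, l] + size[j] * d[j, l]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    code[i] <- m
    minleaf[i] <- min(minleaf[i], minleaf[j])
  }
  structure(list(labels = labels, merge = merge, height = height,
                 similarity = 1 - height, order = tree_leaf_order(merge)),
            class = "cluster_tree")
}

# Leaf order induced by the dendrogram: concatenate child orders recursively.
tree_leaf_order <- function(merge) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(nrow(merge))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d leaves, %d merges, heights [%.3g, %.3g]\n",
              length(x$labels), nrow(x$merge),
              min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a tree into k flat clusters
#'
#' Undoes the last `k - 1` merges; the resulting connected components are the
#' clusters. Labels 1..k are assigned by first appearance in dendrogram
#' leaf order.
#'
#' @param tree a [cluster_tree][average_linkage_tree].
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return named integer vector: gene -> cluster label.
#' @export
cut_tree <- function(tree, k = 5L) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$labels)
  if (!is_count(k, min = 1) || k > n)
    tsr_stop(sprintf("k must be in 1..%d", n), "invalid_config")
  memb <- seq_len(n)
  if (n - k >= 1L) {
    # union-find over the first n-k merges
    parent <- seq_len(2L * n - 1L)          # ids: leaves 1..n, merges n+m
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    node_id <- function(code) if (code < 0L) -code else n + code
    for (m in seq_len(n - k)) {
      a <- find(node_id(tree$merge[m, 1L]))
      b <- find(node_id(tree$merge[m, 2L]))
      parent[a] <- n + m; parent[b] <- n + m
    }
    memb <- vapply(seq_len(n), function(i) find(i), 0L)
  }
  first_seen <- unique(memb[tree$order])
  stats::setNames(match(memb, first_seen), tree$labels)
}
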