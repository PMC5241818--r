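## PCA + k-means clustering and cluster-marker ranking.

#' PCA projection and k-means clustering
#'
#' Runs standard PCA on the standardized genes x cells matrix (genes are
#' already centered and scaled by [normalizeMatrix()]) and k-means with
#' k-means++-style multiple restarts on the first `nPcs` principal
#' components. The within-cluster sum of squared errors is reported for
#' every k in `kRange` (the scree used to choose k); the labelling
#' reported is the one for `k`. A 2-D tSNE embedding of the PCs can be
#' attached for visualization when the Rtsne package is installed; it is
#' decorative and not used by any computation.
#'
#' @param normalized a [NormalizedMatrix-class].
#' @param k number of clusters for the reported labels.
#' @param nPcs number of principal components (default 50, truncated to
#'   what the data support).
#' @param kRange candidate k values for the SSE scree (default `1:k`).
#' @param seed RNG seed (k-means restarts and tSNE).
#' @param nStart k-means restarts (default 10).
#' @param tsne compute the decorative tSNE embedding (default FALSE).
#' @return A [ClusterResult-class].
#' @export
reduceAndCluster <- function(normalized, k, nPcs = 50, kRange = seq_len(k),
                             seed = 1L, nStart = 10L, tsne = FALSE) {
  x <- t(normalized@standardized)  # cells x genes
  nCells <- nrow(x)
  if (k > nCells) stop("k = ", k, " exceeds the ", nCells, " cells")
  nPcs <- min(nPcs, nrow(x) - 1L, ncol(x))
  pca <- prcomp(x, center = FALSE, scale. = FALSE, rank. = nPcs)
  pcs <- pca$x[, seq_len(nPcs), drop = FALSE]
  sse <- setNames(numeric(length(kRange)), kRange)
  labels <- NULL
  for (kk in sort(kRange)) {
    set.seed(seed)
    fit <- kmeans(pcs, centers = kk, nstart = nStart, iter.max = 100L)
    sse[as.character(kk)] <- fit$tot.withinss
    if (kk == k) labels <- fit$cluster
  }
  if (is.null(labels)) {
    set.seed(seed)
    labels <- kmeans(pcs, centers = k, nstart = nStart,
                     iter.max = 100L)$cluster
  }
  emb <- NULL
  if (tsne && requireNamespace("Rtsne", quietly = TRUE)) {
    set.seed(seed)
    emb <- Rtsne::Rtsne(pcs, check_duplicates = FALSE,
                        perplexity = min(30, (nCells - 1) %/% 3))$Y
    rownames(emb) <- rownames(pcs)
  }
  methods::new("ClusterResult",
               labels = setNames(as.integer(labels), rownames(pcs)),
               k = as.integer(k), sse = sse, pcs = pcs, tsne = emb,
               seed = as.integer(seed))
}

#' Rank cluster-specific genes and build a cluster dendrogram
#'
#' For each cluster, every gene is scored as its mean log-normalized
#' expression inside the cluster minus the median expression of the same
#' gene across the cells pooled from all other clusters (`otherStat =
#' "mean"` swaps the median for a mean). The `topN` genes per cluster by
#' score are reported. Clusters are additionally organised in a
#' dendrogram by average-linkage hierarchical clustering on one minus the
#' Pearson correlation of cluster mean profiles.
#'
#' @param normalized a [NormalizedMatrix-class].
#' @param labels per-cell cluster labels (named or in column order).
#' @param topN markers to report per cluster (default 10).
#' @param otherStat statistic over the pooled other cells: `"median"`
#'   (default) or `"mean"`.
#' @return list: `markers` (per-cluster character vectors), `scores`
#'   (genes x clusters), `dendrogram` (an `hclust`), `clusterMeans`.
#' @export
clusterMarkerGenes <- function(normalized, labels, topN = 10,
                               otherStat = c("median", "mean")) {
  otherStat <- match.arg(otherStat)
  x <- as.matrix(normalized@logNorm)  # genes x cells, unstandardized log
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("need at least two clusters")
  sizes <- table(labels)
  if (any(sizes == 1L)) warning("cluster(s) with a single cell: ",
                                paste(names(sizes)[sizes == 1L],
                                      collapse = ", "))
  scores <- matrix(0, nrow(x), length(cl),
                   dimnames = list(rownames(x), as.character(cl)))
  means <- scores
  for (i in seq_along(cl)) {
    inC <- labels == cl[i]
    mIn <- rowMeans(x[, inC, drop = FALSE])
    other <- x[, !inC, drop = FALSE]
    mOut <- if (otherStat == "median") apply(other, 1L, median)
            else rowMeans(other)
    scores[, i] <- mIn - mOut
    means[, i] <- mIn
  }
  markers <- lapply(seq_along(cl), function(i) {
    o <- order(-scores[, i], rownames(scores))
    head(rownames(scores)[o], topN)
  })
  names(markers) <- as.character(cl)
  cc <- suppressWarnings(cor(means))
  cc[!is.finite(cc)] <- 0
  dend <- hclust(as.dist(1 - cc), method = "average")
  list(markers = markers, scores = scores, dendrogram = dend,
       clusterMeans = means)
}
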