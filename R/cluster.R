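#' k-means clustering of family members on a master matrix
#'
#' Partitions domains by their surface frequency profiles with k-means
#' (Euclidean, multiple random restarts under a fixed seed).
#'
#' @param master a [MasterMatrix-class] (typically a [subsetSurface()]
#'   restriction).
#' @param k number of clusters, `1 <= k <=` number of domains.
#' @param seed RNG seed (default 0), recorded in the result.
#' @param nstart number of random restarts (default 50).
#' @param surface surface name recorded in the result.
#' @return A [ClusterResult-class] with labels in `1..k` and the total
#'   within-cluster sum of squares.
#' @export
clusterKmeans <- function(master, k, seed = 0L, nstart = 50L,
                          surface = "custom") {
  D <- nrow(master)
  if (k < 1L || k > D) stop("k must lie in 1..", D)
  m <- unclass(master)
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100L)
  new("ClusterResult", surface = surface, method = "kmeans",
      labels = stats::setNames(as.integer(km$cluster), rownames(m)),
      k = as.integer(k), seed = as.integer(seed),
      withinss = km$tot.withinss, tree = NULL, newick = character(0))
}

#' Hierarchical clustering (dendrogram) of family members
#'
#' Agglomerative clustering on Euclidean distances between master-matrix
#' rows; the tree is also serialised as a Newick string.
#'
#' @param master a [MasterMatrix-class] with at least 2 rows.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#' @param surface surface name recorded in the result.
#' @return A [ClusterResult-class] carrying the `hclust` tree and its
#'   Newick serialisation (see [exportNewick()]).
#' @export
clusterHierarchical <- function(master, linkage = c("average", "complete",
                                                    "ward"),
                                surface = "custom") {
  linkage <- match.arg(linkage)
  if (nrow(master) < 2L) stop("need at least 2 domains to build a tree")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(unclass(master)), method = method)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  new("ClusterResult", surface = surface, method = "hierarchical",
      labels = integer(0), k = NA_integer_, seed = NA_integer_,
      withinss = NA_real_, tree = hc, newick = nwk)
}

#' Cophenetic distance table of a dendrogram
#'
#' Supports comparing how spread out family members are on different
#' surfaces (e.g. SII trees showing larger inter-domain distances than SI
#' trees).
#'
#' @param result a hierarchical [ClusterResult-class].
#' @return Symmetric numeric matrix of cophenetic distances.
#' @export
copheneticDistances <- function(result) {
  if (is.null(result@tree)) stop("no dendrogram in this ClusterResult")
  as.matrix(stats::cophenetic(result@tree))
}

#' Mean pairwise Euclidean distance between master-matrix rows
#'
#' @param master a [MasterMatrix-class].
#' @return Mean of all pairwise distances.
#' @export
meanPairwiseDistance <- function(master) {
  mean(stats::dist(unclass(master)))
}
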