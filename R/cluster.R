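#' Single-linkage clustering at an RMSD threshold
#'
#' Members i and j share a cluster iff they are connected by a chain of
#' pairs each within the threshold, i.e. clusters are the connected
#' components of the threshold graph (the closure of single linkage, which
#' is deterministic and order-independent). Cluster labels are 0-based in
#' order of first member occurrence; each cluster's representative is its
#' medoid (minimum summed intra-cluster distance, ties to the lowest
#' index).
#'
#' @param mat symmetric member x member RMSD matrix with zero diagonal.
#' @param threshold linkage threshold, Angstrom (default 3).
#' @return a \linkS4class{ClusteringResult}.
#' @export
singleLinkageCluster <- function(mat, threshold = 3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) || max(abs(mat - t(mat))) > 1e-8)
    stop("RMSD matrix must be symmetric")
  if (max(abs(diag(mat))) > 1e-8) stop("RMSD matrix must have zero diagonal")
  n <- nrow(mat)
  adj <- (mat <= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labels <- match(comp, unique(comp)) - 1L     # 0-based, first-occurrence order
  reps <- vapply(seq_len(max(labels) + 1L) - 1L, function(cl) {
    idx <- which(labels == cl)
    sums <- rowSums(mat[idx, idx, drop = FALSE])
    idx[which.min(sums)]                        # which.min ties -> lowest index
  }, integer(1))
  new("ClusteringResult", labels = labels, representatives = reps,
      method = "single_linkage", threshold = threshold,
      seed = integer(0), converged = TRUE)
}

# Deterministic farthest-point initial centers: seeded first pick, then
# iteratively the point farthest from the chosen set.
.farthestPointInit <- function(features, k, seed) {
  n <- nrow(features)
  set.seed(seed)
  first <- sample.int(n, 1L)
  chosen <- first
  if (k > 1L) {
    d2min <- rowSums(sweep(features, 2, features[first, ])^2)
    for (i in 2:k) {
      nxt <- which.max(d2min)
      chosen <- c(chosen, nxt)
      d2min <- pmin(d2min, rowSums(sweep(features, 2, features[nxt, ])^2))
    }
  }
  chosen
}

#' Threshold-driven k-means clustering of site conformations
#'
#' Finds the smallest k in 1..maxK such that every member lies within
#' \code{threshold} (on the per-residue RMSD scale) of its cluster
#' centroid; k-means is run with deterministic farthest-point
#' initialization given the seed. If no k satisfies the threshold, the
#' result for maxK is returned with \code{converged = FALSE}.
#'
#' The intended feature space is the concatenated per-residue side-chain
#' geometric centres of the site residues (3 columns per residue);
#' centroid distances are divided by \code{scale} (default
#' \code{sqrt(ncol/3)}, the residue count) to convert them to the
#' per-residue RMSD scale.
#'
#' @param features member x d feature matrix.
#' @param threshold RMSD-equivalent threshold, Angstrom.
#' @param seed integer seed for the initialization (default 17).
#' @param maxK largest k to try (default number of members).
#' @param scale divisor converting centroid distance to RMSD scale.
#' @return a \linkS4class{ClusteringResult}.
#' @export
kmeansThresholdCluster <- function(features, threshold, seed = 17L,
                                   maxK = nrow(features), scale = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (!n) stop("empty ensemble")
  if (!all(is.finite(features))) stop("features must be finite")
  if (maxK < 1L) stop("maxK must be >= 1")
  maxK <- min(maxK, n)
  if (is.null(scale)) scale <- sqrt(ncol(features) / 3)

  rowKey <- apply(features, 1, paste, collapse = "\r")
  nDistinct <- length(unique(rowKey))
  result <- NULL
  for (k in seq_len(maxK)) {
    if (k >= nDistinct) {
      # one cluster per distinct conformation: zero centroid distances, and
      # kmeans itself refuses k = n or duplicate centers
      result <- list(k = nDistinct, cluster = match(rowKey, unique(rowKey)),
                     ok = TRUE)
      break
    }
    init <- .farthestPointInit(features, k, seed)
    km <- suppressWarnings(stats::kmeans(features, centers = features[init, , drop = FALSE],
                                         iter.max = 100L))
    d <- sqrt(rowSums((features - km$centers[km$cluster, , drop = FALSE])^2)) / scale
    result <- list(k = k, cluster = km$cluster, ok = all(d <= threshold))
    if (result$ok) break
  }
  if (!result$ok)
    warning("no k <= ", maxK, " satisfies the ", threshold, " A threshold")
  labels <- match(result$cluster, unique(result$cluster)) - 1L
  reps <- vapply(seq_len(max(labels) + 1L) - 1L, function(cl) {
    idx <- which(labels == cl)
    # medoid in feature space
    d <- as.matrix(stats::dist(features[idx, , drop = FALSE]))
    idx[which.min(rowSums(d))]
  }, integer(1))
  new("ClusteringResult", labels = labels, representatives = reps,
      method = "kmeans", threshold = threshold, seed = as.integer(seed),
      converged = result$ok)
}

#' Per-cluster summary table
#'
#' One row per cluster: size, representative member index and label, and
#' (when per-residue RMSD data are supplied) the representative's RMSD
#' versus the reference for every site residue -- the data behind
#' per-representative RMSD profile plots.
#'
#' @param result a \linkS4class{ClusteringResult}.
#' @param perResidue optional member x residue RMSD matrix
#'   (\code{rmsdStats(...)$perResidue}).
#' @param labels optional member labels.
#' @return data.frame, one row per cluster.
#' @export
clusterReport <- function(result, perResidue = NULL, labels = NULL) {
  k <- nClusters(result)
  reps <- representatives(result)
  out <- data.frame(cluster = seq_len(k) - 1L,
                    size = as.integer(table(factor(clusterLabels(result),
                                                   levels = seq_len(k) - 1L))),
                    representative = reps,
                    representative_label =
                      if (is.null(labels)) as.character(reps) else labels[reps],
                    stringsAsFactors = FALSE)
  if (!is.null(perResidue))
    out <- cbind(out, as.data.frame(perResidue[reps, , drop = FALSE],
                                    row.names = NULL))
  out
}

#' Side-chain-centre feature matrix for k-means clustering
#'
#' Concatenates, per member, the geometric centres of the side-chain heavy
#' atoms of every mapped site residue (reference residue order; unmapped
#' residues in any member are dropped for all members so the space is
#' consistent).
#'
#' @param superposed result of \code{\link{superposeEnsemble}}.
#' @param site a \linkS4class{BindingSite}.
#' @return member x (3 * residues) matrix with residue keys in
#'   \code{attr(, "residues")}.
#' @export
sideChainCenterFeatures <- function(superposed, site) {
  ens <- superposed$ensemble
  mem <- members(ens)
  maps <- superposed$mappings
  keys <- siteResidues(site)$key
  centers <- lapply(seq_along(mem), function(i) {
    p <- mappingPairs(maps[[i]])
    p <- p[!is.na(p$member_key), , drop = FALSE]
    b <- .siteResidueCoords(mem[[i]], p$member_key)
    ctr <- t(vapply(p$member_key, function(k)
      if (is.null(b[[k]])) rep(NA_real_, 3) else b[[k]]$center, numeric(3)))
    rownames(ctr) <- p$ref_key
    ctr
  })
  ok <- keys[vapply(keys, function(k)
    all(vapply(centers, function(c) k %in% rownames(c) && all(is.finite(c[k, ])),
               logical(1))), logical(1))]
  if (!length(ok)) stop("no site residue is mapped in every member")
  feat <- t(vapply(centers, function(c) as.numeric(t(c[ok, , drop = FALSE])),
                   numeric(3 * length(ok))))
  rownames(feat) <- ens@labels
  attr(feat, "residues") <- ok
  feat
}
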