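#' Elementwise paired t map over channels x time
#'
#' @param condA,condB numeric arrays participants x channels x time with
#'   matched participant order.
#' @return channels x time matrix of paired t statistics. Elements with
#'   zero variance of the paired differences get t = 0 with a warning.
#' @export
pairedTMap <- function(condA, condB) {
  stopifnot(identical(dim(condA), dim(condB)))
  n <- dim(condA)[1L]
  if (n < 2L) stop("need at least 2 participants")
  D <- condA - condB
  Dm <- matrix(D, nrow = n)  # participants x (channels*time)
  mu <- colMeans(Dm)
  v <- (colSums(Dm^2) - n * mu^2) / (n - 1)
  t <- mu / sqrt(v / n)
  zv <- v <= 0 | !is.finite(t)
  if (any(zv)) {
    if (any(v <= 0 & mu != 0))
      warning("zero-variance elements in paired differences; t set to 0")
    t[zv] <- 0
  }
  matrix(t, dim(condA)[2L], dim(condA)[3L])
}

#' Build a channel adjacency from coordinates
#'
#' Channels are neighbors when their Euclidean distance is below
#' `distThreshold`. When no threshold is given the smallest distance at
#' which the median neighbor count reaches `targetMedianNeighbors` is
#' chosen, honoring layouts that require a minimum neighborhood size.
#'
#' @param coords numeric matrix (channels x 2 or 3) of positions; rownames
#'   are channel labels.
#' @param distThreshold neighbor distance cutoff (same units as coords).
#' @param targetMedianNeighbors used to auto-pick the threshold (default 4).
#' @return a list of integer neighbor vectors (symmetric, no
#'   self-neighbors), with the labels as names and the threshold as
#'   attribute `distThreshold`.
#' @export
buildAdjacency <- function(coords, distThreshold = NULL,
                           targetMedianNeighbors = 4L) {
  coords <- as.matrix(coords)
  D <- as.matrix(stats::dist(coords))
  if (is.null(distThreshold)) {
    cand <- sort(unique(D[upper.tri(D)]))
    for (th in cand) {
      nb <- rowSums(D <= th) - 1L
      if (stats::median(nb) >= targetMedianNeighbors) {
        distThreshold <- th * (1 + 1e-9)
        break
      }
    }
    if (is.null(distThreshold)) distThreshold <- max(cand) * (1 + 1e-9)
  }
  adj <- lapply(seq_len(nrow(D)), function(i)
    which(D[i, ] <= distThreshold & seq_len(ncol(D)) != i))
  names(adj) <- rownames(coords)
  attr(adj, "distThreshold") <- distThreshold
  adj
}

#' Group suprathreshold channel-time points into clusters
#'
#' Elements with `|t| > threshold` and a common sign are connected when
#' they share a time sample and are neighboring channels, or share a
#' channel and sit at adjacent time samples. Channels with fewer than
#' `minNeighbors` neighbors in the layout are excluded from cluster
#' formation. Positive and negative clusters never merge.
#'
#' @param tMap channels x time matrix of t statistics.
#' @param adjacency neighbor list as from [buildAdjacency()].
#' @param threshold cluster-forming threshold (> 0) applied to |t|.
#' @param minNeighbors minimum layout neighbors for a channel to
#'   participate (default 0: keep all).
#' @return list of clusters, each with `members` (matrix with columns
#'   `channel`, `time`), `sign` and `mass`.
#' @export
findClusters <- function(tMap, adjacency, threshold, minNeighbors = 0L) {
  assertPositive(threshold, "threshold")
  nc <- nrow(tMap); nt <- ncol(tMap)
  stopifnot(length(adjacency) == nc)
  eligible <- vapply(adjacency, length, integer(1L)) >= minNeighbors
  supra <- abs(tMap) > threshold & eligible
  if (!any(supra)) return(list())
  lab <- matrix(0L, nc, nt)
  clusters <- list()
  nextId <- 0L
  idx <- which(supra, arr.ind = TRUE)
  sgn <- sign(tMap)
  for (r in seq_len(nrow(idx))) {
    c0 <- idx[r, 1L]; t0 <- idx[r, 2L]
    if (lab[c0, t0] != 0L) next
    nextId <- nextId + 1L
    s <- sgn[c0, t0]
    queue <- matrix(c(c0, t0), ncol = 2L)
    lab[c0, t0] <- nextId
    members <- queue
    while (nrow(queue)) {
      cur <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      ch <- cur[1L]; tt <- cur[2L]
      cand <- rbind(
        if (tt > 1L) c(ch, tt - 1L),
        if (tt < nt) c(ch, tt + 1L),
        if (length(adjacency[[ch]]))
          cbind(adjacency[[ch]], tt))
      if (is.null(cand)) next
      for (q in seq_len(nrow(cand))) {
        cc <- cand[q, 1L]; ct <- cand[q, 2L]
        if (supra[cc, ct] && lab[cc, ct] == 0L && sgn[cc, ct] == s) {
          lab[cc, ct] <- nextId
          queue <- rbind(queue, c(cc, ct))
          members <- rbind(members, c(cc, ct))
        }
      }
    }
    colnames(members) <- c("channel", "time")
    clusters[[nextId]] <- list(members = members, sign = s,
                               mass = sum(tMap[members]))
  }
  clusters
}

#' Spatiotemporal cluster-based permutation test for paired conditions
#'
#' Paired t maps are thresholded at the two-sided t quantile for
#' `thresholdP`, suprathreshold points are clustered under channel
#' adjacency and temporal contiguity, and each observed cluster's mass
#' (sum of t) is compared against a sign-flip null: per permutation every
#' participant's condition labels are flipped with probability 1/2, and the
#' null statistic is the maximum absolute cluster mass of the permuted map
#' (0 when no cluster forms). Cluster p-values follow the add-one rule.
#'
#' @param condA,condB participants x channels x time arrays (paired).
#' @param adjacency neighbor list from [buildAdjacency()].
#' @param nPerm number of permutations (default 1000).
#' @param alpha test level recorded in the result (default 0.05).
#' @param thresholdP two-sided p for the cluster-forming t threshold
#'   (default 0.05).
#' @param minNeighbors minimum layout neighbors per channel (default 0).
#' @param seed RNG seed.
#' @return a [ClusterResult-class].
#' @export
clusterPermutationTest <- function(condA, condB, adjacency, nPerm = 1000L,
                                   alpha = 0.05, thresholdP = 0.05,
                                   minNeighbors = 0L, seed = NULL) {
  nPerm <- assertCount(nPerm, "nPerm")
  n <- dim(condA)[1L]
  if (n < 2L) stop("need at least 2 participants")
  thr <- stats::qt(1 - thresholdP / 2, df = n - 1L)
  if (!is.finite(thr)) stop("sample too small for the requested threshold")
  tObs <- pairedTMap(condA, condB)
  obs <- findClusters(tObs, adjacency, thr, minNeighbors)
  nc <- dim(condA)[2L]; nt <- dim(condA)[3L]
  D <- matrix(condA - condB, nrow = n)
  ss <- colSums(D^2)
  nullMax <- withSeed(seed, {
    vapply(seq_len(nPerm), function(p) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      mu <- colMeans(s * D)
      v <- (ss - n * mu^2) / (n - 1)
      t <- mu / sqrt(v / n)
      t[!is.finite(t)] <- 0
      cl <- findClusters(matrix(t, nc, nt), adjacency, thr, minNeighbors)
      if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1L), "mass")))
    }, numeric(1L))
  })
  pv <- vapply(obs, function(cl)
    (1 + sum(nullMax >= abs(cl$mass))) / (nPerm + 1), numeric(1L))
  new("ClusterResult", clusters = obs, pValues = pv, tMap = tObs,
      nPerm = as.integer(nPerm), threshold = thr)
}
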