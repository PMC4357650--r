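#' Correlation distance between two intensity vectors
#'
#' 1 - Pearson correlation: 0 for affinely identical profiles, 1 for
#' uncorrelated, 2 for perfectly anti-correlated. Undefined (an error) when
#' either vector has zero variance.
#'
#' @param u,v numeric vectors of equal length.
#' @return distance in [0, 2].
#' @export
correlationDistance <- function(u, v) {
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("correlation distance undefined for zero-variance vectors")
  1 - stats::cor(u, v)
}

.asSpotMatrix <- function(x) {
  ## accept a binned SummarizedExperiment (bins x spots) or a spots x bins matrix
  if (is(x, "SummarizedExperiment")) t(SummarizedExperiment::assay(x, "intensity"))
  else as.matrix(x)
}

.rowStandardize <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  (m - mu) / s
}

.leafInertia <- function(m) {
  ## summed correlation distance to the leaf mean spectrum
  if (nrow(m) < 2) return(0)
  centroid <- colMeans(m)
  if (stats::sd(centroid) == 0) return(0)
  sum(apply(m, 1, function(r) 1 - stats::cor(r, centroid)))
}

#' Bisecting k-means spatial segmentation under correlation distance
#'
#' Starts from one segment holding every spot and repeatedly splits the
#' highest-inertia leaf (inertia = summed correlation distance to the leaf
#' mean spectrum) with 2-means. Each split runs \code{stats::kmeans} on
#' row-standardised spectra — squared Euclidean distance between
#' z-standardised rows is proportional to correlation distance, so the
#' 2-means objective matches the correlation criterion. Deterministic given
#' \code{seed}. Spots whose binned spectrum has zero variance cannot enter a
#' correlation geometry and are excluded (with a message).
#'
#' @param x a binned SummarizedExperiment from \code{\link{binSpectra}}, or
#'   a spots x bins matrix with spot ids as row names.
#' @param leaves target number of leaf segments (>= 1).
#' @param seed integer RNG seed.
#' @param restarts random restarts per split (default 5).
#' @return a \linkS4class{SegmentationTree}; extract partitions with
#'   \code{\link{segmentLabels}}.
#' @export
bisectingKmeans <- function(x, leaves, seed = 1L, restarts = 5L) {
  m <- .asSpotMatrix(x)
  zerovar <- apply(m, 1, function(r) stats::sd(r) == 0)
  if (any(zerovar)) {
    message(sum(zerovar), " zero-variance spot(s) excluded from segmentation")
    m <- m[!zerovar, , drop = FALSE]
  }
  if (leaves < 1) stop("leaves must be >= 1")
  if (nrow(m) < leaves) stop("fewer spots than requested leaves")
  set.seed(seed)
  nodes <- list(list(id = 1L, parent = NA_integer_, children = integer(0),
                     spots = rownames(m), inertia = .leafInertia(m)))
  splitOrder <- integer(0)
  nextId <- 2L
  leafIds <- function() which(vapply(nodes, function(n) !length(n$children), logical(1)))
  while (length(leafIds()) < leaves) {
    lv <- leafIds()
    splittable <- lv[vapply(nodes[lv], function(n)
      length(n$spots) >= 2 && n$inertia > 0, logical(1))]
    if (!length(splittable)) stop("no splittable leaf left before reaching ", leaves, " leaves")
    node <- splittable[which.max(vapply(nodes[splittable], `[[`, numeric(1), "inertia"))]
    sub <- m[nodes[[node]]$spots, , drop = FALSE]
    km <- stats::kmeans(.rowStandardize(sub), centers = 2, nstart = restarts)
    for (cl in 1:2) {
      spots <- nodes[[node]]$spots[km$cluster == cl]
      nodes[[nextId]] <- list(id = nextId, parent = nodes[[node]]$id,
                              children = integer(0), spots = spots,
                              inertia = .leafInertia(m[spots, , drop = FALSE]))
      nodes[[node]]$children <- c(nodes[[node]]$children, nextId)
      nextId <- nextId + 1L
    }
    splitOrder <- c(splitOrder, nodes[[node]]$id)
  }
  new("SegmentationTree", nodes = nodes, splitOrder = splitOrder,
      spotIds = rownames(m))
}

#' Cut a segmentation tree into k segments
#'
#' Replays the first k - 1 splits, yielding the partition the tree had when
#' it held k leaves (children partition their parent, so any cut is a
#' partition of the spot set).
#'
#' @param tree a \linkS4class{SegmentationTree}.
#' @param leaves number of segments (1 to the tree's leaf count).
#' @return integer segment labels (1..leaves) named by spot id.
#' @export
segmentLabels <- function(tree, leaves) {
  if (leaves < 1 || leaves > length(tree@splitOrder) + 1L)
    stop("leaves must be between 1 and ", length(tree@splitOrder) + 1L)
  lab <- stats::setNames(rep(1L, length(tree@spotIds)), tree@spotIds)
  for (i in seq_len(leaves - 1L)) {
    node <- tree@nodes[[tree@splitOrder[i]]]
    for (ch in node$children) lab[tree@nodes[[ch]]$spots] <- ch
  }
  stats::setNames(as.integer(factor(lab)), names(lab))
}

setMethod("show", "SegmentationTree", function(object) {
  nl <- sum(vapply(object@nodes, function(n) !length(n$children), logical(1)))
  cat("SegmentationTree:", length(object@spotIds), "spots,", nl, "leaves,",
      length(object@splitOrder), "splits\n")
})

#' Fit a pLSA model by EM
#'
#' Fits the multinomial aspect model
#' p(spot, bin) = sum_z p(z) p(spot|z) p(bin|z) to a nonnegative binned
#' matrix with random-initialisation EM, stopping when the log-likelihood
#' gain drops below \code{tol} or after \code{maxIter} iterations. Spots
#' with zero total intensity carry no information and are excluded (listed
#' in the model's \code{excluded} slot, mapped as NA downstream).
#'
#' @param x a binned SummarizedExperiment or spots x bins matrix.
#' @param k number of components (1 <= k <= min(dims)); 10 is the
#'   conventional choice for full-section summaries.
#' @param seed integer RNG seed for the random initialisation.
#' @param maxIter maximum EM iterations (default 500).
#' @param tol absolute log-likelihood gain at which to stop (default 1e-8
#'   per unit of total intensity, scaled internally).
#' @return a \linkS4class{PlsaModel}.
#' @export
plsaFit <- function(x, k = 10, seed = 1L, maxIter = 500L, tol = 1e-8) {
  m <- .asSpotMatrix(x)
  if (any(m < 0)) stop("pLSA needs a nonnegative matrix")
  rowTot <- rowSums(m)
  excluded <- rownames(m)[rowTot == 0]
  m <- m[rowTot > 0, , drop = FALSE]
  if (!nrow(m) || sum(m) <= 0) stop("pLSA needs a positive total intensity")
  if (k < 1 || k > min(dim(m))) stop("k must be between 1 and min(dims)")
  keepBin <- colSums(m) > 0
  X <- m[, keepBin, drop = FALSE]
  ns <- nrow(X); nb <- ncol(X); N <- sum(X)
  set.seed(seed)
  pz <- rep(1 / k, k)
  ps <- apply(matrix(stats::runif(ns * k) + 0.1, ns, k), 2, function(v) v / sum(v))
  pb <- apply(matrix(stats::runif(nb * k) + 0.1, nb, k), 2, function(v) v / sum(v))
  ps <- matrix(ps, ns, k); pb <- matrix(pb, nb, k)
  trace <- numeric(0)
  pos <- X > 0
  for (it in seq_len(maxIter)) {
    P <- ps %*% (pz * t(pb))          # ns x nb mixture probabilities
    ## floor against underflow of vanishing factors (keeps X/P finite so
    ## that 0-probability components contribute exactly 0, never NaN)
    P <- pmax(P, 1e-300)
    ll <- sum(X[pos] * log(P[pos]))
    trace <- c(trace, ll)
    if (it > 1 && ll - trace[it - 1] < tol * N) break
    R <- X / P                        # shared ratio for all components
    for (z in seq_len(k)) {
      W <- R * (pz[z] * outer(ps[, z], pb[, z]))  # expected counts for z
      tz <- sum(W)
      ps[, z] <- rowSums(W) / tz
      pb[, z] <- colSums(W) / tz
      pz[z] <- tz / N
    }
    pz <- pz / sum(pz)
  }
  pbFull <- matrix(0, ncol(m), k)
  pbFull[keepBin, ] <- pb
  new("PlsaModel", k = as.integer(k), pComponent = pz,
      pSpot = matrix(ps, ns, k, dimnames = list(rownames(X), NULL)),
      pBin = pbFull, logLik = trace, spotIds = rownames(X),
      excluded = as.character(excluded))
}

setMethod("show", "PlsaModel", function(object) {
  cat("PlsaModel: k =", object@k, "on", length(object@spotIds), "spots;",
      length(object@logLik), "EM iterations, logLik",
      sprintf("%.2f", utils::tail(object@logLik, 1)), "\n")
})

#' Per-spot posterior weights of one pLSA component
#'
#' Posterior p(z|spot) proportional to p(z) p(spot|z), normalised across
#' components per spot, placed on the acquisition grid. Spots excluded from
#' the fit are NA.
#'
#' @param model a \linkS4class{PlsaModel}.
#' @param component component index (1..k).
#' @param dataset the \linkS4class{MsiDataset} giving the grid.
#' @return a \linkS4class{SpatialMap}.
#' @export
componentMap <- function(model, component, dataset) {
  if (component < 1 || component > model@k) stop("component index out of range")
  post <- t(model@pComponent * t(model@pSpot))  # ns x k, unnormalised p(z|s)
  post <- post / rowSums(post)
  v <- stats::setNames(post[, component], model@spotIds)
  spatialMap(dataset, v, what = paste0("plsa_component_", component))
}

#' @describeIn componentMap hard per-spot component assignment (argmax of
#'   the posterior), named by spot id.
#' @export
componentAssignment <- function(model) {
  post <- t(model@pComponent * t(model@pSpot))
  stats::setNames(max.col(post, ties.method = "first"), model@spotIds)
}
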