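#' Row-wise z-scoring of expression profiles
#'
#' Each gene's profile is centred and scaled to population standard
#' deviation 1 (divisor n, matching the z-score definition rather than the
#' sample sd). Constant rows cannot be z-scored and are dropped with a
#' warning.
#'
#' @param expression gene x timepoint numeric matrix.
#' @return z-scored matrix, possibly with fewer rows; dropped gene ids in
#'   attribute `"dropped"`.
#' @export
zscoreRows <- function(expression) {
    m <- as.matrix(expression)
    n <- ncol(m)
    mu <- rowMeans(m)
    sdp <- sqrt(rowMeans((m - mu)^2))
    drop <- sdp == 0
    if (any(drop))
        warnf("dropping %d constant expression row(s)", sum(drop))
    z <- (m[!drop, , drop = FALSE] - mu[!drop]) / sdp[!drop]
    attr(z, "dropped") <- rownames(m)[drop]
    z
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre.
.kmeansPlusPlusInit <- function(m, k) {
    n <- nrow(m)
    centers <- matrix(NA_real_, k, ncol(m))
    centers[1, ] <- m[sample.int(n, 1), ]
    d2 <- rowSums((m - matrix(centers[1, ], n, ncol(m), byrow = TRUE))^2)
    for (j in seq_len(k - 1) + 1) {
        pick <- if (all(d2 == 0)) sample.int(n, 1)
                else sample.int(n, 1, prob = d2)
        centers[j, ] <- m[pick, ]
        dj <- rowSums((m - matrix(centers[j, ], n, ncol(m), byrow = TRUE))^2)
        d2 <- pmin(d2, dj)
    }
    centers
}

.lloyd <- function(m, centers, maxIter = 300) {
    k <- nrow(centers)
    labels <- rep(0L, nrow(m))
    for (it in seq_len(maxIter)) {
        d <- vapply(seq_len(k), function(j)
            rowSums((m - matrix(centers[j, ], nrow(m), ncol(m),
                                byrow = TRUE))^2), numeric(nrow(m)))
        newLabels <- max.col(-d, ties.method = "first")
        # empty-cluster repair: reseed with the point farthest from its centre
        for (j in seq_len(k)) {
            if (!any(newLabels == j)) {
                far <- which.max(d[cbind(seq_len(nrow(m)), newLabels)])
                newLabels[far] <- j
                centers[j, ] <- m[far, ]
            }
        }
        if (identical(newLabels, labels)) break
        labels <- newLabels
        for (j in seq_len(k))
            centers[j, ] <- colMeans(m[labels == j, , drop = FALSE])
    }
    d <- vapply(seq_len(k), function(j)
        rowSums((m - matrix(centers[j, ], nrow(m), ncol(m),
                            byrow = TRUE))^2), numeric(nrow(m)))
    wss <- sum(d[cbind(seq_len(nrow(m)), labels)])
    list(labels = labels, centers = centers, wss = wss)
}

#' k-means clustering of expression profiles
#'
#' Lloyd iterations from k-means++ initialisation, best of `restarts` runs
#' by total within-cluster sum of squares; deterministic given `seed`.
#' Empty clusters are repaired by reseeding with the farthest point from its
#' assigned centre.
#'
#' @param m numeric matrix (rows = genes, typically z-scored).
#' @param k number of clusters (must not exceed the number of rows).
#' @param seed integer seed.
#' @param restarts independent initialisations (default 25).
#' @return list with `k`, `labels` (named by rownames), `centroids` (k x T),
#'   `wss`, `seed`, `restarts`.
#' @export
kmeansFit <- function(m, k, seed = 1L, restarts = 25) {
    m <- as.matrix(m)
    if (k > nrow(m)) stopf("k (%d) exceeds number of rows (%d)", k, nrow(m))
    best <- NULL
    withSeed(childSeed(seed, "kmeans"), {
        for (r in seq_len(restarts)) {
            fit <- .lloyd(m, .kmeansPlusPlusInit(m, k))
            if (is.null(best) || fit$wss < best$wss) best <- fit
        }
    })
    list(k = k, labels = setNames(best$labels, rownames(m)),
         centroids = best$centers, wss = best$wss, seed = seed,
         restarts = restarts)
}

#' Elbow-based selection of the number of clusters
#'
#' Fits k-means for each k in `kMin:kMax` and picks the k maximising the
#' second difference `wss(k-1) - 2 wss(k) + wss(k+1)` over interior k — a
#' reproducible formalisation of the visual elbow. The full curve is
#' returned for manual inspection or override.
#'
#' @param m numeric matrix.
#' @param kMin,kMax search range (default 2..10).
#' @param seed integer seed.
#' @param restarts restarts per fit.
#' @return list with `k` (chosen), `wss` (named numeric over the range),
#'   `second_difference`.
#' @export
elbowSelect <- function(m, kMin = 2, kMax = 10, seed = 1L, restarts = 25) {
    kMax <- min(kMax, nrow(m))
    ks <- kMin:kMax
    wss <- vapply(ks, function(k)
        kmeansFit(m, k, seed = childSeed(seed, paste0("elbow_k", k)),
                  restarts = restarts)$wss, numeric(1))
    names(wss) <- ks
    interior <- ks[ks > kMin & ks < kMax]
    if (length(interior) == 0)
        return(list(k = ks[which.min(wss)], wss = wss,
                    second_difference = setNames(numeric(0), character(0))))
    d2 <- vapply(interior, function(k)
        wss[as.character(k - 1)] - 2 * wss[as.character(k)] +
            wss[as.character(k + 1)], numeric(1))
    names(d2) <- interior
    list(k = interior[which.max(d2)], wss = wss, second_difference = d2)
}

#' Cluster mean expression profiles
#'
#' @param model result of [kmeansFit()].
#' @param zmatrix the matrix that was clustered.
#' @return k x T matrix of per-cluster, per-timepoint mean values.
#' @export
clusterProfiles <- function(model, zmatrix) {
    zmatrix <- as.matrix(zmatrix)
    stopifnot(all(names(model$labels) %in% rownames(zmatrix)))
    out <- vapply(seq_len(model$k), function(j) {
        rows <- names(model$labels)[model$labels == j]
        colMeans(zmatrix[rows, , drop = FALSE])
    }, numeric(ncol(zmatrix)))
    t(out)
}
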