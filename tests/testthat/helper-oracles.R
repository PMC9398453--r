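# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: plain loops and closed forms only.

library(GenomicRanges)

# random interval set on a small genome (1-based closed, like GRanges)
randomIntervals <- function(n, chroms = c("cA", "cB"), maxPos = 1e5,
                            maxLen = 500) {
    ch <- sample(chroms, n, replace = TRUE)
    st <- sample.int(maxPos, n, replace = TRUE)
    w <- sample.int(maxLen, n, replace = TRUE)
    GRanges(ch, IRanges(st, st + w - 1))
}

# O(n*m) any-overlap test: >= 1 shared base under 1-based closed coords
bruteAnyOverlap <- function(grA, grB) {
    chA <- as.character(seqnames(grA)); chB <- as.character(seqnames(grB))
    sA <- start(grA); eA <- end(grA); sB <- start(grB); eB <- end(grB)
    vapply(seq_along(grA), function(i) {
        any(chA[i] == chB & sA[i] <= eB & sB <= eA[i])
    }, logical(1))
}

# independent Benjamini-Hochberg implementation
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
# point probabilities not exceeding the observed one (with the conventional
# relative tolerance for ties)
fisherOracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    pObs <- dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# brute-force PWM scan: explicit per-window, per-position log-odds scoring
# on both strands, independent of the package's vectorized scanner
bruteScan <- function(seq, probs, background, pseudo, thresholdFraction) {
    bases <- c("A", "C", "G", "T")
    lo <- log2((probs + matrix(background * pseudo, nrow(probs), 4,
                               byrow = TRUE)) / (1 + pseudo) /
               matrix(background, nrow(probs), 4, byrow = TRUE))
    L <- nrow(probs)
    maxScore <- 0
    for (j in seq_len(L)) maxScore <- maxScore + max(lo[j, ])
    thr <- thresholdFraction * maxScore
    scoreAt <- function(s, off) {
        tot <- 0
        for (j in seq_len(L)) {
            b <- match(substr(s, off + j - 1, off + j - 1), bases)
            if (is.na(b)) return(-Inf)
            tot <- tot + lo[j, b]
        }
        tot
    }
    rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s),
                                         "")[[1]]), collapse = "")
    n <- nchar(seq)
    hits <- list()
    for (off in seq_len(n - L + 1)) {
        sF <- scoreAt(toupper(seq), off)
        if (sF >= thr)
            hits[[length(hits) + 1]] <- data.frame(offset = off,
                                                   strand = "+", score = sF)
        sR <- scoreAt(rc(toupper(seq)), off)
        if (sR >= thr)
            hits[[length(hits) + 1]] <- data.frame(
                offset = n - L + 1 - off + 1, strand = "-", score = sR)
    }
    out <- do.call(rbind, hits)
    if (is.null(out))
        return(data.frame(offset = integer(0), strand = character(0),
                          score = numeric(0)))
    out <- out[order(out$offset, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# greedy cross-age dedup oracle: literal per-interval reimplementation
dedupOracle <- function(perAge) {
    adm <- GRanges()
    ids <- character(0); disc <- character(0); active <- list()
    n <- 0
    for (age in names(perAge)) {
        gr <- perAge[[age]]
        gr <- gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
        for (i in seq_along(gr)) {
            hit <- which(bruteAnyOverlap(adm, gr[i]))
            if (length(hit) > 0) {
                for (h in hit) active[[ids[h]]] <- union(active[[ids[h]]], age)
            } else {
                n <- n + 1
                id <- sprintf("o%05d", n)
                adm <- c(adm, granges(gr[i]))
                ids <- c(ids, id); disc <- c(disc, age)
                active[[id]] <- age
            }
        }
    }
    list(ranges = adm, discovery = disc, active = unname(active))
}

# tiny config for fast unit tests
smallConfig <- function(seed = 1L, ...) {
    args <- list(...)
    defaults <- list(seed = seed, n_chroms = 2L, chrom_length = 6e5,
                     n_early = 10L, n_late = 10L, n_stable = 10L,
                     n_genes = 60L, n_tads = 60L, n_case_dnm = 200L,
                     n_sib_dnm = 200L, n_index_snps = 40L,
                     n_control_snps = 500L)
    do.call(syntheticConfig, modifyList(defaults, args))
}
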