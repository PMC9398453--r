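#' Log-odds scoring matrix of a motif
#'
#' Entry `log2((p + pseudo * bg) / (1 + pseudo) / bg)`; the pseudocount is
#' apportioned by the background composition so a zero-probability base gets
#' a finite negative score.
#'
#' @param pwm A [MotifPWM-class].
#' @return L x 4 numeric matrix (columns A, C, G, T).
#' @export
logOdds <- function(pwm) {
    bg <- pwm@background
    if (any(bg <= 0)) stopf("background frequencies must be strictly positive")
    p <- pwm@probs
    lo <- log2(sweep(sweep(p, 2, bg * pwm@pseudo, "+") / (1 + pwm@pseudo),
                     2, bg, "/"))
    colnames(lo) <- colnames(p)
    lo
}

.BASES <- c("A", "C", "G", "T")
.RCMAP <- c(A = "T", C = "G", G = "C", `T` = "A", N = "N")

.seqToIdx <- function(seq) {
    match(strsplit(toupper(seq), "")[[1]], .BASES)  # N and others -> NA
}

revComp <- function(seq) {
    paste(rev(.RCMAP[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# score all windows of idx (integer-coded sequence) against lo; windows with
# an ambiguous base score -Inf
.scanStrand <- function(idx, lo) {
    L <- nrow(lo)
    n <- length(idx) - L + 1
    if (n <= 0) return(numeric(0))
    sc <- rep(0, n)
    for (j in seq_len(L)) {
        b <- idx[j:(j + n - 1)]
        v <- lo[j, ][b]
        v[is.na(b)] <- -Inf
        sc <- sc + v
    }
    sc
}

#' Scan a sequence for motif hits on both strands
#'
#' Scores every window of motif length on the forward and reverse-complement
#' strand with the log-odds matrix and reports windows reaching
#' `thresholdFraction` of the maximum achievable score. Windows containing
#' an N never qualify. Offsets are 1-based positions of the window start on
#' the forward strand.
#'
#' @param seq nucleotide string.
#' @param pwm A [MotifPWM-class].
#' @param thresholdFraction fraction of the maximum log-odds score required
#'   for a hit (default 0.8).
#' @return data.frame with `offset`, `strand`, `score` (possibly 0 rows).
#' @export
scanSequence <- function(seq, pwm, thresholdFraction = 0.8) {
    stopifnot(thresholdFraction > 0, thresholdFraction <= 1)
    lo <- logOdds(pwm)
    L <- nrow(lo)
    maxScore <- sum(apply(lo, 1, max))
    thr <- thresholdFraction * maxScore
    idxF <- .seqToIdx(seq)
    if (length(idxF) < L)
        return(data.frame(offset = integer(0), strand = character(0),
                          score = numeric(0)))
    scF <- .scanStrand(idxF, lo)
    idxR <- .seqToIdx(revComp(seq))
    scR <- .scanStrand(idxR, lo)
    n <- length(scF)
    hitsF <- which(scF >= thr)
    hitsR <- which(scR >= thr)
    out <- data.frame(
        offset = c(hitsF, n - hitsR + 1L),  # map RC window to forward coords
        strand = c(rep("+", length(hitsF)), rep("-", length(hitsR))),
        score = c(scF[hitsF], scR[hitsR]),
        stringsAsFactors = FALSE)
    out[order(out$offset, out$strand), , drop = FALSE]
}

gcContent <- function(seq) {
    ch <- strsplit(toupper(seq), "")[[1]]
    acgt <- ch %in% .BASES
    if (!any(acgt)) return(NA_real_)
    sum(ch %in% c("G", "C")) / sum(acgt)
}

#' Select a GC-matched background sequence set
#'
#' For each target sequence, samples `ratio` pool sequences (without
#' replacement) whose GC fraction differs by at most `gcTolerance`; when a
#' target's stratum is exhausted the tolerance is doubled, with a warning,
#' until selection completes. Deterministic given `seed`.
#'
#' @param targets named character vector of target sequences.
#' @param pool named character vector of candidate background sequences.
#' @param gcTolerance initial absolute GC-fraction tolerance (default 0.02).
#' @param ratio background sequences per target (default 2).
#' @param seed integer seed.
#' @return named character vector of selected background sequences.
#' @export
selectBackground <- function(targets, pool, gcTolerance = 0.02, ratio = 2,
                             seed = 1L) {
    if (length(pool) == 0) stopf("empty background pool")
    gcT <- vapply(targets, gcContent, numeric(1))
    gcP <- vapply(pool, gcContent, numeric(1))
    chosen <- character(0)
    withSeed(childSeed(seed, "background"), {
        avail <- rep(TRUE, length(pool))
        for (i in seq_along(targets)) {
            tol <- gcTolerance
            for (r in seq_len(ratio)) {
                repeat {
                    ok <- which(avail & abs(gcP - gcT[i]) <= tol)
                    if (length(ok) > 0) break
                    if (!any(avail))
                        stopf("background pool exhausted")
                    tol <- tol * 2
                    warnf("GC tolerance relaxed to %.3f for target %d",
                          tol, i)
                }
                pick <- ok[sample.int(length(ok), 1)]
                avail[pick] <- FALSE
                chosen <- c(chosen, names(pool)[pick])
            }
        }
    })
    pool[chosen]
}

#' Cumulative-binomial motif enrichment for one motif
#'
#' Counts target sequences with at least one hit (`k`), estimates the
#' per-sequence hit probability `p0` from the background set (floored at
#' `1 / (2 * n_background)` so p0 is never zero), and computes the upper
#' binomial tail `P(X >= k)` with `X ~ Binomial(n_target, p0)`.
#'
#' @param targets,background named character vectors of sequences.
#' @param pwm A [MotifPWM-class].
#' @param thresholdFraction hit threshold, see [scanSequence()].
#' @return one-row data.frame: `motif_id`, `k_target`, `n_target`, `p0`,
#'   `p_binomial`.
#' @export
binomialEnrichment <- function(targets, background, pwm,
                               thresholdFraction = 0.8) {
    if (length(background) == 0) stopf("empty background set")
    hasHit <- function(s) nrow(scanSequence(s, pwm, thresholdFraction)) > 0
    k <- sum(vapply(targets, hasHit, logical(1)))
    n <- length(targets)
    bg <- mean(vapply(background, hasHit, logical(1)))
    p0 <- max(bg, 1 / (2 * length(background)))
    p0 <- min(p0, 1)
    p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    data.frame(motif_id = motifId(pwm), k_target = k, n_target = n,
               p0 = p0, p_binomial = p, stringsAsFactors = FALSE)
}

#' Motif enrichment over a motif library
#'
#' Runs [binomialEnrichment()] for every motif and applies
#' Benjamini-Hochberg adjustment across the library.
#'
#' @param targets,background named character vectors of sequences.
#' @param pwms list of [MotifPWM-class].
#' @param thresholdFraction hit threshold.
#' @return data.frame, one row per motif, with `p_adjusted` added.
#' @export
motifEnrichment <- function(targets, background, pwms,
                            thresholdFraction = 0.8) {
    res <- do.call(rbind, lapply(pwms, function(p)
        binomialEnrichment(targets, background, p, thresholdFraction)))
    res$p_adjusted <- p.adjust(res$p_binomial, method = "BH")
    rownames(res) <- NULL
    res
}

#' Filter and rank enriched motifs
#'
#' @param results data.frame from [motifEnrichment()].
#' @param alpha adjusted-p threshold (default 1e-11).
#' @return rows with `p_adjusted < alpha`, sorted ascending by `p_adjusted`,
#'   ties broken by `motif_id`.
#' @export
rankMotifs <- function(results, alpha = 1e-11) {
    keep <- results[results$p_adjusted < alpha, , drop = FALSE]
    keep <- keep[order(keep$p_adjusted, keep$motif_id), , drop = FALSE]
    rownames(keep) <- NULL
    keep
}
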