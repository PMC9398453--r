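#' Mean normalized H3K27ac signal at the anchor stages
#'
#' @param normalized numeric matrix from [normalizeCounts()].
#' @param design ChIP design rows.
#' @param ages ordered anchor stage labels (length 3).
#' @return matrix intervals x 3 of replicate-mean normalized signal, columns
#'   in stage order.
#' @export
anchorSignal <- function(normalized, design, ages) {
    stopifnot(length(ages) == 3)
    miss <- setdiff(ages, design$age)
    if (length(miss)) stopf("missing stage(s): %s", paste(miss, collapse = ", "))
    out <- vapply(ages, function(a) {
        cols <- rownames(design)[design$age == a]
        rowMeans(normalized[, cols, drop = FALSE])
    }, numeric(nrow(normalized)))
    if (is.null(dim(out)))  # single interval: vapply simplifies to a vector
        out <- matrix(out, nrow = 1,
                      dimnames = list(rownames(normalized), NULL))
    colnames(out) <- ages
    out
}

#' Pearson correlation of two length-3 profiles
#'
#' Returns `NA` (an "undefined" value, not an error) when either profile has
#' zero variance; undefined correlations are excluded from target
#' assignment rather than treated as zero.
#'
#' @param signal3,expr3 numeric vectors of length 3.
#' @return Pearson r in `[-1, 1]`, or `NA`.
#' @export
correlateProfiles <- function(signal3, expr3) {
    stopifnot(length(signal3) == 3, length(expr3) == 3)
    if (sd(signal3) == 0 || sd(expr3) == 0) return(NA_real_)
    cor(signal3, expr3)
}

#' Assign putative target genes to enhancers within shared TADs
#'
#' Candidate genes for an enhancer are those whose TSS lies in the same TAD
#' (enhancer membership by midpoint containment, TSS by position
#' containment; an enhancer spanning a TAD boundary follows its midpoint).
#' Candidates with a defined, strictly positive Pearson correlation between
#' the enhancer's anchor-stage H3K27ac signal and the gene's anchor-stage
#' expression are retained and ranked per enhancer by decreasing r, ties
#' broken lexicographically by gene id.
#'
#' @param enhancers [EnhancerSet-class] or GRanges with `enhancer_id`.
#' @param tads GRanges of TADs.
#' @param tss TSS table (data.frame).
#' @param signal matrix intervals x 3 from [anchorSignal()] (rownames =
#'   enhancer ids).
#' @param expression gene x timepoint matrix; must contain the three anchor
#'   stage columns.
#' @param ages anchor stage labels (default the signal's column names).
#' @return data.frame with `enhancer_id`, `gene_id`, `pearson_r`, `rank`.
#' @export
assignTargets <- function(enhancers, tads, tss, signal, expression,
                          ages = colnames(signal)) {
    gr <- if (is(enhancers, "EnhancerSet")) enhancerRanges(enhancers)
          else enhancers
    miss <- setdiff(ages, colnames(expression))
    if (length(miss))
        stopf("expression misses anchor column(s): %s",
              paste(miss, collapse = ", "))
    mid <- GRanges(seqnames(gr),
                   IRanges(floor((start(gr) + end(gr)) / 2),
                           floor((start(gr) + end(gr)) / 2)))
    enhTad <- findOverlaps(mid, tads, select = "first")
    tssGr <- tssToRanges(tss)
    tssTad <- findOverlaps(tssGr, tads, select = "first")
    genesByTad <- split(tss$gene_id, tssTad)
    rows <- vector("list", length(gr))
    for (i in seq_along(gr)) {
        td <- enhTad[i]
        if (is.na(td)) next
        cand <- genesByTad[[as.character(td)]]
        cand <- intersect(cand, rownames(expression))
        if (length(cand) == 0) next
        r <- vapply(cand, function(g)
            correlateProfiles(signal[gr$enhancer_id[i], ],
                              expression[g, ages]), numeric(1))
        keep <- !is.na(r) & r > 0
        if (!any(keep)) next
        cand <- cand[keep]; r <- r[keep]
        ord <- order(-r, cand)
        rows[[i]] <- data.frame(enhancer_id = gr$enhancer_id[i],
                                gene_id = cand[ord],
                                pearson_r = r[ord],
                                rank = seq_along(ord),
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(enhancer_id = character(0), gene_id = character(0),
                          pearson_r = numeric(0), rank = integer(0),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Permutation test for enrichment of an annotated gene set among targets
#'
#' Draws `nPerm` random gene sets of the target-set size from the expressed
#' universe (without replacement within a draw) and counts annotated genes
#' in each. The one-sided p-value is the fraction of permutations whose
#' count reaches the observed count; with `plusOne = TRUE` the conventional
#' `(k + 1) / (n + 1)` estimator is used instead. The null count is exactly
#' hypergeometric, which the test suite uses as the closed-form oracle.
#'
#' @param targetGenes character vector (subset of `universe`).
#' @param universe character vector of all eligible genes.
#' @param annotated character vector of annotated genes (subset of
#'   `universe`).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param plusOne use the (k+1)/(n+1) estimator (default FALSE).
#' @return list with `observed_count`, `n_perm`, `null_mean`, `null_sd`,
#'   `null_max`, `p_one_sided`, `null_counts`.
#' @export
permutationEnrichment <- function(targetGenes, universe, annotated,
                                  nPerm = 10000, seed = 1L,
                                  plusOne = FALSE) {
    if (length(universe) == 0) stopf("empty universe")
    stopifnot(all(targetGenes %in% universe), all(annotated %in% universe))
    observed <- length(intersect(targetGenes, annotated))
    isAnn <- universe %in% annotated
    k <- length(targetGenes)
    nullCounts <- withSeed(seed, {
        vapply(seq_len(nPerm), function(i)
            sum(isAnn[sample.int(length(universe), k)]), integer(1))
    })
    hits <- sum(nullCounts >= observed)
    p <- if (plusOne) (hits + 1) / (nPerm + 1) else hits / nPerm
    list(observed_count = observed, n_perm = nPerm,
         null_mean = mean(nullCounts), null_sd = sd(nullCounts),
         null_max = max(nullCounts), p_one_sided = p,
         null_counts = nullCounts)
}
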