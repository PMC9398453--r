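#' Replicate-consensus peaks
#'
#' Returns the peaks of replicate A that overlap (>= 1 bp) at least one peak
#' of replicate B, keeping replicate A's coordinates — the bedtools
#' `intersect -u` convention. Output is sorted genomically.
#'
#' @param repA,repB GRanges of peak calls for the two biological replicates.
#' @return GRanges subset of `repA`, sorted by (chrom, start, end).
#' @export
consensusPeaks <- function(repA, repB) {
    sortGenomic(repA[overlapsAny(repA, repB, ignore.strand = TRUE)])
}

#' Dual-mark overlap: H3K27ac peaks supported by H3K4me1
#'
#' Keeps H3K27ac peaks (coordinates unchanged) that overlap >= 1 bp with any
#' H3K4me1 peak at the same stage; the H3K27ac coordinates define the
#' enhancer.
#'
#' @param h3k27ac,h3k4me1 GRanges of replicate-consensus peaks for each mark.
#' @return GRanges subset of `h3k27ac`, sorted.
#' @export
intersectMarks <- function(h3k27ac, h3k4me1) {
    sortGenomic(h3k27ac[overlapsAny(h3k27ac, h3k4me1,
                                    ignore.strand = TRUE)])
}

#' Remove peaks near transcription start sites
#'
#' Excludes any peak overlapping the symmetric, strand-agnostic window of
#' `window` bp up- and downstream of a TSS (the TSS base itself is always
#' part of the window). With `window = 0` only peaks containing a TSS base
#' are removed.
#'
#' @param peaks GRanges of peaks.
#' @param tss data.frame from `readTable(..., "tss")` or a GRanges of
#'   single-base TSS positions.
#' @param window half-width of the exclusion window in bp (default 500).
#' @return GRanges of surviving peaks, coordinates untouched.
#' @export
excludePromoters <- function(peaks, tss, window = 500) {
    stopifnot(window >= 0)
    tssGr <- if (is.data.frame(tss)) tssToRanges(tss) else tss
    if (length(tssGr) == 0) return(peaks)
    win <- GRanges(seqnames(tssGr),
                   IRanges(pmax(1, start(tssGr) - window),
                           start(tssGr) + window))
    peaks[!overlapsAny(peaks, win, ignore.strand = TRUE)]
}

#' Deduplicate dual-mark peaks across developmental stages
#'
#' Iterates stages chronologically; a peak overlapping (>= 1 bp) a
#' previously admitted enhancer is not admitted again, but its stage is
#' appended to that enhancer's active-stage set. The earliest admission's
#' coordinates are kept. Enhancer ids are assigned deterministically: sorted
#' genomic order within stage, stages in the given order.
#'
#' @param perAge named list of GRanges, one per stage, in chronological
#'   order.
#' @return An [EnhancerSet-class].
#' @export
dedupAcrossAges <- function(perAge) {
    stopifnot(!is.null(names(perAge)))
    chroms <- character(0); starts <- integer(0); ends <- integer(0)
    ids <- character(0); disc <- character(0)
    active <- list()
    n <- 0L
    for (age in names(perAge)) {
        gr <- sortGenomic(granges(perAge[[age]]))
        if (length(gr) == 0) next
        admGr <- GRanges(chroms, IRanges(starts, ends))
        ov <- findOverlaps(gr, admGr, ignore.strand = TRUE)
        hitOld <- unique(queryHits(ov))
        for (h in unique(subjectHits(ov)))
            active[[ids[h]]] <- union(active[[ids[h]]], age)
        # greedy admission of the remainder, in sorted order: a candidate
        # is skipped if it overlaps an interval already admitted this age
        rest <- setdiff(seq_along(gr), hitOld)
        lastEnd <- list()
        for (i in rest) {
            ch <- as.character(seqnames(gr))[i]
            le <- lastEnd[[ch]]
            if (!is.null(le) && start(gr)[i] <= le) next  # same-age overlap

            n <- n + 1L
            id <- sprintf("enh_%05d", n)
            chroms <- c(chroms, ch)
            starts <- c(starts, start(gr)[i])
            ends <- c(ends, end(gr)[i])
            ids <- c(ids, id)
            disc <- c(disc, age)
            active[[id]] <- age
            lastEnd[[ch]] <- end(gr)[i]
        }
    }
    admitted <- GRanges(chroms, IRanges(starts, ends))
    mcols(admitted)$enhancer_id <- ids
    mcols(admitted)$discovery_age <- disc
    EnhancerSet(admitted, active)
}

#' Full enhancer-calling pipeline
#'
#' Fixed stage order: replicate consensus per mark, dual-mark overlap,
#' promoter exclusion, then cross-stage deduplication. Each stage only
#' removes or merges intervals; every output interval is present verbatim in
#' that stage's H3K27ac input.
#'
#' @param peaks named list `<age>.<mark>.rep<k>` of GRanges (as produced by
#'   [generatePeaksAndCounts()], or read from BED files).
#' @param tss TSS table (data.frame) for promoter exclusion.
#' @param ages chronological stage labels.
#' @param promoterWindow bp half-width of the TSS exclusion window.
#' @return An [EnhancerSet-class].
#' @export
callEnhancers <- function(peaks, tss, ages, promoterWindow = 500) {
    perAge <- list()
    for (age in ages) {
        k27 <- consensusPeaks(peaks[[paste(age, "H3K27ac", 1, sep = ".")]],
                              peaks[[paste(age, "H3K27ac", 2, sep = ".")]])
        k4 <- consensusPeaks(peaks[[paste(age, "H3K4me1", 1, sep = ".")]],
                             peaks[[paste(age, "H3K4me1", 2, sep = ".")]])
        dual <- intersectMarks(k27, k4)
        perAge[[age]] <- excludePromoters(dual, tss, promoterWindow)
    }
    dedupAcrossAges(perAge)
}

#' Annotate enhancers by overlap with labelled interval sets
#'
#' For each enhancer, collects the labels (the `name` column) of all
#' annotation intervals overlapping >= 1 bp; used e.g. to assign cell types
#' from single-nucleus ATAC-seq CREs or brain-region peak sets.
#'
#' @param enhancers An [EnhancerSet-class] or GRanges with `enhancer_id`.
#' @param annotation GRanges whose `name` column carries the labels.
#' @return named list mapping enhancer_id to a character vector of labels
#'   (possibly empty).
#' @export
annotateByOverlap <- function(enhancers, annotation) {
    gr <- if (is(enhancers, "EnhancerSet")) enhancerRanges(enhancers)
          else enhancers
    stopifnot(!is.null(annotation$name) || length(annotation) == 0)
    out <- setNames(vector("list", length(gr)), gr$enhancer_id)
    for (i in seq_along(out)) out[[i]] <- character(0)
    if (length(annotation) == 0) return(out)
    ov <- findOverlaps(gr, annotation, ignore.strand = TRUE)
    for (k in seq_along(ov)) {
        i <- queryHits(ov)[k]
        out[[i]] <- union(out[[i]],
                          as.character(annotation$name[subjectHits(ov)[k]]))
    }
    out
}
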