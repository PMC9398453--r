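#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps
#'   countOverlaps granges mcols mcols<- sort reduce
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowRanges
#' @importFrom stats approx cor fisher.test kmeans median p.adjust pbinom
#'   pnorm binom.test quantile rbinom rnbinom rnorm runif sd setNames var
#'   rpois dhyper phyper
#' @importFrom utils read.table write.table head
NULL

#' Robust enhancer set
#'
#' Container for a deduplicated set of robust enhancers: replicate-consensus
#' H3K27ac peaks overlapping H3K4me1 at the same developmental stage, outside
#' promoter windows, deduplicated across stages. Each enhancer keeps the
#' coordinates of its earliest admission (`discoveryAge`) and the set of
#' stages at which an overlapping dual-mark peak was observed (`agesActive`).
#'
#' @slot ranges A [GenomicRanges::GRanges] with one range per enhancer and
#'   metadata columns `enhancer_id` (unique character) and `discovery_age`.
#' @slot agesActive Named list mapping `enhancer_id` to a character vector of
#'   active stages; always contains the discovery age.
#'
#' @export
setClass("EnhancerSet",
    representation(ranges = "GRanges", agesActive = "list"))

setValidity("EnhancerSet", function(object) {
    msg <- character()
    ids <- object@ranges$enhancer_id
    if (is.null(ids))
        return("ranges must carry an 'enhancer_id' metadata column")
    if (anyDuplicated(ids))
        msg <- c(msg, "enhancer_id values must be unique")
    if (is.null(object@ranges$discovery_age))
        msg <- c(msg, "ranges must carry a 'discovery_age' metadata column")
    if (!setequal(names(object@agesActive), ids))
        msg <- c(msg, "agesActive must be named by enhancer_id")
    else {
        disc <- as.character(object@ranges$discovery_age)
        ok <- mapply(function(a, d) d %in% a,
                     object@agesActive[ids], disc)
        if (!all(ok))
            msg <- c(msg, "every discovery_age must appear in agesActive")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an EnhancerSet
#'
#' @param ranges GRanges with `enhancer_id` and `discovery_age` metadata
#'   columns.
#' @param agesActive named list of character vectors, one per enhancer id.
#' @return An [EnhancerSet-class] object.
#' @export
EnhancerSet <- function(ranges, agesActive) {
    new("EnhancerSet", ranges = ranges, agesActive = agesActive)
}

#' @describeIn EnhancerSet-class Number of enhancers.
#' @param x,object An `EnhancerSet`.
#' @export
setMethod("length", "EnhancerSet", function(x) length(x@ranges))

#' Accessors for EnhancerSet
#'
#' @param x An [EnhancerSet-class].
#' @return `enhancerRanges` the GRanges; `enhancerIds` the character vector of
#'   ids; `agesActive` the named list of active stages.
#' @export
enhancerRanges <- function(x) x@ranges

#' @rdname enhancerRanges
#' @export
enhancerIds <- function(x) as.character(x@ranges$enhancer_id)

#' @rdname enhancerRanges
#' @export
agesActive <- function(x) x@agesActive

setMethod("show", "EnhancerSet", function(object) {
    ages <- sort(unique(as.character(object@ranges$discovery_age)))
    cat("EnhancerSet with", length(object), "enhancers\n")
    cat("  discovery ages:", paste(ages, collapse = ", "), "\n")
    if (length(object) > 0) {
        cat("  first:", as.character(seqnames(object@ranges)[1]),
            paste0("[", start(object@ranges)[1], ", ",
                   end(object@ranges)[1], "]"),
            object@ranges$enhancer_id[1], "\n")
    }
})

#' ChIP-seq count experiment over enhancer intervals
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `counts` assay
#' holds non-negative integer read counts per interval per sample and whose
#' `colData` carries the sample design: `age` (stage label), `replicate`
#' (integer), `role` (`"chip"` or `"input"`) and optionally `paired_input`
#' (sample id of the matched input library).
#'
#' @export
setClass("ChIPCountSet", contains = "RangedSummarizedExperiment")

setValidity("ChIPCountSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- assay(object, "counts")
    if (any(m < 0) || any(m != round(m)))
        msg <- c(msg, "counts must be non-negative integers")
    cd <- colData(object)
    need <- c("age", "replicate", "role")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("colData misses column(s):",
                            paste(miss, collapse = ", ")))
    else {
        if (!all(cd$role %in% c("chip", "input")))
            msg <- c(msg, "role must be 'chip' or 'input'")
        if ("paired_input" %in% colnames(cd)) {
            pi <- cd$paired_input
            bad <- !is.na(pi) & !(pi %in% colnames(object)[cd$role == "input"])
            if (any(bad))
                msg <- c(msg, "paired_input must reference an input sample")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ChIPCountSet
#'
#' @param counts integer matrix (intervals x samples) with row and column
#'   names.
#' @param design data.frame with one row per sample (rownames = sample ids)
#'   and columns `age`, `replicate`, `role`, optionally `paired_input`.
#' @param rowRanges optional GRanges for the intervals.
#' @return A [ChIPCountSet-class].
#' @export
ChIPCountSet <- function(counts, design, rowRanges = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
    design <- DataFrame(design[colnames(counts), , drop = FALSE])
    if (is.null(rowRanges))  # placeholder ranges when intervals are abstract
        rowRanges <- GRanges(rep("unplaced", nrow(counts)),
                             IRanges(seq_len(nrow(counts)), width = 1))
    names(rowRanges) <- rownames(counts)
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = design, rowRanges = rowRanges)
    new("ChIPCountSet", se)
}

setMethod("show", "ChIPCountSet", function(object) {
    cd <- colData(object)
    cat("ChIPCountSet:", nrow(object), "intervals x", ncol(object),
        "samples\n")
    cat("  ages:", paste(unique(as.character(cd$age)), collapse = ", "),
        "| chip:", sum(cd$role == "chip"),
        "| input:", sum(cd$role == "input"), "\n")
})

#' Position weight matrix motif model
#'
#' Probabilistic model of a transcription-factor binding motif. `probs` is an
#' L x 4 matrix over (A, C, G, T) whose rows each sum to 1; `background` is
#' the genomic base composition used for log-odds scoring; `pseudo` is the
#' pseudocount weight mixed into each probability before taking logs.
#'
#' @slot motifId character scalar.
#' @slot probs L x 4 numeric matrix, columns A, C, G, T, rows summing to 1.
#' @slot background length-4 numeric, strictly positive, summing to 1.
#' @slot pseudo small positive numeric.
#' @export
setClass("MotifPWM",
    representation(motifId = "character", probs = "matrix",
                   background = "numeric", pseudo = "numeric"))

setValidity("MotifPWM", function(object) {
    msg <- character()
    p <- object@probs
    if (ncol(p) != 4 || !identical(colnames(p), c("A", "C", "G", "T")))
        msg <- c(msg, "probs must have columns A, C, G, T")
    if (nrow(p) < 4)
        msg <- c(msg, "motif length must be >= 4")
    if (any(p < 0))
        msg <- c(msg, "probabilities must be non-negative")
    if (ncol(p) == 4 && any(abs(rowSums(p) - 1) > 1e-6))
        msg <- c(msg, "each position's probabilities must sum to 1 (+-1e-6)")
    if (length(object@background) != 4 || any(object@background < 0))
        msg <- c(msg, "background must be 4 non-negative frequencies")
    if (length(object@pseudo) != 1 || object@pseudo <= 0)
        msg <- c(msg, "pseudo must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' Construct a MotifPWM
#'
#' @param motifId character id.
#' @param probs L x 4 matrix over A, C, G, T (rows sum to 1).
#' @param background base frequencies (default uniform).
#' @param pseudo pseudocount weight (default 0.01).
#' @return A [MotifPWM-class].
#' @export
MotifPWM <- function(motifId, probs, background = rep(0.25, 4),
                     pseudo = 0.01) {
    probs <- as.matrix(probs)
    colnames(probs) <- c("A", "C", "G", "T")
    new("MotifPWM", motifId = motifId, probs = probs,
        background = background, pseudo = pseudo)
}

setMethod("show", "MotifPWM", function(object) {
    cons <- paste(c("A", "C", "G", "T")[apply(object@probs, 1, which.max)],
                  collapse = "")
    cat("MotifPWM", object@motifId, "| length", nrow(object@probs),
        "| consensus", cons, "\n")
})

#' @rdname MotifPWM
#' @param x A `MotifPWM`.
#' @export
motifId <- function(x) x@motifId

#' @rdname MotifPWM
#' @export
motifProbs <- function(x) x@probs
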