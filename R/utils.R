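# Internal helpers shared across modules.

# Derive a reproducible child seed from a root seed and a stream name, so each
# module consumes its own random stream regardless of what other stages run.
# Kept below 2^31 - 1 (R integers are 32-bit).
childSeed <- function(seed, stream) {
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
    as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483587) + 1L
}

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Deterministic genomic sort order: chromosome name (lexicographic), start,
# end. Returns an index permutation.
genomicOrder <- function(gr) {
    order(as.character(seqnames(gr)), start(gr), end(gr))
}

sortGenomic <- function(gr) gr[genomicOrder(gr)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
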