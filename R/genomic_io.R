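#' Read a BED or narrowPeak file into a GRanges
#'
#' Parses BED3, BED6 or ENCODE narrowPeak (10-column) files. BED coordinates
#' are 0-based half-open on disk and are converted to the 1-based closed
#' convention of [GenomicRanges::GRanges] on read (start + 1); [writeBed()]
#' inverts the conversion, so a read/write round trip is exact. narrowPeak
#' signalValue/pValue/qValue and the summit offset (`peak`) are retained as
#' metadata columns but are never required downstream.
#'
#' Malformed lines are rejected with an error naming the offending line;
#' nothing is silently coerced.
#'
#' @param path file path.
#' @param dialect one of `"BED3"`, `"BED6"`, `"narrowPeak"`.
#' @return A `GRanges`; BED6/narrowPeak carry `name` and `score` metadata
#'   columns, narrowPeak additionally `signalValue`, `pValue`, `qValue`,
#'   `peak`.
#' @export
readBed <- function(path, dialect = c("BED6", "BED3", "narrowPeak")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stopf("file not found: %s", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    ncols <- switch(dialect, BED3 = 3L, BED6 = 6L, narrowPeak = 10L)
    if (length(lines) == 0) {
        gr <- GRanges()
        if (dialect != "BED3") {
            mcols(gr)$name <- character(0)
            mcols(gr)$score <- numeric(0)
        }
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < ncols)
    if (length(bad))
        stopf("line %d: expected >= %d tab-separated columns, found %d",
              lineno[bad[1]], ncols, nf[bad[1]])
    m <- do.call(rbind, lapply(fields, `[`, seq_len(ncols)))
    chrom <- m[, 1]
    startc <- suppressWarnings(as.numeric(m[, 2]))
    endc <- suppressWarnings(as.numeric(m[, 3]))
    bad <- which(is.na(startc) | is.na(endc))
    if (length(bad))
        stopf("line %d: non-numeric start/end", lineno[bad[1]])
    bad <- which(endc <= startc | startc < 0)
    if (length(bad))
        stopf("line %d: invalid interval [%s, %s) (need 0 <= start < end)",
              lineno[bad[1]], m[bad[1], 2], m[bad[1], 3])
    bad <- which(!nzchar(chrom))
    if (length(bad)) stopf("line %d: empty chromosome name", lineno[bad[1]])
    strand <- "*"
    meta <- list()
    if (dialect != "BED3") {
        strand <- m[, 6]
        strand[!strand %in% c("+", "-")] <- "*"
        score <- suppressWarnings(as.numeric(m[, 5]))
        score[m[, 5] == "."] <- NA_real_
        meta$name <- m[, 4]
        meta$score <- score
    }
    if (dialect == "narrowPeak") {
        meta$signalValue <- suppressWarnings(as.numeric(m[, 7]))
        meta$pValue <- suppressWarnings(as.numeric(m[, 8]))
        meta$qValue <- suppressWarnings(as.numeric(m[, 9]))
        meta$peak <- suppressWarnings(as.integer(m[, 10]))
    }
    gr <- GRanges(chrom, IRanges(start = startc + 1, end = endc),
                  strand = strand)
    for (nm in names(meta)) mcols(gr)[[nm]] <- meta[[nm]]
    gr
}

#' Write a GRanges to a sorted BED file
#'
#' Emits BED6 when `name` or `score` metadata are present, otherwise BED3.
#' Output is sorted by (chromosome, start, end) and byte-deterministic for
#' identical input. Coordinates are converted back to 0-based half-open.
#'
#' @param gr GRanges to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    gr <- sortGenomic(gr)
    has6 <- any(c("name", "score") %in% colnames(mcols(gr)))
    if (has6) {
        nm <- if (!is.null(gr$name)) as.character(gr$name)
              else rep(".", length(gr))
        sc <- if (!is.null(gr$score)) gr$score else rep(NA_real_, length(gr))
        scs <- ifelse(is.na(sc), ".",
                      ifelse(sc == round(sc), format(sc, scientific = FALSE,
                                                     trim = TRUE),
                             as.character(sc)))
        st <- as.character(strand(gr))
        st[st == "*"] <- "."
        out <- paste(as.character(seqnames(gr)), start(gr) - 1, end(gr),
                     nm, scs, st, sep = "\t")
    } else {
        out <- paste(as.character(seqnames(gr)), start(gr) - 1, end(gr),
                     sep = "\t")
    }
    writeLines(out, path)
    invisible(path)
}

.schemaCols <- list(
    tss = c("gene_id", "chrom", "position", "strand"),
    variants = c("chrom", "pos", "ref", "alt", "subject_id", "affected",
                 "vtype"),
    pwm = c("motif_id", "position", "A", "C", "G", "T")
)

#' Read a typed tab-separated table
#'
#' Reads one of the pipeline's tabular inputs with schema validation. All
#' tables are tab-separated with a mandatory header row; rows violating the
#' schema's invariants are rejected with an error naming the row, never
#' coerced.
#'
#' Schemas:
#' \describe{
#'   \item{expression}{`gene_id` + one numeric column per timepoint; returns
#'     a non-negative gene x timepoint matrix.}
#'   \item{counts}{`interval_id` + one integer column per sample; returns an
#'     integer matrix.}
#'   \item{tss}{`gene_id`, `chrom`, `position` (0-based), `strand`; gene ids
#'     must be unique.}
#'   \item{variants}{`chrom`, `pos` (1-based), `ref`, `alt`, `subject_id`,
#'     `affected` (logical), `vtype` in SNV/indel/CNV_del/CNV_dup, optional
#'     `end` (1-based inclusive, CNVs only, `end >= pos`). SNV ref/alt must
#'     be single bases.}
#'   \item{pwm}{long format `motif_id`, `position`, `A`, `C`, `G`, `T`; each
#'     position's probabilities must sum to 1 within 1e-6. Returns a list of
#'     [MotifPWM-class] objects.}
#' }
#'
#' @param path file path.
#' @param schema one of `"expression"`, `"counts"`, `"tss"`, `"variants"`,
#'   `"pwm"`.
#' @return See Details; matrices for expression/counts, data.frame for
#'   tss/variants, list of `MotifPWM` for pwm.
#' @export
readTable <- function(path, schema = c("expression", "counts", "tss",
                                       "variants", "pwm")) {
    schema <- match.arg(schema)
    if (!file.exists(path)) stopf("file not found: %s", path)
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE,
                     colClasses = "character")
    asNum <- function(cols, label) {
        for (cn in cols) {
            v <- suppressWarnings(as.numeric(df[[cn]]))
            bad <- which(is.na(v) & !is.na(df[[cn]]))
            if (length(bad))
                stopf("%s: non-numeric value '%s' in column '%s', row %d",
                      label, df[[cn]][bad[1]], cn, bad[1])
            df[[cn]] <<- v
        }
    }
    need <- function(cols) {
        miss <- setdiff(cols, colnames(df))
        if (length(miss))
            stopf("schema '%s': missing column(s): %s", schema,
                  paste(miss, collapse = ", "))
    }
    switch(schema,
    expression = {
        need("gene_id")
        tp <- setdiff(colnames(df), "gene_id")
        if (length(tp) == 0) stopf("expression table has no timepoint columns")
        asNum(tp, "expression")
        m <- as.matrix(df[, tp, drop = FALSE])
        rownames(m) <- df$gene_id
        if (any(m < 0)) stopf("expression values must be non-negative")
        m
    },
    counts = {
        need("interval_id")
        sm <- setdiff(colnames(df), "interval_id")
        if (length(sm) == 0) stopf("counts table has no sample columns")
        asNum(sm, "counts")
        m <- as.matrix(df[, sm, drop = FALSE])
        if (any(m < 0) || any(m != round(m)))
            stopf("counts must be non-negative integers")
        storage.mode(m) <- "integer"
        rownames(m) <- df$interval_id
        m
    },
    tss = {
        need(.schemaCols$tss)
        asNum("position", "tss")
        if (anyDuplicated(df$gene_id))
            stopf("tss: duplicate gene_id '%s'",
                  df$gene_id[anyDuplicated(df$gene_id)])
        if (any(df$position < 0)) stopf("tss: negative position")
        if (!all(df$strand %in% c("+", "-")))
            stopf("tss: strand must be '+' or '-'")
        df[, .schemaCols$tss]
    },
    variants = {
        need(.schemaCols$variants)
        asNum("pos", "variants")
        if ("end" %in% colnames(df)) asNum("end", "variants")
        else df$end <- NA_real_
        df$affected <- df$affected %in% c("TRUE", "True", "true", "1")
        ok <- df$vtype %in% c("SNV", "indel", "CNV_del", "CNV_dup")
        if (!all(ok)) stopf("variants: unknown vtype '%s' in row %d",
                            df$vtype[which(!ok)[1]], which(!ok)[1])
        cnv <- grepl("^CNV", df$vtype)
        bad <- which(cnv & (is.na(df$end) | df$end < df$pos))
        if (length(bad))
            stopf("variants: CNV in row %d needs end >= pos", bad[1])
        bad <- which(df$vtype == "SNV" &
                     (nchar(df$ref) != 1 | nchar(df$alt) != 1))
        if (length(bad))
            stopf("variants: SNV in row %d must have single-base ref/alt",
                  bad[1])
        if (any(df$pos < 1)) stopf("variants: pos must be >= 1")
        df[, c(.schemaCols$variants, "end")]
    },
    pwm = {
        need(.schemaCols$pwm)
        asNum(c("position", "A", "C", "G", "T"), "pwm")
        lapply(split(df, df$motif_id)[unique(df$motif_id)], function(d) {
            d <- d[order(d$position), ]
            p <- as.matrix(d[, c("A", "C", "G", "T")])
            bad <- which(abs(rowSums(p) - 1) > 1e-6)
            if (length(bad))
                stopf("pwm '%s': position %d probabilities sum to %.4f, not 1",
                      d$motif_id[1], d$position[bad[1]], rowSums(p)[bad[1]])
            MotifPWM(d$motif_id[1], p)
        })
    })
}

#' Write a typed table produced by the pipeline
#'
#' Inverse of [readTable()] for the matrix-valued schemas; writes a
#' deterministic tab-separated file with header.
#'
#' @param x matrix (expression/counts) or data.frame.
#' @param path output path.
#' @param idColumn name of the id column for matrices.
#' @return `path`, invisibly.
#' @export
writeTable <- function(x, path, idColumn = "gene_id") {
    if (is.matrix(x)) {
        df <- data.frame(rownames(x), x, check.names = FALSE,
                         stringsAsFactors = FALSE)
        colnames(df)[1] <- idColumn
    } else df <- x
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a FASTA file with strict alphabet validation
#'
#' Sequences are uppercased and keyed by the first whitespace-delimited token
#' of each header. Duplicate ids and characters outside `{A, C, G, T, N}` are
#' errors.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    ss <- readDNAStringSet(path)
    names(ss) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1)
    if (anyDuplicated(names(ss)))
        stopf("duplicate sequence id '%s'",
              names(ss)[anyDuplicated(names(ss))])
    chr <- toupper(as.character(ss))
    bad <- regexpr("[^ACGTN]", chr)
    if (any(bad > 0)) {
        i <- which(bad > 0)[1]
        stopf("illegal character '%s' in sequence '%s' at position %d",
              substr(chr[i], bad[i], bad[i]), names(ss)[i], bad[i])
    }
    DNAStringSet(setNames(chr, names(ss)))
}

#' Write sequences to FASTA
#'
#' @param seqs named DNAStringSet or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    if (is.character(seqs)) seqs <- DNAStringSet(seqs)
    writeXStringSet(seqs, path)
    invisible(path)
}

#' Convert variant records to genomic ranges
#'
#' Centralises the 1-based variant to interval conversion: an SNV/indel at
#' `pos` becomes the single-base range `[pos, pos]`; a CNV spanning
#' `[pos, end]` (1-based inclusive) keeps those bounds. In the 0-based
#' half-open convention these are `[pos-1, pos)` and `[pos-1, end)`.
#'
#' @param variants data.frame from `readTable(..., "variants")`.
#' @return GRanges with the variant columns as metadata.
#' @export
variantsToRanges <- function(variants) {
    vend <- ifelse(grepl("^CNV", variants$vtype), variants$end, variants$pos)
    gr <- GRanges(variants$chrom, IRanges(variants$pos, vend))
    mcols(gr) <- DataFrame(variants[, setdiff(colnames(variants),
                                              c("chrom", "pos", "end"))],
                           pos = variants$pos, end = vend)
    gr
}

#' Convert TSS records to genomic positions
#'
#' TSS tables store 0-based positions; the returned GRanges uses the 1-based
#' single-base range `[position + 1, position + 1]`.
#'
#' @param tss data.frame from `readTable(..., "tss")`.
#' @return GRanges named by `gene_id`.
#' @export
tssToRanges <- function(tss) {
    gr <- GRanges(tss$chrom, IRanges(tss$position + 1, tss$position + 1),
                  strand = tss$strand)
    names(gr) <- tss$gene_id
    gr$gene_id <- tss$gene_id
    gr
}
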