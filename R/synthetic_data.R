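#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: three
#' developmental stages (E12, P0, P9) profiled for two enhancer marks in two
#' biological replicates; negative-binomial read counts with a planted
#' four-fold activity change for Early/Late enhancers; a 12-timepoint
#' expression course correlated with enhancer signal for planted target
#' genes; TADs tiling each chromosome with each planted enhancer-gene pair
#' confined to one TAD; motif instances embedded in enhancer sequence; and
#' case/sibling de novo mutations with a planted enhancer burden.
#'
#' @param seed integer root seed; every generator output is a pure function
#'   of the configuration including this seed.
#' @param n_chroms,chrom_length genome shape (bp per chromosome).
#' @param n_early,n_late,n_stable planted enhancer counts per temporal class.
#' @param enhancer_width enhancer width in bp.
#' @param n_genes total genes; the first `n_early+n_late+n_stable` are planted
#'   targets (one per enhancer), the remainder decoys in other TADs.
#' @param n_tads total TADs (split evenly across chromosomes); must be at
#'   least the number of enhancers so each planted pair gets its own TAD.
#' @param ages ordered stage labels.
#' @param n_replicates biological replicates per stage and mark.
#' @param base_mean expected read count at a non-activated stage.
#' @param fold_change planted activity fold change at the activated stage
#'   (E12 for Early, P9 for Late); must exceed 1.
#' @param nb_dispersion negative-binomial dispersion alpha in the
#'   variance = m + alpha m^2 parameterisation.
#' @param n_timepoints_expr number of expression timepoints (anchor stages
#'   E12, P0, P9 are embedded in this grid).
#' @param expr_noise_sd Gaussian noise sd added to target-gene expression at
#'   the anchor stages (expression units). The default of 60 puts the
#'   enhancer-target correlation of dynamic (Early/Late) pairs near 0.9;
#'   set to 0 for the noiseless limit where planted correlations are exact.
#' @param motif_embed_rate probability an enhancer sequence carries an
#'   embedded instance of the planted motif.
#' @param background_hit_rate probability a non-enhancer background sequence
#'   carries an instance.
#' @param decoy_peak_rate fraction of replicate-discordant decoy peaks added
#'   per peak set (appear in exactly one replicate).
#' @param n_case_dnm,n_sib_dnm de novo mutation counts in affected cases and
#'   unaffected siblings.
#' @param dnm_enhancer_rate_case,dnm_enhancer_rate_sib probability a DNM
#'   falls inside an enhancer for cases and siblings.
#' @param n_index_snps,index_snp_enhancer_rate GWAS-style index SNPs and the
#'   fraction placed inside enhancers.
#' @param n_control_snps,control_snp_enhancer_rate matched-control SNP pool
#'   and its enhancer-overlap rate.
#' @return A validated `synthetic_config` list.
#' @export
syntheticConfig <- function(seed = 1L,
                            n_chroms = 2L, chrom_length = 3e6,
                            n_early = 100L, n_late = 100L, n_stable = 300L,
                            enhancer_width = 600L,
                            n_genes = 800L, n_tads = 600L,
                            ages = c("E12", "P0", "P9"),
                            n_replicates = 2L,
                            base_mean = 100, fold_change = 4,
                            nb_dispersion = 0.1,
                            n_timepoints_expr = 12L,
                            expr_noise_sd = 60,
                            motif_embed_rate = 0.6,
                            background_hit_rate = 0.05,
                            decoy_peak_rate = 0.1,
                            n_case_dnm = 1000L, n_sib_dnm = 1000L,
                            dnm_enhancer_rate_case = 0.2,
                            dnm_enhancer_rate_sib = 0.1,
                            n_index_snps = 100L,
                            index_snp_enhancer_rate = 0.5,
                            n_control_snps = 5000L,
                            control_snp_enhancer_rate = 0.05) {
    cfg <- as.list(environment())
    counts <- c("n_chroms", "n_early", "n_late", "n_stable", "n_genes",
                "n_tads", "n_replicates", "n_case_dnm", "n_sib_dnm",
                "n_index_snps", "n_control_snps")
    for (nm in counts)
        if (cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
    probs <- c("motif_embed_rate", "background_hit_rate", "decoy_peak_rate",
               "dnm_enhancer_rate_case", "dnm_enhancer_rate_sib",
               "index_snp_enhancer_rate", "control_snp_enhancer_rate")
    for (nm in probs)
        if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
            stopf("%s must be in [0, 1]", nm)
    if (fold_change < 1)
        stopf("fold_change must be >= 1 (1 = null, no planted effect)")
    if (base_mean <= 0 || nb_dispersion < 0)
        stopf("base_mean must be positive and nb_dispersion non-negative")
    nEnh <- n_early + n_late + n_stable
    if (n_tads > 0 && nEnh > n_tads)
        stopf("need n_tads >= total enhancers (%d) for one pair per TAD",
              nEnh)
    if (n_genes < nEnh)
        stopf("n_genes must be >= total enhancers (one target each)")
    if (length(ages) != 3) stopf("exactly 3 stage labels are required")
    if (n_timepoints_expr < 3) stopf("n_timepoints_expr must be >= 3")
    class(cfg) <- "synthetic_config"
    cfg
}

.enhClasses <- function(config) {
    rep(c("Early", "Late", "Neither"),
        c(config$n_early, config$n_late, config$n_stable))
}

# The planted transcription-factor motif: a 10-bp high-information PWM.
.plantedConsensus <- "TGACGTCATC"

#' The planted motif model used by the synthetic genome
#'
#' @param p probability mass on the consensus base at each position.
#' @return A [MotifPWM-class] for the embedded 10-mer.
#' @export
plantedMotifPWM <- function(p = 0.97) {
    bases <- c("A", "C", "G", "T")
    cons <- match(strsplit(.plantedConsensus, "")[[1]], bases)
    m <- matrix((1 - p) / 3, nrow = length(cons), ncol = 4,
                dimnames = list(NULL, bases))
    m[cbind(seq_along(cons), cons)] <- p
    MotifPWM("planted_motif", m)
}

#' Generate random decoy motif models
#'
#' Decoys are moderately informative PWMs over random consensus sequences,
#' used to exercise motif ranking against the planted motif.
#'
#' @param n number of decoys.
#' @param length motif length.
#' @param seed integer seed.
#' @return A list of [MotifPWM-class] objects named `decoy_01`, ...
#' @export
decoyMotifPWMs <- function(n = 20, length = 10, seed = 1L) {
    withSeed(childSeed(seed, "decoy_pwms"), {
        lapply(seq_len(n), function(i) {
            cons <- sample.int(4, length, replace = TRUE)
            m <- matrix(0.1, nrow = length, ncol = 4,
                        dimnames = list(NULL, c("A", "C", "G", "T")))
            m[cbind(seq_len(length), cons)] <- 0.7
            MotifPWM(sprintf("decoy_%02d", i), m)
        })
    })
}

#' Generate a synthetic genome with planted enhancers, TADs and targets
#'
#' Chromosomes are i.i.d. uniform A/C/G/T sequence tiled by equal-width,
#' non-overlapping TADs. Each planted enhancer is placed in its own TAD
#' together with its target gene's TSS (at least 500 bp apart); decoy genes
#' go to the remaining TADs. A planted 10-bp motif is embedded in a
#' `motif_embed_rate` fraction of enhancer sequences, with positions recorded
#' in the truth object.
#'
#' @param config a [syntheticConfig()] object.
#' @return list with elements `sequences` (DNAStringSet), `tss` (data.frame,
#'   0-based positions), `tads` (GRanges), `enhancers` (GRanges with
#'   `enhancer_id`), and `truth` (list with `enhancer_class`, `target_map`,
#'   `cluster_label`, `motif_positions`, `enriched_snp_ids`).
#' @export
generateGenome <- function(config) {
    stopifnot(inherits(config, "synthetic_config"))
    nEnh <- config$n_early + config$n_late + config$n_stable
    tadPerChrom <- config$n_tads %/% config$n_chroms
    if (config$n_tads %% config$n_chroms != 0)
        stopf("n_tads must be divisible by n_chroms")
    tadWidth <- floor(config$chrom_length / max(tadPerChrom, 1))
    if (config$n_tads > 0 && tadWidth < config$enhancer_width + 2000)
        stopf("TADs too narrow (%d bp) to place an enhancer and a TSS",
              tadWidth)
    chroms <- sprintf("chrS%d", seq_len(config$n_chroms))

    withSeed(childSeed(config$seed, "genome"), {
        sequences <- DNAStringSet(setNames(vapply(chroms, function(ch) {
            paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                         replace = TRUE), collapse = "")
        }, ""), chroms))

        tads <- GRanges()
        if (config$n_tads > 0) {
            tads <- GRanges(rep(chroms, each = tadPerChrom),
                            IRanges(start = rep((seq_len(tadPerChrom) - 1) *
                                                tadWidth + 1,
                                                config$n_chroms),
                                    width = tadWidth))
            tads$name <- sprintf("tad_%04d", seq_along(tads))
        }

        classes <- .enhClasses(config)
        enhancers <- GRanges()
        tss <- data.frame(gene_id = character(0), chrom = character(0),
                          position = numeric(0), strand = character(0))
        truth <- list(enhancer_class = setNames(character(0), character(0)),
                      target_map = setNames(character(0), character(0)),
                      cluster_label = setNames(integer(0), character(0)),
                      motif_positions = list(),
                      enriched_snp_ids = character(0))
        if (nEnh > 0) {
            # one planted pair per TAD; shuffle so classes mix across TADs
            pairTads <- sample(seq_along(tads), nEnh)
            w <- config$enhancer_width
            place <- function(i) {
                ts <- start(tads)[pairTads[i]]
                te <- end(tads)[pairTads[i]]
                for (try in 1:50) {
                    es <- ts + sample.int(te - ts + 1 - w - 1500, 1) - 1
                    # TSS at least 500 bp from the enhancer, inside the TAD
                    cand <- setdiff(seq(ts, te),
                                    seq(max(ts, es - 500),
                                        min(te, es + w - 1 + 500)))
                    if (length(cand) > 0)
                        return(c(es, cand[sample.int(length(cand), 1)]))
                }
                stopf("could not place enhancer %d in its TAD", i)
            }
            pos <- vapply(seq_len(nEnh), place, numeric(2))
            ids <- sprintf("enh_%04d", seq_len(nEnh))
            geneIds <- sprintf("gene_%04d", seq_len(config$n_genes))
            enhancers <- GRanges(as.character(seqnames(tads))[pairTads],
                                 IRanges(start = pos[1, ], width = w))
            enhancers$enhancer_id <- ids
            tss <- data.frame(gene_id = geneIds[seq_len(nEnh)],
                              chrom = as.character(seqnames(enhancers)),
                              position = pos[2, ] - 1,  # 0-based on disk
                              strand = sample(c("+", "-"), nEnh,
                                              replace = TRUE),
                              stringsAsFactors = FALSE)
            # decoy genes in TADs without a planted pair
            nDecoy <- config$n_genes - nEnh
            if (nDecoy > 0) {
                freeTads <- setdiff(seq_along(tads), pairTads)
                dt <- sample(rep(freeTads, length.out = nDecoy))
                dpos <- start(tads)[dt] +
                    floor(runif(nDecoy) * (width(tads)[dt] - 1))
                tss <- rbind(tss, data.frame(
                    gene_id = geneIds[(nEnh + 1):config$n_genes],
                    chrom = as.character(seqnames(tads))[dt],
                    position = dpos - 1,
                    strand = sample(c("+", "-"), nDecoy, replace = TRUE),
                    stringsAsFactors = FALSE))
            }
            # embed the planted motif in a subset of enhancer sequences
            motifPositions <- list()
            embed <- runif(nEnh) < config$motif_embed_rate
            mot <- .plantedConsensus
            motRc <- paste(rev(c(A = "T", C = "G", G = "C", `T` = "A")[
                strsplit(mot, "")[[1]]]), collapse = "")
            chrSeq <- setNames(as.character(sequences), chroms)
            embedAt <- lapply(setNames(nm = chroms), function(x) integer(0))
            embedIns <- lapply(setNames(nm = chroms), function(x) character(0))
            for (i in which(embed)) {
                off <- sample.int(w - nchar(mot) + 1, 1)  # 1-based offset
                strandHit <- sample(c("+", "-"), 1)
                ch <- as.character(seqnames(enhancers))[i]
                at <- start(enhancers)[i] + off - 1
                embedAt[[ch]] <- c(embedAt[[ch]], at)
                embedIns[[ch]] <- c(embedIns[[ch]],
                                    if (strandHit == "+") mot else motRc)
                motifPositions[[ids[i]]] <-
                    list(offset = off, strand = strandHit)
            }
            # splice all insertions per chromosome in one rebuild
            for (ch in chroms) {
                at <- embedAt[[ch]]
                if (length(at) == 0) next
                o <- order(at)
                at <- at[o]; ins <- embedIns[[ch]][o]
                s <- chrSeq[[ch]]
                gaps <- substring(s, c(1, at + nchar(mot)),
                                  c(at - 1, nchar(s)))
                pieces <- character(2 * length(at) + 1)
                pieces[seq(1, length(pieces), 2)] <- gaps
                pieces[seq(2, length(pieces), 2)] <- ins
                chrSeq[[ch]] <- paste(pieces, collapse = "")
            }
            sequences <- DNAStringSet(chrSeq)
            clusterLabel <- .assignClusterLabels(classes, nEnh)
            truth <- list(
                enhancer_class = setNames(classes, ids),
                target_map = setNames(geneIds[seq_len(nEnh)], ids),
                cluster_label = setNames(clusterLabel,
                                         geneIds[seq_len(nEnh)]),
                motif_positions = motifPositions,
                enriched_snp_ids = character(0))
        }
        list(sequences = sequences, tss = tss, tads = tads,
             enhancers = enhancers, truth = truth)
    })
}

# Four co-expression programs: Early and Late targets each split into a
# convex and a concave interpolation shape between the anchor stages.
.assignClusterLabels <- function(classes, nEnh) {
    lab <- integer(nEnh)
    half <- function(idx, a, b) {
        out <- integer(length(idx))
        out[seq_along(idx) %% 2 == 1] <- a
        out[seq_along(idx) %% 2 == 0] <- b
        out
    }
    lab[classes == "Early"] <- half(which(classes == "Early"), 1L, 2L)
    lab[classes == "Late"] <- half(which(classes == "Late"), 3L, 4L)
    lab
}

#' Generate per-age peak sets and the NB count matrix
#'
#' Every planted enhancer yields an H3K27ac and an H3K4me1 peak in both
#' replicates at every stage; activity differences are encoded in the counts.
#' Per-sample H3K27ac counts are drawn from a negative binomial with mean
#' `base_mean * fold_change^(stage is the planted-high stage)` and dispersion
#' `nb_dispersion`. A `decoy_peak_rate` fraction of replicate-discordant
#' decoy peaks (present in exactly one replicate) is added to each peak set
#' to exercise the consensus step.
#'
#' @param config a [syntheticConfig()].
#' @param genome output of [generateGenome()] for the same config.
#' @return list with `peaks` (named list `<age>.<mark>.rep<k>` of GRanges)
#'   and `counts` (a [ChIPCountSet-class] over the planted enhancers).
#' @export
generatePeaksAndCounts <- function(config, genome) {
    enh <- genome$enhancers
    classes <- genome$truth$enhancer_class
    nEnh <- length(enh)
    marks <- c("H3K27ac", "H3K4me1")
    withSeed(childSeed(config$seed, "peaks_counts"), {
        peaks <- list()
        for (age in config$ages) for (mark in marks)
            for (rep_ in seq_len(config$n_replicates)) {
                gr <- granges(enh)
                nDecoy <- round(config$decoy_peak_rate * max(nEnh, 1))
                if (nDecoy > 0 && rep_ == 1) {
                    # decoys only in replicate 1: discordant by construction
                    dch <- sample(names(genome$sequences), nDecoy,
                                  replace = TRUE)
                    dst <- floor(runif(nDecoy) *
                                 (config$chrom_length -
                                  config$enhancer_width)) + 1
                    dec <- GRanges(dch, IRanges(start = dst,
                                                width = config$enhancer_width))
                    dec <- dec[!overlapsAny(dec, enh)]
                    gr <- c(gr, dec)
                }
                gr <- sortGenomic(gr)
                gr$name <- sprintf("%s_%s_rep%d_pk%05d", age, mark, rep_,
                                   seq_along(gr))
                gr$score <- rep(0, length(gr))
                peaks[[paste(age, mark, rep_, sep = ".")]] <- gr
            }
        highAge <- ifelse(classes == "Early", config$ages[1],
                          ifelse(classes == "Late", config$ages[3], ""))
        samples <- expand.grid(rep_ = seq_len(config$n_replicates),
                               age = config$ages,
                               stringsAsFactors = FALSE)
        sampleIds <- sprintf("H3K27ac_%s_rep%d", samples$age, samples$rep_)
        cnt <- matrix(0L, nrow = nEnh, ncol = nrow(samples),
                      dimnames = list(enh$enhancer_id, sampleIds))
        for (j in seq_len(nrow(samples))) {
            mu <- config$base_mean *
                ifelse(highAge == samples$age[j], config$fold_change, 1)
            cnt[, j] <- if (config$nb_dispersion > 0)
                rnbinom(nEnh, mu = mu, size = 1 / config$nb_dispersion)
            else rpois(nEnh, mu)
        }
        design <- data.frame(age = samples$age, replicate = samples$rep_,
                             role = "chip", row.names = sampleIds,
                             stringsAsFactors = FALSE)
        list(peaks = peaks,
             counts = ChIPCountSet(cnt, design, rowRanges = enh))
    })
}

#' Generate the 12-timepoint expression table
#'
#' Planted target genes follow an affine transform of their enhancer's mean
#' normalized H3K27ac signal at the three anchor stages, plus Gaussian noise
#' (`expr_noise_sd`), interpolated across the full timepoint grid with a
#' cluster-specific curvature (four co-expression programs). Decoy genes get
#' smooth random profiles built independently of every enhancer. Values are
#' clipped at zero.
#'
#' @param config a [syntheticConfig()].
#' @param genome output of [generateGenome()].
#' @param counts the [ChIPCountSet-class] from [generatePeaksAndCounts()].
#' @return numeric matrix genes x timepoints; anchor stages appear as columns
#'   named by their stage label.
#' @export
generateExpression <- function(config, genome, counts) {
    tpLabels <- .timepointLabels(config)
    anchorIdx <- match(config$ages, tpLabels)
    geneIds <- genome$tss$gene_id
    nEnh <- length(genome$enhancers)
    expr <- matrix(0, nrow = length(geneIds), ncol = length(tpLabels),
                   dimnames = list(geneIds, tpLabels))
    norm <- normalizeCounts(counts)
    sig <- vapply(config$ages, function(a) {
        cols <- colData(counts)$age == a & colData(counts)$role == "chip"
        rowMeans(norm$normalized[, cols, drop = FALSE])
    }, numeric(max(nEnh, 0)))
    withSeed(childSeed(config$seed, "expression"), {
        grid <- seq_along(tpLabels)
        for (i in seq_len(nEnh)) {
            gid <- genome$truth$target_map[[i]]
            a <- runif(1, 0.5, 2)
            b <- runif(1, 0, 50)
            anchors <- a * sig[i, ] + b +
                rnorm(3, 0, config$expr_noise_sd)
            lab <- genome$truth$cluster_label[[gid]]
            gamma <- if (lab %in% c(1L, 3L)) 0.35 else 2.8
            expr[gid, ] <- .curvedInterp(anchors, anchorIdx, grid, gamma)
        }
        decoys <- setdiff(geneIds, unname(genome$truth$target_map))
        for (gid in decoys) {
            # smooth random profile, independent of all enhancer signal
            knots <- runif(3, 0, 200)
            expr[gid, ] <- .curvedInterp(knots, anchorIdx, grid, 1) +
                rnorm(length(grid), 0, 5)
        }
    })
    pmax(expr, 0)
}

.timepointLabels <- function(config) {
    n <- config$n_timepoints_expr
    if (n == 12) c("E11", "E12", "E13", "E14", "E15", "E16", "E17", "E18",
                   "P0", "P3", "P6", "P9")
    else {
        lab <- sprintf("t%02d", seq_len(n))
        lab[1 + 0] <- lab[1]
        # embed the anchors at the start, middle and end of the grid
        lab[c(1, ceiling(n / 2), n)] <- config$ages
        lab
    }
}

# Piecewise interpolation through the anchor values with a power curvature
# between consecutive anchors; flat extrapolation outside. Anchor positions
# reproduce their values exactly.
.curvedInterp <- function(anchors, anchorIdx, grid, gamma) {
    out <- numeric(length(grid))
    for (g in seq_along(grid)) {
        x <- grid[g]
        if (x <= anchorIdx[1]) out[g] <- anchors[1]
        else if (x >= anchorIdx[length(anchorIdx)])
            out[g] <- anchors[length(anchors)]
        else {
            k <- max(which(anchorIdx <= x))
            f <- (x - anchorIdx[k]) / (anchorIdx[k + 1] - anchorIdx[k])
            out[g] <- anchors[k] + (anchors[k + 1] - anchors[k]) * f^gamma
        }
    }
    out
}

#' Generate de novo mutations and GWAS-style SNPs with planted enrichment
#'
#' Case DNMs fall inside enhancers with probability
#' `dnm_enhancer_rate_case`, sibling DNMs with `dnm_enhancer_rate_sib`; the
#' remainder land uniformly on the non-enhancer genome. Index SNPs are
#' emitted with a planted in-enhancer fraction and a large matched-control
#' pool with a background rate; the in-enhancer index SNPs are recorded in
#' `truth$enriched_snp_ids`.
#'
#' @param config a [syntheticConfig()].
#' @param genome output of [generateGenome()].
#' @return list with `dnms` (variants data.frame), `index_snps`,
#'   `control_snps` (data.frames with `snp_id`, `chrom`, `pos`), and
#'   `enriched_snp_ids`.
#' @export
generateVariants <- function(config, genome) {
    enh <- genome$enhancers
    chroms <- names(genome$sequences)
    withSeed(childSeed(config$seed, "variants"), {
        placePos <- function(n, rate) {
            inEnh <- runif(n) < rate
            pos <- matrix(NA_real_, n, 2)
            chs <- character(n)
            if (any(inEnh) && length(enh) > 0) {
                k <- sample.int(length(enh), sum(inEnh), replace = TRUE)
                chs[inEnh] <- as.character(seqnames(enh))[k]
                pos[inEnh, 1] <- start(enh)[k] +
                    floor(runif(sum(inEnh)) * width(enh)[k])
            }
            out <- which(!inEnh | length(enh) == 0)
            while (length(out) > 0) {
                ch <- sample(chroms, length(out), replace = TRUE)
                p <- floor(runif(length(out)) * config$chrom_length) + 1
                cand <- GRanges(ch, IRanges(p, p))
                ok <- !overlapsAny(cand, enh)
                chs[out[ok]] <- ch[ok]
                pos[out[ok], 1] <- p[ok]
                out <- out[!ok]
            }
            data.frame(chrom = chs, pos = pos[, 1],
                       stringsAsFactors = FALSE)
        }
        mkDnm <- function(n, rate, affected, prefix) {
            if (n == 0)
                return(data.frame(chrom = character(0), pos = numeric(0),
                                  ref = character(0), alt = character(0),
                                  subject_id = character(0),
                                  affected = logical(0),
                                  vtype = character(0), end = numeric(0)))
            loc <- placePos(n, rate)
            bases <- c("A", "C", "G", "T")
            ref <- sample(bases, n, replace = TRUE)
            alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
            data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref,
                       alt = alt,
                       subject_id = sprintf("%s%03d", prefix,
                                            (seq_len(n) - 1) %% 100 + 1),
                       affected = affected, vtype = "SNV",
                       end = NA_real_, stringsAsFactors = FALSE)
        }
        dnms <- rbind(mkDnm(config$n_case_dnm, config$dnm_enhancer_rate_case,
                            TRUE, "case"),
                      mkDnm(config$n_sib_dnm, config$dnm_enhancer_rate_sib,
                            FALSE, "sib"))
        idx <- placePos(config$n_index_snps, config$index_snp_enhancer_rate)
        indexSnps <- data.frame(snp_id = sprintf("rsIDX%04d",
                                                 seq_len(config$n_index_snps)),
                                idx, stringsAsFactors = FALSE)
        ctl <- placePos(config$n_control_snps,
                        config$control_snp_enhancer_rate)
        controlSnps <- data.frame(snp_id = sprintf("rsCTL%05d",
                                                   seq_len(config$n_control_snps)),
                                  ctl, stringsAsFactors = FALSE)
        inEnh <- if (length(enh) && nrow(indexSnps))
            overlapsAny(GRanges(indexSnps$chrom,
                                IRanges(indexSnps$pos, indexSnps$pos)), enh)
        else logical(0)
        list(dnms = dnms, index_snps = indexSnps,
             control_snps = controlSnps,
             enriched_snp_ids = indexSnps$snp_id[inEnh])
    })
}

#' Write a complete synthetic fixture directory
#'
#' Runs all generators and serialises every output through the package's
#' standard formats (BED for peaks/TADs/enhancers, FASTA for the genome, TSV
#' for tables, JSON for the planted truth), so that downstream stages can be
#' exercised end-to-end from files.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly; files: `genome.fa`, `tss.tsv`, `tads.bed`,
#'   `peaks/<age>.<mark>.rep<k>.bed`, `counts.tsv`, `design.tsv`,
#'   `expression.tsv`, `variants.tsv`, `index_snps.tsv`,
#'   `control_snps.tsv`, `pwms.tsv`, `truth.json`.
#' @export
simulateFixtures <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
    genome <- generateGenome(config)
    pc <- generatePeaksAndCounts(config, genome)
    expr <- generateExpression(config, genome, pc$counts)
    vars <- generateVariants(config, genome)
    genome$truth$enriched_snp_ids <- vars$enriched_snp_ids

    writeFasta(genome$sequences, file.path(dir, "genome.fa"))
    writeTable(genome$tss, file.path(dir, "tss.tsv"))
    writeBed(genome$tads, file.path(dir, "tads.bed"))
    enhBed <- genome$enhancers
    if (length(enhBed) > 0) {
        enhBed$name <- enhBed$enhancer_id
        enhBed$score <- rep(0, length(enhBed))
    }
    writeBed(enhBed, file.path(dir, "planted_enhancers.bed"))
    for (nm in names(pc$peaks))
        writeBed(pc$peaks[[nm]], file.path(dir, "peaks",
                                           paste0(nm, ".bed")))
    writeTable(assay(pc$counts, "counts"), file.path(dir, "counts.tsv"),
               idColumn = "interval_id")
    design <- as.data.frame(colData(pc$counts))
    design <- data.frame(sample_id = rownames(design), design,
                         stringsAsFactors = FALSE)
    writeTable(design, file.path(dir, "design.tsv"))
    writeTable(expr, file.path(dir, "expression.tsv"))
    writeTable(vars$dnms, file.path(dir, "variants.tsv"))
    writeTable(vars$index_snps, file.path(dir, "index_snps.tsv"))
    writeTable(vars$control_snps, file.path(dir, "control_snps.tsv"))
    pwms <- c(list(plantedMotifPWM()), decoyMotifPWMs(seed = config$seed))
    writePwmTable(pwms, file.path(dir, "pwms.tsv"))
    truth <- genome$truth
    truth$enhancer_class <- as.list(truth$enhancer_class)
    truth$target_map <- as.list(truth$target_map)
    truth$cluster_label <- as.list(truth$cluster_label)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Write motif models as a long-format PWM table
#'
#' @param pwms list of [MotifPWM-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePwmTable <- function(pwms, path) {
    rows <- do.call(rbind, lapply(pwms, function(p) {
        data.frame(motif_id = motifId(p),
                   position = seq_len(nrow(motifProbs(p))),
                   motifProbs(p), check.names = FALSE,
                   stringsAsFactors = FALSE)
    }))
    writeTable(rows, path)
}

#' Extract enhancer sequences from a genome
#'
#' @param sequences named DNAStringSet of chromosomes.
#' @param gr GRanges of regions (1-based closed).
#' @return named character vector of region sequences.
#' @export
extractSequences <- function(sequences, gr) {
    nm <- if (!is.null(gr$enhancer_id)) gr$enhancer_id
          else if (!is.null(gr$name)) gr$name
          else sprintf("region_%05d", seq_along(gr))
    out <- vapply(seq_along(gr), function(i) {
        ch <- as.character(seqnames(gr))[i]
        substr(as.character(sequences[[ch]]), start(gr)[i], end(gr)[i])
    }, "")
    setNames(out, nm)
}
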