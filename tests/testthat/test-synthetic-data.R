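test_that("generator output is a pure function of config and seed", {
    cfg <- smallConfig(seed = 5)
    g1 <- generateGenome(cfg)
    g2 <- generateGenome(cfg)
    expect_identical(as.character(g1$sequences), as.character(g2$sequences))
    expect_identical(g1$tss, g2$tss)
    expect_identical(g1$truth, g2$truth)
    p1 <- generatePeaksAndCounts(cfg, g1)
    p2 <- generatePeaksAndCounts(cfg, g2)
    expect_identical(SummarizedExperiment::assay(p1$counts),
                     SummarizedExperiment::assay(p2$counts))
})

test_that("zero-enhancer config yields empty sets and truth maps", {
    cfg <- smallConfig(n_early = 0L, n_late = 0L, n_stable = 0L,
                       n_genes = 10L)
    g <- generateGenome(cfg)
    expect_length(g$enhancers, 0)
    expect_length(g$truth$enhancer_class, 0)
    expect_length(g$truth$target_map, 0)
})

test_that("every planted enhancer-target pair shares a TAD (containment oracle)", {
    cfg <- smallConfig(seed = 3, n_early = 20L, n_late = 20L,
                       n_stable = 10L, n_genes = 70L, n_tads = 60L)
    g <- generateGenome(cfg)
    ch <- as.character(seqnames(g$tads))
    ts <- start(g$tads); te <- end(g$tads)
    shared <- vapply(seq_along(g$enhancers), function(i) {
        eid <- g$enhancers$enhancer_id[i]
        gid <- g$truth$target_map[[eid]]
        trow <- g$tss[g$tss$gene_id == gid, ]
        tpos <- trow$position + 1
        # independent containment check against every TAD
        inE <- which(ch == as.character(seqnames(g$enhancers))[i] &
                     ts <= start(g$enhancers)[i] &
                     te >= end(g$enhancers)[i])
        inT <- which(ch == trow$chrom & ts <= tpos & te >= tpos)
        length(intersect(inE, inT)) > 0
    }, logical(1))
    expect_true(all(shared))
    # enhancers keep >= 500 bp distance from every TSS
    tssGr <- tssToRanges(g$tss)
    near <- GenomicRanges::distanceToNearest(g$enhancers, tssGr)
    expect_true(all(S4Vectors::mcols(near)$distance >= 500))
})

test_that("peak bookkeeping: ages x marks x replicates sets, decoys discordant", {
    cfg <- smallConfig(seed = 2)
    g <- generateGenome(cfg)
    pc <- generatePeaksAndCounts(cfg, g)
    expect_length(pc$peaks, 3 * 2 * 2)
    # replicate-1 decoys never overlap planted enhancers and are absent in rep2
    k1 <- pc$peaks[["E12.H3K27ac.1"]]
    k2 <- pc$peaks[["E12.H3K27ac.2"]]
    expect_gt(length(k1), length(k2))
    dec <- k1[!bruteAnyOverlap(k1, g$enhancers)]
    expect_false(any(bruteAnyOverlap(dec, k2)))
})

test_that("NB counts honor the planted fold change and the null", {
    cfg <- syntheticConfig(seed = 4, n_early = 500L, n_late = 0L,
                           n_stable = 0L, n_genes = 500L, n_tads = 600L,
                           base_mean = 100, fold_change = 4)
    g <- generateGenome(cfg)
    pc <- generatePeaksAndCounts(cfg, g)
    m <- SummarizedExperiment::assay(pc$counts)
    e12 <- rowMeans(m[, grepl("E12", colnames(m))])
    expect_lt(abs(mean(e12) - 400) / 400, 0.1)
    p9 <- rowMeans(m[, grepl("P9", colnames(m))])
    expect_lt(abs(mean(p9) - 100) / 100, 0.1)

    # fold_change = 1: per-age empirical means within 3 SE of each other
    cfg0 <- smallConfig(seed = 6, n_early = 200L, n_late = 0L,
                        n_stable = 0L, n_genes = 200L, n_tads = 400L,
                        chrom_length = 4e6, fold_change = 1)
    g0 <- generateGenome(cfg0)
    m0 <- SummarizedExperiment::assay(generatePeaksAndCounts(cfg0, g0)$counts)
    byAge <- vapply(c("E12", "P0", "P9"), function(a)
        mean(m0[, grepl(a, colnames(m0))]), numeric(1))
    se <- sd(as.vector(m0)) / sqrt(2 * nrow(m0))
    expect_lt(max(byAge) - min(byAge), 6 * se)
})

test_that("noiseless expression is an exact affine image of enhancer signal", {
    cfg <- smallConfig(seed = 8, n_early = 15L, n_late = 15L,
                       n_stable = 0L, n_genes = 40L, expr_noise_sd = 0)
    g <- generateGenome(cfg)
    pc <- generatePeaksAndCounts(cfg, g)
    e <- generateExpression(cfg, g, pc$counts)
    expect_equal(ncol(e), 12)
    norm <- normalizeCounts(pc$counts)
    sig <- anchorSignal(norm$normalized, norm$design, cfg$ages)
    r <- vapply(seq_along(g$enhancers), function(i) {
        gid <- g$truth$target_map[[g$enhancers$enhancer_id[i]]]
        cor(sig[i, ], e[gid, cfg$ages])
    }, numeric(1))
    expect_equal(r, rep(1, length(r)), tolerance = 1e-12)
})

test_that("cluster templates are recovered in the generated profiles", {
    cfg <- smallConfig(seed = 10, n_early = 40L, n_late = 40L,
                       n_stable = 0L, n_genes = 100L, n_tads = 100L,
                       chrom_length = 1e6, expr_noise_sd = 10)
    g <- generateGenome(cfg)
    pc <- generatePeaksAndCounts(cfg, g)
    e <- generateExpression(cfg, g, pc$counts)
    lab <- g$truth$cluster_label
    genes <- names(lab)[lab > 0]
    z <- zscoreRows(e[genes, ])
    # genes sharing a template correlate better within than across clusters
    cl <- lab[rownames(z)]
    cm <- cor(t(z))
    within <- mean(cm[outer(cl, cl, "==") & upper.tri(cm)])
    across <- mean(cm[outer(cl, cl, "!=") & upper.tri(cm)])
    expect_gt(within, across + 0.3)
})

test_that("variant planting obeys the configured rates", {
    cfg <- smallConfig(seed = 12, n_case_dnm = 1000L,
                       dnm_enhancer_rate_case = 0.2,
                       dnm_enhancer_rate_sib = 0)
    g <- generateGenome(cfg)
    v <- generateVariants(cfg, g)
    dn <- v$dnms
    gr <- GRanges(dn$chrom, IRanges(dn$pos, dn$pos))
    inEnh <- bruteAnyOverlap(gr, g$enhancers)
    # zero-rate group never lands in enhancers
    expect_equal(sum(inEnh & !dn$affected), 0)
    # binomial bound on the planted group
    nCase <- sum(dn$affected)
    obs <- sum(inEnh & dn$affected)
    expect_lt(abs(obs - 0.2 * nCase), 3 * sqrt(nCase * 0.2 * 0.8))
})

test_that("equal case/sibling rates give a null odds ratio on average", {
    ors <- vapply(1:10, function(s) {
        cfg <- smallConfig(seed = 100 + s, n_case_dnm = 400L,
                           n_sib_dnm = 400L,
                           dnm_enhancer_rate_case = 0.15,
                           dnm_enhancer_rate_sib = 0.15)
        g <- generateGenome(cfg)
        v <- generateVariants(cfg, g)
        dnmBurden(v$dnms, g$enhancers)$odds_ratio
    }, numeric(1))
    expect_gt(mean(ors), 0.8)
    expect_lt(mean(ors), 1.25)
})

test_that("written fixtures are consistent with the truth object", {
    cfg <- smallConfig(seed = 20)
    dir <- withr::local_tempdir()
    simulateFixtures(cfg, dir)
    expect_true(all(file.exists(file.path(dir, c(
        "genome.fa", "tss.tsv", "tads.bed", "counts.tsv", "design.tsv",
        "expression.tsv", "variants.tsv", "pwms.tsv", "truth.json")))))
    expect_length(list.files(file.path(dir, "peaks")), 12)
    truth <- jsonlite::read_json(file.path(dir, "truth.json"))
    enh <- readBed(file.path(dir, "planted_enhancers.bed"), "BED6")
    expect_setequal(enh$name, names(truth$enhancer_class))
    cnt <- readTable(file.path(dir, "counts.tsv"), "counts")
    expect_setequal(rownames(cnt), names(truth$enhancer_class))
    expr <- readTable(file.path(dir, "expression.tsv"), "expression")
    tssTab <- readTable(file.path(dir, "tss.tsv"), "tss")
    expect_setequal(rownames(expr), tssTab$gene_id)
    # determinism across reruns, file by file
    dir2 <- withr::local_tempdir()
    simulateFixtures(cfg, dir2)
    for (f in c("genome.fa", "counts.tsv", "expression.tsv", "truth.json"))
        expect_identical(readLines(file.path(dir, f)),
                         readLines(file.path(dir2, f)))
})
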