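mkDnms <- function(nCaseIn, nCaseOut, nSibIn, nSibOut,
                   region = c(1000, 2000)) {
    pos <- function(n, inside) {
        if (n == 0) return(numeric(0))
        if (inside) round(seq(region[1], region[2], length.out = n))
        else seq(5000, 5000 + n - 1)
    }
    df <- data.frame(
        chrom = "c1",
        pos = c(pos(nCaseIn, TRUE), pos(nCaseOut, FALSE),
                pos(nSibIn, TRUE), pos(nSibOut, FALSE)),
        ref = "A", alt = "T",
        subject_id = "s",
        affected = rep(c(TRUE, FALSE), c(nCaseIn + nCaseOut,
                                         nSibIn + nSibOut)),
        vtype = "SNV", end = NA_real_, stringsAsFactors = FALSE)
    df
}

test_that("dnmBurden builds the 2x2 table; symmetric table gives OR 1, p 1", {
    reg <- GRanges("c1", IRanges(1000, 2000))
    b <- dnmBurden(mkDnms(10, 10, 10, 10), reg)
    expect_equal(unname(as.vector(b$table)), c(10, 10, 10, 10))
    expect_equal(b$odds_ratio, 1)
    expect_equal(b$p_fisher, 1)
    expect_error(dnmBurden(mkDnms(5, 5, 0, 0)[1:10, ], reg), "unaffected")
    # zero cell makes the odds ratio undefined
    b0 <- dnmBurden(mkDnms(5, 0, 3, 7), reg)
    expect_true(is.na(b0$odds_ratio))
})

test_that("Fisher p equals exhaustive hypergeometric summation", {
    set.seed(71)
    for (i in 1:200) {
        a <- sample(0:15, 1); b <- sample(0:15, 1)
        c_ <- sample(0:15, 1); d <- sample(0:15, 1)
        if (a + b == 0 || c_ + d == 0) next
        got <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
        expect_equal(got, fisherOracle(a, b, c_, d), tolerance = 1e-10)
    }
})

test_that("burden is invariant to input order and region splitting", {
    dn <- mkDnms(8, 12, 3, 17)
    reg <- GRanges("c1", IRanges(1000, 2000))
    # split the region into adjacent pieces covering identical bases
    regSplit <- GRanges("c1", IRanges(c(1000, 1501), c(1500, 2000)))
    b1 <- dnmBurden(dn, reg)
    b2 <- dnmBurden(dn[sample(nrow(dn)), ], regSplit)
    expect_equal(b1$table, b2$table)
    expect_equal(b1$p_fisher, b2$p_fisher)
    # overlapping duplicate records also collapse to the same bases
    regDup <- c(reg, GRanges("c1", IRanges(1200, 1800)))
    expect_equal(dnmBurden(dn, regDup)$table, b1$table)
})

test_that("a planted twofold burden is recovered", {
    cfg <- smallConfig(seed = 72, n_case_dnm = 1000L, n_sib_dnm = 1000L,
                       dnm_enhancer_rate_case = 0.2,
                       dnm_enhancer_rate_sib = 0.1)
    g <- generateGenome(cfg)
    v <- generateVariants(cfg, g)
    b <- dnmBurden(v$dnms, g$enhancers, "enhancers")
    expect_gte(b$odds_ratio, 1.5)
    expect_lte(b$odds_ratio, 2.7)
    expect_lt(b$p_fisher, 0.05)
})

test_that("cnvReport joins CNVs, enhancers and targets", {
    enh <- GRanges("c1", IRanges(c(1000, 3000), c(1500, 3500)),
                   enhancer_id = c("e1", "e2"))
    targets <- data.frame(enhancer_id = c("e1", "e2"),
                          gene_id = c("gA", "gB"), pearson_r = 0.9,
                          rank = 1L, stringsAsFactors = FALSE)
    tss <- data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                      position = c(100, 5000), strand = "+")
    cnv <- data.frame(chrom = "c1", pos = 900, ref = "N", alt = "N",
                      subject_id = "s1", affected = TRUE,
                      vtype = "CNV_del", end = 3200,
                      stringsAsFactors = FALSE)
    rep <- cnvReport(cnv, enh, targets, tss)
    expect_equal(nrow(rep), 2)  # CNV spans both enhancers, 1 target each
    expect_setequal(rep$gene_id, c("gA", "gB"))
    # distance: e1 [1000,1500] to gA TSS at 1-based 101 -> 899
    expect_equal(rep$distance_to_tss[rep$enhancer_id == "e1"], 899)
    # no CNV overlap -> empty
    cnvFar <- cnv; cnvFar$pos <- 9000; cnvFar$end <- 9500
    expect_equal(nrow(cnvReport(cnvFar, enh, targets, tss)), 0)
    # brute-force triple join on a random fixture
    set.seed(73)
    enhR <- randomIntervals(40)
    enhR$enhancer_id <- sprintf("e%02d", 1:40)
    tgR <- data.frame(enhancer_id = rep(enhR$enhancer_id, each = 2),
                      gene_id = sprintf("g%02d", rep(1:40, each = 2)),
                      pearson_r = 0.5, rank = rep(1:2, 40),
                      stringsAsFactors = FALSE)
    tssR <- data.frame(gene_id = unique(tgR$gene_id),
                       chrom = sample(c("cA", "cB"), 40, TRUE),
                       position = sample.int(1e5, 40), strand = "+")
    cnvR <- data.frame(chrom = sample(c("cA", "cB"), 15, TRUE),
                       pos = sample.int(9e4, 15), ref = "N", alt = "N",
                       subject_id = sprintf("s%02d", 1:15),
                       affected = TRUE, vtype = "CNV_dup",
                       end = NA_real_, stringsAsFactors = FALSE)
    cnvR$end <- cnvR$pos + sample.int(5000, 15)
    got <- cnvReport(cnvR, enhR, tgR, tssR)
    wantRows <- 0
    for (i in seq_len(nrow(cnvR))) for (j in seq_along(enhR)) {
        if (cnvR$chrom[i] == as.character(seqnames(enhR))[j] &&
            cnvR$pos[i] <= end(enhR)[j] && start(enhR)[j] <= cnvR$end[i])
            wantRows <- wantRows +
                sum(tgR$enhancer_id == enhR$enhancer_id[j])
    }
    expect_equal(nrow(got), wantRows)
})

test_that("snpEnrichment: empty regions, planted signal, +1 estimator", {
    cfg <- smallConfig(seed = 74, n_index_snps = 100L,
                       index_snp_enhancer_rate = 0.5,
                       n_control_snps = 2000L,
                       control_snp_enhancer_rate = 0.05)
    g <- generateGenome(cfg)
    v <- generateVariants(cfg, g)
    # empty region set: nothing overlaps, p = 1
    s0 <- suppressWarnings(
        snpEnrichment(v$index_snps, GRanges(), v$control_snps,
                      nResamples = 100, seed = 1))
    expect_equal(s0$observed_overlap, 0)
    expect_equal(s0$p_one_sided, 1)
    # planted tenfold enrichment is highly significant, never exactly 0
    s1 <- snpEnrichment(v$index_snps, g$enhancers, v$control_snps,
                        tss = g$tss, nResamples = 2000, seed = 2)
    expect_lte(s1$p_one_sided, 0.001)
    expect_gt(s1$p_one_sided, 0)
    expect_error(snpEnrichment(v$index_snps, g$enhancers,
                               v$control_snps[0, ]), "empty")
    # supplied LD proxies can create the overlap
    idx1 <- data.frame(snp_id = "rsX", chrom = "far", pos = 10)
    prox <- list(rsX = g$enhancers[1])
    s2 <- suppressWarnings(
        snpEnrichment(idx1, g$enhancers, v$control_snps,
                      proxies = prox, nResamples = 50, seed = 3))
    expect_equal(s2$observed_overlap, 1)
})
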