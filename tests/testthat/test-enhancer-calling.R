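test_that("consensusPeaks equals the all-pairs overlap oracle", {
    set.seed(21)
    repA <- randomIntervals(100)
    repB <- randomIntervals(100)
    got <- consensusPeaks(repA, repB)
    want <- repA[bruteAnyOverlap(repA, repB)]
    want <- want[order(as.character(seqnames(want)), start(want),
                       end(want))]
    expect_equal(granges(got), granges(want))
    # empty partner and idempotence
    expect_length(consensusPeaks(repA, GRanges()), 0)
    self <- consensusPeaks(repA, repA)
    expect_equal(sort(start(self)), sort(start(repA)))
})

test_that("intersectMarks keeps H3K27ac coordinates and honors 1 bp overlaps", {
    # BED [100,200) vs [199,300): single shared base -> retained
    k27 <- GRanges("c1", IRanges(101, 200))
    k4a <- GRanges("c1", IRanges(200, 300))
    expect_length(intersectMarks(k27, k4a), 1)
    expect_equal(start(intersectMarks(k27, k4a)), 101)  # coords unchanged
    # BED [100,200) vs [200,300): adjacent, no shared base -> dropped
    k4b <- GRanges("c1", IRanges(201, 300))
    expect_length(intersectMarks(k27, k4b), 0)
    # random fixture vs oracle
    set.seed(22)
    a <- randomIntervals(120)
    b <- randomIntervals(80)
    expect_equal(length(intersectMarks(a, b)), sum(bruteAnyOverlap(a, b)))
})

test_that("excludePromoters implements the symmetric strand-agnostic window", {
    tss <- data.frame(gene_id = "g1", chrom = "c1", position = 900,
                      strand = "-")
    # peak BED [0,400): window around 0-based 900 with 500 bp is [400,1401)
    peak <- GRanges("c1", IRanges(1, 400))
    expect_length(excludePromoters(peak, tss, 500), 1)  # adjacency retained
    peak2 <- GRanges("c1", IRanges(1, 401))             # reaches base 400
    expect_length(excludePromoters(peak2, tss, 500), 0)
    # window = 0 removes only peaks containing the TSS base itself
    peak3 <- GRanges("c1", IRanges(901, 950))
    peak4 <- GRanges("c1", IRanges(902, 950))
    expect_length(excludePromoters(peak3, tss, 0), 0)
    expect_length(excludePromoters(peak4, tss, 0), 1)
    # default window is 500 bp
    expect_equal(formals(excludePromoters)$window, 500)

    # brute-force distance check on a random fixture
    set.seed(23)
    peaks <- randomIntervals(200)
    tssN <- data.frame(gene_id = paste0("g", 1:20),
                       chrom = sample(c("cA", "cB"), 20, TRUE),
                       position = sample.int(1e5, 20), strand = "+")
    got <- excludePromoters(peaks, tssN, 500)
    win <- GRanges(tssN$chrom, IRanges(tssN$position + 1 - 500,
                                       tssN$position + 1 + 500))
    keep <- !bruteAnyOverlap(peaks, win)
    expect_equal(length(got), sum(keep))
    expect_equal(start(got), start(peaks)[keep])
})

test_that("cross-age dedup keeps earliest coordinates and accumulates ages", {
    # one age with non-overlapping peaks (as a peak caller emits them):
    # every peak admitted
    one <- list(E12 = GRanges("c1", IRanges(seq(1, 30000, 1000),
                                            width = 500)))
    es <- dedupAcrossAges(one)
    expect_length(es, 30)
    expect_true(all(enhancerRanges(es)$discovery_age == "E12"))
    # identical interval at all three ages collapses to one record
    iv <- GRanges("c1", IRanges(1000, 1500))
    es3 <- dedupAcrossAges(list(E12 = iv, P0 = iv, P9 = iv))
    expect_length(es3, 1)
    expect_setequal(agesActive(es3)[[1]], c("E12", "P0", "P9"))
    expect_equal(enhancerRanges(es3)$discovery_age, "E12")

    # partial overlaps across ages match the greedy brute-force oracle
    set.seed(24)
    perAge <- list(E12 = randomIntervals(60), P0 = randomIntervals(60),
                   P9 = randomIntervals(60))
    got <- dedupAcrossAges(perAge)
    want <- dedupOracle(perAge)
    expect_equal(granges(enhancerRanges(got)), granges(want$ranges))
    expect_equal(enhancerRanges(got)$discovery_age, want$discovery)
    expect_equal(unname(agesActive(got)[enhancerIds(got)]), want$active)
})

test_that("pipeline stages never fabricate coordinates", {
    cfg <- smallConfig(seed = 25)
    g <- generateGenome(cfg)
    pc <- generatePeaksAndCounts(cfg, g)
    enh <- callEnhancers(pc$peaks, g$tss, cfg$ages)
    gr <- enhancerRanges(enh)
    allK27 <- do.call(c, unname(lapply(
        pc$peaks[grepl("H3K27ac", names(pc$peaks))], granges)))
    key <- paste(seqnames(gr), start(gr), end(gr))
    pool <- paste(seqnames(allK27), start(allK27), end(allK27))
    expect_true(all(key %in% pool))
})

test_that("annotateByOverlap collects labels of every overlapping interval", {
    enh <- GRanges("c1", IRanges(c(100, 5000), c(400, 5400)),
                   enhancer_id = c("e1", "e2"))
    # empty annotation -> empty label sets
    ann0 <- GRanges()
    lab0 <- annotateByOverlap(enh, ann0)
    expect_equal(unname(lengths(lab0)), c(0L, 0L))
    # one enhancer under two differently labelled CREs
    ann <- GRanges("c1", IRanges(c(90, 350, 9999), c(120, 450, 10100)),
                   name = c("granule", "purkinje", "progenitor"))
    lab <- annotateByOverlap(enh, ann)
    expect_setequal(lab$e1, c("granule", "purkinje"))
    expect_equal(lab$e2, character(0))
    # planted overlap fraction equals the exact count
    set.seed(26)
    many <- GRanges("cX", IRanges(seq(1, 100000, 1000), width = 200))
    many$enhancer_id <- sprintf("m%03d", seq_along(many))
    hitIdx <- sort(sample(seq_along(many), 37))
    annP <- GRanges("cX", IRanges(start(many)[hitIdx] + 50, width = 10))
    annP$name <- "cre"
    labP <- annotateByOverlap(many, annP)
    expect_equal(sum(lengths(labP) > 0), 37)
})
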