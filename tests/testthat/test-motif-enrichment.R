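randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

test_that("log-odds matrix: uniform limit, sign structure, hand computation", {
    uni <- MotifPWM("u", matrix(0.25, 4, 4), pseudo = 1e-9)
    expect_lt(max(abs(logOdds(uni))), 1e-8)
    det <- MotifPWM("d", rbind(c(1, 0, 0, 0), c(1, 0, 0, 0),
                               c(0, 1, 0, 0), c(0, 0, 0, 1)),
                    pseudo = 0.01)
    lo <- logOdds(det)
    expect_gt(lo[1, "A"], 0)
    expect_true(all(lo[1, c("C", "G", "T")] < 0))
    # hand-computed toy entry: p=0.5, bg=0.25, pseudo=0.01
    toy <- MotifPWM("t", matrix(rep(c(0.5, 0.2, 0.2, 0.1), 4), 4, 4,
                                byrow = TRUE), pseudo = 0.01)
    want <- log2((0.5 + 0.01 * 0.25) / 1.01 / 0.25)
    expect_equal(unname(logOdds(toy)[1, "A"]), want, tolerance = 1e-12)
    bad <- MotifPWM("b", matrix(0.25, 4, 4), background = c(0.5, 0.5, 0, 0))
    expect_error(logOdds(bad), "strictly positive")
})

test_that("scanSequence finds planted consensus and mirrors under revcomp", {
    pwm <- plantedMotifPWM()
    cons <- "TGACGTCATC"
    set.seed(61)
    seq <- randomSeq(100)
    substr(seq, 17, 26) <- cons
    hits <- scanSequence(seq, pwm)
    expect_true(any(hits$offset == 17 & hits$strand == "+"))
    top <- hits[hits$offset == 17, ]
    lo <- logOdds(pwm)
    expect_equal(top$score[top$strand == "+"], sum(apply(lo, 1, max)),
                 tolerance = 1e-10)
    # reverse-complementing the sequence mirrors offsets and flips strands
    rc <- enhancerTempo:::revComp(seq)
    hitsRc <- scanSequence(rc, pwm)
    n <- nchar(seq) - nrow(motifProbs(pwm)) + 1
    mapped <- data.frame(offset = n - hitsRc$offset + 1,
                         strand = ifelse(hitsRc$strand == "+", "-", "+"),
                         score = hitsRc$score)
    mapped <- mapped[order(mapped$offset, mapped$strand), ]
    expect_equal(mapped$offset, hits$offset)
    expect_equal(mapped$strand, hits$strand)
    expect_equal(mapped$score, hits$score, tolerance = 1e-10)
    # windows containing N never score
    seqN <- seq
    substr(seqN, 20, 20) <- "N"
    hitsN <- scanSequence(seqN, pwm)
    expect_false(any(hitsN$offset == 17 & hitsN$strand == "+"))
})

test_that("vectorized scanner equals the brute-force per-window scorer", {
    set.seed(62)
    pwm <- decoyMotifPWMs(n = 1, seed = 5)[[1]]
    for (i in 1:30) {
        seq <- randomSeq(500)
        got <- scanSequence(seq, pwm, thresholdFraction = 0.7)
        want <- bruteScan(seq, motifProbs(pwm), pwm@background,
                          pwm@pseudo, 0.7)
        expect_equal(got$offset, want$offset)
        expect_equal(got$strand, want$strand)
        expect_equal(got$score, want$score, tolerance = 1e-10)
    }
})

test_that("GC-matched background selection stays within tolerance", {
    set.seed(63)
    targets <- setNames(vapply(1:20, function(i) randomSeq(200), ""),
                        paste0("t", 1:20))
    pool <- setNames(vapply(1:200, function(i) randomSeq(200), ""),
                     paste0("p", 1:200))
    bg <- selectBackground(targets, pool, seed = 7)
    expect_length(bg, 40)
    expect_false(any(duplicated(names(bg))))
    gc <- function(s) {
        ch <- strsplit(s, "")[[1]]
        mean(ch %in% c("G", "C"))
    }
    # each consecutive pair was drawn for one target; mean |GC diff| small
    diffs <- abs(vapply(bg, gc, numeric(1)) -
                 rep(vapply(targets, gc, numeric(1)), each = 2))
    expect_lt(mean(diffs), 0.05)
    # pool = targets is trivially matched
    bg2 <- selectBackground(targets[1:5], targets, ratio = 1, seed = 1)
    expect_true(all(names(bg2) %in% names(targets)))
    # impossible composition relaxes with warnings but completes
    at <- setNames(c(strrep("AT", 100)), "at1")
    gcp <- setNames(vapply(1:10, function(i) strrep("GC", 100), ""),
                    paste0("gc", 1:10))
    expect_warning(bg3 <- selectBackground(at, gcp, seed = 2), "relaxed")
    expect_length(bg3, 2)
    expect_error(selectBackground(at, character(0)), "empty")
})

test_that("binomial tail equals direct pmf summation; degenerate k", {
    for (n in c(5, 20, 50)) for (p0 in c(0.02, 0.3, 0.7)) {
        for (k in unique(c(0, 1, floor(n * p0), n))) {
            direct <- sum(dbinom(k:n, n, p0))
            got <- pbinom(k - 1, n, p0, lower.tail = FALSE)
            expect_equal(got, direct, tolerance = 1e-12)
        }
    }
    seqs <- setNames(c("ACGTACGTACGTACGT", "TTTTTTTTTTTTTTTT"),
                     c("s1", "s2"))
    pwm <- plantedMotifPWM()
    res <- binomialEnrichment(seqs, seqs, pwm)
    expect_equal(res$k_target, 0)
    expect_equal(res$p_binomial, 1)
    # p ~ 0.5 when observed sits at the null expectation
    expect_gt(pbinom(24, 50, 0.5, lower.tail = FALSE), 0.3)
    expect_lt(pbinom(24, 50, 0.5, lower.tail = FALSE), 0.7)
})

test_that("planted motif outranks decoys and enrichment is strand-symmetric", {
    set.seed(64)
    cons <- "TGACGTCATC"
    targets <- vapply(1:50, function(i) {
        s <- randomSeq(300)
        if (i <= 30) substr(s, 100, 109) <- cons  # 60 % embed rate
        s
    }, "")
    names(targets) <- paste0("t", 1:50)
    background <- setNames(vapply(1:100, function(i) {
        s <- randomSeq(300)
        if (i <= 5) substr(s, 50, 59) <- cons     # 5 % background rate
        s
    }, ""), paste0("b", 1:100))
    pwms <- c(list(plantedMotifPWM()), decoyMotifPWMs(n = 5, seed = 3))
    res <- motifEnrichment(targets, background, pwms)
    best <- res$motif_id[which.min(res$p_adjusted)]
    expect_equal(best, "planted_motif")
    ranked <- rankMotifs(res, alpha = 1e-5)
    expect_equal(ranked$motif_id[1], "planted_motif")
    expect_equal(nrow(rankMotifs(res[0, ], alpha = 1)), 0)

    # reverse-complement every sequence: identical counts and p-values
    rcAll <- function(v) setNames(vapply(v, enhancerTempo:::revComp, ""),
                                  names(v))
    resRc <- motifEnrichment(rcAll(targets), rcAll(background), pwms)
    expect_equal(res$k_target, resRc$k_target)
    expect_equal(res$p0, resRc$p0)
    expect_equal(res$p_binomial, resRc$p_binomial, tolerance = 1e-12)
})
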