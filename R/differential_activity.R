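#' Normalize a ChIP count matrix
#'
#' Two optional steps mirroring a standard differential-binding workflow:
#' (1) if paired input libraries are present and `subtractInput = TRUE`, the
#' input count is scaled to the ChIP library size and subtracted, floored at
#' zero; (2) median-of-ratios size factors are computed over ChIP samples
#' using intervals with all-positive counts, and every sample is divided by
#' its factor.
#'
#' @param counts A [ChIPCountSet-class] (or an integer matrix plus `design`).
#' @param design optional data.frame with `age`, `replicate`, `role`,
#'   `paired_input` when `counts` is a bare matrix.
#' @param subtractInput subtract paired input libraries first (default
#'   FALSE).
#' @return list with `normalized` (ChIP-only numeric matrix), `sizeFactors`
#'   (named vector over ChIP samples), `design` (ChIP-only design rows).
#' @export
normalizeCounts <- function(counts, design = NULL, subtractInput = FALSE) {
    if (is(counts, "ChIPCountSet")) {
        design <- as.data.frame(colData(counts))
        m <- assay(counts, "counts")
    } else m <- as.matrix(counts)
    stopifnot(!is.null(design))
    m <- m * 1.0
    chip <- rownames(design)[design$role == "chip"]
    if (length(chip) == 0) stopf("no chip samples in design")
    if (subtractInput && "paired_input" %in% colnames(design)) {
        for (s in chip) {
            pin <- design[s, "paired_input"]
            if (!is.na(pin) && pin %in% colnames(m)) {
                scale <- sum(m[, s]) / max(sum(m[, pin]), 1)
                m[, s] <- pmax(m[, s] - m[, pin] * scale, 0)
            }
        }
    }
    mc <- m[, chip, drop = FALSE]
    pos <- rowSums(mc > 0) == ncol(mc)
    if (!any(pos)) stopf("no usable rows for size factors")
    logGeo <- rowMeans(log(mc[pos, , drop = FALSE]))
    sf <- apply(mc[pos, , drop = FALSE], 2,
                function(col) exp(median(log(col) - logGeo)))
    normalized <- sweep(mc, 2, sf, "/")
    list(normalized = normalized, sizeFactors = sf,
         design = design[chip, , drop = FALSE])
}

#' Method-of-moments NB dispersion with shrinkage
#'
#' Per interval, replicate means and variances are pooled across stages into
#' the moment estimate `alpha = max(0, sum(s2 - m) / sum(m^2 - s2/n))`
#' (variance model `m + alpha m^2`; the `- s2/n` term removes the upward
#' bias of the squared replicate mean). The per-interval estimate, which is
#' nearly pure noise at two replicates, is shrunk strongly (3:1 by default)
#' toward the pooled global moment estimate computed from the summed
#' numerators and denominators over all intervals.
#'
#' @param normalized numeric matrix from [normalizeCounts()].
#' @param design ChIP design rows (with `age`).
#' @param shrink weight on the per-interval estimate (default 0.25).
#' @return list with `alpha` (shrunk, per interval), `alphaRaw`,
#'   `alphaGlobal` and `alphaMedian`.
#' @export
estimateDispersion <- function(normalized, design, shrink = 0.25) {
    ages <- unique(design$age)
    num <- rep(0, nrow(normalized))
    den <- rep(0, nrow(normalized))
    for (a in ages) {
        cols <- rownames(design)[design$age == a]
        if (length(cols) < 2) stopf("need >= 2 replicates at stage %s", a)
        sub <- normalized[, cols, drop = FALSE]
        m <- rowMeans(sub)
        s2 <- apply(sub, 1, var)
        num <- num + (s2 - m)
        den <- den + (m^2 - s2 / length(cols))
    }
    alphaRaw <- pmax(0, ifelse(den > 0, num / den, 0))
    alphaGlobal <- max(0, sum(num) / max(sum(pmax(den, 0)), 1e-8))
    alpha <- shrink * alphaRaw + (1 - shrink) * alphaGlobal
    list(alpha = alpha, alphaRaw = alphaRaw, alphaGlobal = alphaGlobal,
         alphaMedian = median(alphaRaw))
}

#' Two-group negative-binomial contrast between stages
#'
#' Per interval, tests equality of mean H3K27ac signal between two stages.
#' With positive dispersion a Wald test on the difference of log means is
#' used, with variance `(1/m + alpha) / n` per group from the NB model
#' `var = m + alpha m^2`. When the shrunk dispersion is zero the data are
#' treated as Poisson and an exact conditional binomial test on the raw
#' replicate sums (success probability proportional to the groups' total
#' size factors) is used instead. P-values are Benjamini-Hochberg adjusted
#' across all intervals in the contrast.
#'
#' @param counts A [ChIPCountSet-class].
#' @param ageA,ageB stage labels to contrast; `signal_difference` is
#'   mean(`ageA`) - mean(`ageB`) on the normalized scale.
#' @param subtractInput passed to [normalizeCounts()].
#' @return data.frame with `interval_id`, `age_a`, `age_b`,
#'   `log2_fold_change`, `signal_difference`, `p_value`, `fdr`.
#' @export
testContrast <- function(counts, ageA, ageB, subtractInput = FALSE) {
    design <- as.data.frame(colData(counts))
    for (a in c(ageA, ageB))
        if (!a %in% design$age) stopf("unknown stage label '%s'", a)
    norm <- normalizeCounts(counts, subtractInput = subtractInput)
    disp <- estimateDispersion(norm$normalized, norm$design)
    raw <- assay(counts, "counts")[, rownames(norm$design), drop = FALSE]
    colsA <- rownames(norm$design)[norm$design$age == ageA]
    colsB <- rownames(norm$design)[norm$design$age == ageB]
    if (length(colsA) < 2 || length(colsB) < 2)
        stopf("both stages need >= 2 chip replicates")
    mA <- rowMeans(norm$normalized[, colsA, drop = FALSE])
    mB <- rowMeans(norm$normalized[, colsB, drop = FALSE])
    nA <- length(colsA); nB <- length(colsB)
    eps <- 0.5
    l2fc <- log2((mA + eps) / (mB + eps))
    p <- numeric(nrow(raw))
    sfA <- sum(norm$sizeFactors[colsA])
    sfB <- sum(norm$sizeFactors[colsB])
    for (i in seq_len(nrow(raw))) {
        a <- disp$alpha[i]
        if (a > 0) {
            va <- (1 / max(mA[i], eps) + a) / nA
            vb <- (1 / max(mB[i], eps) + a) / nB
            z <- (log(mA[i] + eps) - log(mB[i] + eps)) / sqrt(va + vb)
            p[i] <- 2 * pnorm(-abs(z))
        } else {
            kA <- sum(raw[i, colsA])
            tot <- kA + sum(raw[i, colsB])
            p[i] <- if (tot == 0) 1
                    else binom.test(kA, tot, sfA / (sfA + sfB))$p.value
        }
    }
    p <- pmin(p, 1)
    data.frame(interval_id = rownames(raw), age_a = ageA, age_b = ageB,
               log2_fold_change = l2fc, signal_difference = mA - mB,
               p_value = p, fdr = p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify enhancers as Early, Late, P0-specific or Neither
#'
#' Early: significantly higher signal at E12 (FDR below threshold and
#' positive E12-ward signal difference) in the E12-vs-P0 or the E12-vs-P9
#' contrast. Late: analogously for P9 in E12-vs-P9 or P0-vs-P9. An enhancer
#' significant in both of a class's contrasts is counted once. The
#' middle-stage class requires significantly higher signal at P0 in *both*
#' of its contrasts.
#'
#' An enhancer can qualify for both Early and Late through a P0 trough
#' (higher E12 than P0 *and* higher P9 than P0) without any internal
#' contradiction; such enhancers are arbitrated by the direct E12-vs-P9
#' contrast: Early or Late when that contrast is significant, otherwise
#' Neither. A genuinely contradictory input (an E12-vs-P9 contrast claiming
#' both directions, possible only for corrupted inputs) raises an integrity
#' error naming the offenders.
#'
#' @param contrastEP0 result of `testContrast(counts, ages[1], ages[2])`.
#' @param contrastEP9 result of `testContrast(counts, ages[1], ages[3])`.
#' @param contrastP0P9 result of `testContrast(counts, ages[2], ages[3])`.
#' @param alphaFdr FDR threshold (default 0.05).
#' @return data.frame with `interval_id` and `class` in
#'   `{Early, Late, P0, Neither}`; classes partition the tested universe.
#' @export
classifyTemporal <- function(contrastEP0, contrastEP9, contrastP0P9,
                             alphaFdr = 0.05) {
    ids <- contrastEP0$interval_id
    stopifnot(identical(ids, contrastEP9$interval_id),
              identical(ids, contrastP0P9$interval_id))
    sigHigherA <- function(ct) ct$fdr < alphaFdr & ct$signal_difference > 0
    sigHigherB <- function(ct) ct$fdr < alphaFdr & ct$signal_difference < 0
    earlyDirect <- sigHigherA(contrastEP9)
    lateDirect <- sigHigherB(contrastEP9)
    contradiction <- earlyDirect & lateDirect
    if (any(contradiction))
        stopf("inconsistent contrasts: enhancer(s) qualify as both Early and Late: %s",
              paste(head(ids[contradiction], 10), collapse = ", "))
    early <- sigHigherA(contrastEP0) | earlyDirect
    late <- lateDirect | sigHigherB(contrastP0P9)
    p0cls <- sigHigherB(contrastEP0) & sigHigherA(contrastP0P9)
    both <- early & late
    cls <- rep("Neither", length(ids))
    cls[p0cls] <- "P0"
    cls[late] <- "Late"
    cls[early] <- "Early"
    # P0-trough pattern: arbitrate by the direct E12-vs-P9 evidence
    cls[both] <- ifelse(earlyDirect[both], "Early",
                        ifelse(lateDirect[both], "Late", "Neither"))
    data.frame(interval_id = ids, class = cls, stringsAsFactors = FALSE)
}
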