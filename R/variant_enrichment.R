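#' Matched-control resampling test for SNP enrichment in regions
#'
#' A Monte-Carlo replacement for the analytic matched-control overlap
#' probability of GREGOR-style tools: an index SNP "overlaps" if it, or any
#' supplied LD-proxy interval, intersects a region. Each resample draws one
#' control variant per index SNP from the same matching stratum (default:
#' decile of distance to the nearest TSS, computed over the control pool)
#' and the one-sided p-value is estimated from the null overlap counts.
#'
#' Overlap counts are small integers, so ties between the observed count
#' and null counts carry substantial mass; the default estimator therefore
#' counts ties at half weight (the mid-p convention,
#' `(#\{null > obs\} + 0.5 #\{null = obs\} + 1) / (n + 1)`), which keeps the
#' null p-value distribution centred at 0.5. `tieBreak = "literal"` counts
#' ties fully (`#\{null >= obs\}`). The +1 continuity term mirrors an
#' analytic p that is never exactly zero; set `plusOne = FALSE` for the
#' bare fraction.
#'
#' @param indexSnps data.frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param regions GRanges of regions (e.g. enhancers).
#' @param controlPool data.frame with `snp_id`, `chrom`, `pos`.
#' @param proxies optional named list mapping snp_id to a GRanges of LD-proxy
#'   intervals (supplied externally, never computed here).
#' @param tss optional TSS table for the distance-decile matching feature;
#'   without it a single stratum is used, with a warning.
#' @param nResamples number of resamples (default 10000).
#' @param seed integer seed.
#' @param plusOne use the (k+1)/(n+1) estimator (default TRUE).
#' @param tieBreak `"midp"` (default) counts null ties at half weight;
#'   `"literal"` counts them fully.
#' @return list with `n_index`, `observed_overlap`, `n_resamples`,
#'   `null_mean`, `p_one_sided`, `matching_features`.
#' @export
snpEnrichment <- function(indexSnps, regions, controlPool, proxies = NULL,
                          tss = NULL, nResamples = 10000, seed = 1L,
                          plusOne = TRUE, tieBreak = c("midp", "literal")) {
    tieBreak <- match.arg(tieBreak)
    if (nrow(controlPool) == 0) stopf("empty control pool")
    toGr <- function(df) GRanges(df$chrom, IRanges(df$pos, df$pos))
    idxGr <- toGr(indexSnps)
    ctlGr <- toGr(controlPool)
    overlaps <- overlapsAny(idxGr, regions, ignore.strand = TRUE)
    if (!is.null(proxies)) {
        for (i in seq_len(nrow(indexSnps))) {
            pr <- proxies[[indexSnps$snp_id[i]]]
            if (!is.null(pr) && length(pr) > 0)
                overlaps[i] <- overlaps[i] ||
                    any(overlapsAny(pr, regions, ignore.strand = TRUE))
        }
    }
    observed <- sum(overlaps)
    matching <- "distance-to-nearest-TSS decile"
    if (is.null(tss)) {
        warnf("no TSS table supplied; matching on a single stratum")
        matching <- "none"
        idxStrat <- rep(1L, nrow(indexSnps))
        ctlStrat <- rep(1L, nrow(controlPool))
    } else {
        tssGr <- tssToRanges(tss)
        distTo <- function(gr) {
            d <- GenomicRanges::distanceToNearest(gr, tssGr)
            out <- rep(Inf, length(gr))
            out[queryHits(d)] <- mcols(d)$distance
            out
        }
        dIdx <- distTo(idxGr)
        dCtl <- distTo(ctlGr)
        br <- unique(quantile(dCtl, probs = seq(0, 1, 0.1), names = FALSE))
        cutStrat <- function(d) as.integer(cut(d, breaks = c(-1, br[-1]),
                                               include.lowest = TRUE))
        idxStrat <- cutStrat(pmin(dIdx, max(dCtl)))
        ctlStrat <- cutStrat(dCtl)
    }
    ctlOverlap <- overlapsAny(ctlGr, regions, ignore.strand = TRUE)
    strata <- lapply(sort(unique(idxStrat)), function(s)
        which(ctlStrat == s))
    names(strata) <- sort(unique(idxStrat))
    small <- vapply(as.character(unique(idxStrat)), function(s)
        length(strata[[s]]) < 10 * sum(idxStrat == as.integer(s)),
        logical(1))
    if (any(small))
        warnf("control pool < 10x index SNPs in %d stratum/strata",
              sum(small))
    for (s in names(strata))
        if (length(strata[[s]]) == 0)
            stopf("no control variants in matching stratum %s", s)
    nullCounts <- withSeed(childSeed(seed, "snp_resample"), {
        vapply(seq_len(nResamples), function(b) {
            cnt <- 0L
            for (s in names(strata)) {
                nIdx <- sum(idxStrat == as.integer(s))
                pick <- strata[[s]][sample.int(length(strata[[s]]), nIdx,
                                               replace = TRUE)]
                cnt <- cnt + sum(ctlOverlap[pick])
            }
            cnt
        }, integer(1))
    })
    k <- if (tieBreak == "midp")
        sum(nullCounts > observed) + 0.5 * sum(nullCounts == observed)
    else sum(nullCounts >= observed)
    p <- if (plusOne) (k + 1) / (nResamples + 1) else k / nResamples
    if (observed == 0) p <- 1  # zero overlap is never evidence of enrichment
    list(n_index = nrow(indexSnps), observed_overlap = observed,
         n_resamples = nResamples, null_mean = mean(nullCounts),
         p_one_sided = p, matching_features = matching)
}

#' Case-versus-sibling de novo mutation burden in a region set
#'
#' Builds the 2x2 contingency table of (affected, unaffected) x (DNM
#' overlapping, not overlapping) the region set and applies a two-sided
#' Fisher exact test. Regions are merged before counting so each DNM is
#' counted once even when region records overlap (relevant when testing a
#' union of enhancer classes). CNVs are excluded here; see [cnvReport()].
#'
#' @param dnms variants data.frame (SNV/indel rows are used).
#' @param regions GRanges of regions.
#' @param regionLabel label for the output.
#' @return list with `table` (2x2 matrix), `odds_ratio` (ad/bc; `NA` when a
#'   zero cell makes it undefined), `p_fisher`, `region_label`.
#' @export
dnmBurden <- function(dnms, regions, regionLabel = "regions") {
    dnms <- dnms[dnms$vtype %in% c("SNV", "indel"), , drop = FALSE]
    if (!any(!dnms$affected)) stopf("no unaffected subjects in DNM table")
    merged <- reduce(regions, ignore.strand = TRUE)
    gr <- GRanges(dnms$chrom, IRanges(dnms$pos, dnms$pos))
    inReg <- overlapsAny(gr, merged, ignore.strand = TRUE)
    tab <- matrix(c(sum(dnms$affected & inReg),
                    sum(dnms$affected & !inReg),
                    sum(!dnms$affected & inReg),
                    sum(!dnms$affected & !inReg)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("case", "sibling"),
                                  c("in_region", "out_region")))
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    orEst <- if (b * c_ == 0) NA_real_ else (a * d) / (b * c_)
    p <- fisher.test(tab)$p.value
    list(table = tab, odds_ratio = orEst, p_fisher = p,
         region_label = regionLabel)
}

#' Report de novo CNVs overlapping enhancers and their target genes
#'
#' One row per (CNV, overlapped enhancer, assigned target gene) triple,
#' with the distance from the enhancer to the target's TSS in bp.
#'
#' @param cnvs variants data.frame (CNV_del/CNV_dup rows are used; `end`
#'   required).
#' @param enhancers [EnhancerSet-class] or GRanges with `enhancer_id`.
#' @param targets data.frame from [assignTargets()].
#' @param tss TSS table for the distance column.
#' @return data.frame with `subject_id`, `vtype`, `chrom`, `pos`, `end`,
#'   `enhancer_id`, `gene_id`, `distance_to_tss`.
#' @export
cnvReport <- function(cnvs, enhancers, targets, tss) {
    gr <- if (is(enhancers, "EnhancerSet")) enhancerRanges(enhancers)
          else enhancers
    cnvs <- cnvs[grepl("^CNV", cnvs$vtype), , drop = FALSE]
    empty <- data.frame(subject_id = character(0), vtype = character(0),
                        chrom = character(0), pos = numeric(0),
                        end = numeric(0), enhancer_id = character(0),
                        gene_id = character(0),
                        distance_to_tss = numeric(0),
                        stringsAsFactors = FALSE)
    if (nrow(cnvs) == 0 || length(gr) == 0) return(empty)
    cnvGr <- GRanges(cnvs$chrom, IRanges(cnvs$pos, cnvs$end))
    ov <- findOverlaps(cnvGr, gr, ignore.strand = TRUE)
    if (length(ov) == 0) return(empty)
    tssGr <- tssToRanges(tss)
    rows <- lapply(seq_along(ov), function(k) {
        ci <- queryHits(ov)[k]; ei <- subjectHits(ov)[k]
        eid <- gr$enhancer_id[ei]
        tg <- targets[targets$enhancer_id == eid, , drop = FALSE]
        if (nrow(tg) == 0) return(NULL)
        dist <- vapply(tg$gene_id, function(g) {
            tp <- start(tssGr[g])
            if (as.character(seqnames(tssGr[g])) !=
                as.character(seqnames(gr))[ei]) return(NA_real_)
            if (tp >= start(gr)[ei] && tp <= end(gr)[ei]) 0
            else min(abs(tp - start(gr)[ei]), abs(tp - end(gr)[ei]))
        }, numeric(1))
        data.frame(subject_id = cnvs$subject_id[ci],
                   vtype = cnvs$vtype[ci], chrom = cnvs$chrom[ci],
                   pos = cnvs$pos[ci], end = cnvs$end[ci],
                   enhancer_id = eid, gene_id = tg$gene_id,
                   distance_to_tss = dist, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(empty)
    rownames(out) <- NULL
    out
}
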