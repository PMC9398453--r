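#' Pipeline configuration
#'
#' Bundles a synthetic-data block with the analysis thresholds. Every
#' default mirrors the corresponding analysis default: 500 bp promoter
#' window, FDR 0.05 for differential activity, adjusted p < 1e-11 for motif
#' ranking, 10,000 permutations/resamples for the enrichment tests.
#'
#' @param synthetic a [syntheticConfig()] describing the simulated inputs.
#' @param promoter_window bp half-width of the TSS exclusion window.
#' @param fdr FDR threshold for temporal classification.
#' @param motif_alpha adjusted-p threshold for motif ranking.
#' @param n_perm permutations for the target-gene enrichment test.
#' @param n_resamples resamples for the SNP enrichment test.
#' @param motif_threshold fraction of the maximum log-odds score required
#'   for a motif hit.
#' @param seed root seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           promoter_window = 500, fdr = 0.05,
                           motif_alpha = 1e-11, n_perm = 10000,
                           n_resamples = 10000,
                           motif_threshold = 0.8, seed = 1L) {
    cfg <- as.list(environment())
    if (is.null(synthetic)) stopf("a synthetic block is required")
    class(cfg) <- "pipeline_config"
    cfg
}

.log <- function(con, fmt, ...) {
    writeLines(sprintf(fmt, ...), con)
}

#' Run the full enhancer-atlas pipeline
#'
#' Executes every stage in fixed order on a synthetic dataset: fixture
#' simulation, enhancer calling, differential activity and temporal
#' classification, target assignment and permutation enrichment (against
#' the planted target genes as the annotated set), co-expression
#' clustering, motif enrichment, and variant enrichment. Writes
#' `enhancers.bed`, `classes.tsv`, `contrasts.tsv`, `targets.tsv`,
#' `clusters.tsv`, `motif_enrichment.tsv`, `variant_reports/`, `atlas.json`
#' and `run_log.txt` under `outDir`. Reruns with an identical configuration
#' produce byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @return `outDir`, invisibly.
#' @export
runAll <- function(config, outDir) {
    stopifnot(inherits(config, "pipeline_config"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    vdir <- file.path(outDir, "variant_reports")
    dir.create(vdir, showWarnings = FALSE)
    logPath <- file.path(outDir, "run_log.txt")
    con <- file(logPath, "w")
    on.exit(close(con))
    scfg <- config$synthetic
    scfg$seed <- childSeed(config$seed, "synthetic")

    .log(con, "stage simulate: seed=%d ages=%s", scfg$seed,
         paste(scfg$ages, collapse = ","))
    fixDir <- file.path(outDir, "fixtures")
    simulateFixtures(scfg, fixDir)
    genome <- generateGenome(scfg)
    pc <- generatePeaksAndCounts(scfg, genome)
    expr <- generateExpression(scfg, genome, pc$counts)
    vars <- generateVariants(scfg, genome)
    .log(con, "stage simulate: enhancers=%d genes=%d tads=%d",
         length(genome$enhancers), nrow(genome$tss), length(genome$tads))

    enh <- callEnhancers(pc$peaks, genome$tss, scfg$ages,
                         promoterWindow = config$promoter_window)
    enhBed <- enhancerRanges(enh)
    enhBed$name <- enhBed$enhancer_id
    enhBed$score <- rep(0, length(enhBed))
    writeBed(enhBed, file.path(outDir, "enhancers.bed"))
    agesTab <- data.frame(
        enhancer_id = enhancerIds(enh),
        discovery_age = enhancerRanges(enh)$discovery_age,
        ages_active = vapply(agesActive(enh)[enhancerIds(enh)],
                             paste, "", collapse = ","),
        stringsAsFactors = FALSE)
    writeTable(agesTab, file.path(outDir, "enhancer_ages.tsv"))
    .log(con, "stage call-enhancers: promoter_window=%g admitted=%d",
         config$promoter_window, length(enh))

    # counts are simulated over the planted enhancers; map called enhancers
    # onto them by overlap for the count-based stages
    called <- enhancerRanges(enh)
    hit <- findOverlaps(called, rowRanges(pc$counts), select = "first")
    keep <- !is.na(hit)
    idMap <- setNames(rownames(pc$counts)[hit[keep]],
                      called$enhancer_id[keep])
    counts <- pc$counts[unique(unname(idMap)), ]
    ages <- scfg$ages
    ctEP0 <- testContrast(counts, ages[1], ages[2])
    ctEP9 <- testContrast(counts, ages[1], ages[3])
    ctP0P9 <- testContrast(counts, ages[2], ages[3])
    contrasts <- rbind(ctEP0, ctEP9, ctP0P9)
    contrasts$neg_log10_fdr <- -log10(pmax(contrasts$fdr, 1e-300))
    writeTable(contrasts, file.path(outDir, "contrasts.tsv"))
    classes <- classifyTemporal(ctEP0, ctEP9, ctP0P9,
                                alphaFdr = config$fdr)
    writeTable(classes, file.path(outDir, "classes.tsv"))
    .log(con, "stage differential: fdr=%g tested=%d early=%d late=%d",
         config$fdr, nrow(classes), sum(classes$class == "Early"),
         sum(classes$class == "Late"))

    norm <- normalizeCounts(counts)
    sig <- anchorSignal(norm$normalized, norm$design, ages)
    targets <- assignTargets(rowRanges(counts)[rownames(sig)],
                             genome$tads, genome$tss, sig, expr,
                             ages = ages)
    writeTable(targets, file.path(outDir, "targets.tsv"))
    .log(con, "stage targets: assignments=%d enhancers_with_target=%d mean_r=%.4f",
         nrow(targets), length(unique(targets$enhancer_id)),
         mean(targets$pearson_r[targets$rank == 1]))

    universe <- genome$tss$gene_id
    annotated <- unname(genome$truth$target_map)
    targetGenes <- unique(targets$gene_id[targets$rank == 1])
    perm <- permutationEnrichment(targetGenes, universe, annotated,
                                  nPerm = config$n_perm,
                                  seed = childSeed(config$seed, "perm"))
    writeTable(data.frame(observed_count = perm$observed_count,
                          n_perm = perm$n_perm,
                          null_mean = perm$null_mean,
                          null_sd = perm$null_sd,
                          p_one_sided = perm$p_one_sided),
               file.path(outDir, "target_enrichment.tsv"))
    .log(con, "stage enrich-permutation: n_perm=%d observed=%d p=%.4g",
         config$n_perm, perm$observed_count, perm$p_one_sided)

    # co-expression programs are delineated among targets of temporally
    # dynamic (Early/Late) enhancers, mirroring the classification split
    dynIds <- classes$interval_id[classes$class %in% c("Early", "Late")]
    dynGenes <- unique(targets$gene_id[targets$rank == 1 &
                                       targets$enhancer_id %in% dynIds])
    exprTargets <- expr[intersect(rownames(expr), dynGenes), , drop = FALSE]
    z <- zscoreRows(exprTargets)
    elbow <- elbowSelect(z, seed = childSeed(config$seed, "cluster"),
                         restarts = 10)
    fit <- kmeansFit(z, elbow$k, seed = childSeed(config$seed, "cluster"))
    writeTable(data.frame(gene_id = names(fit$labels),
                          cluster = unname(fit$labels),
                          stringsAsFactors = FALSE),
               file.path(outDir, "clusters.tsv"))
    profiles <- clusterProfiles(fit, z)
    rownames(profiles) <- sprintf("cluster_%d", seq_len(fit$k))
    writeTable(profiles, file.path(outDir, "cluster_profiles.tsv"),
               idColumn = "cluster")
    .log(con, "stage cluster: k=%d wss=%.3f genes=%d", fit$k, fit$wss,
         nrow(z))

    enhSeqs <- extractSequences(genome$sequences, rowRanges(counts))
    names(enhSeqs) <- rownames(counts)
    poolN <- max(4 * length(enhSeqs), 200)
    pool <- withSeed(childSeed(config$seed, "motif_pool"), {
        chrom <- names(genome$sequences)[1]
        chlen <- nchar(as.character(genome$sequences[[chrom]]))
        st <- floor(runif(poolN) * (chlen - scfg$enhancer_width)) + 1
        setNames(vapply(st, function(s)
            substr(as.character(genome$sequences[[chrom]]), s,
                   s + scfg$enhancer_width - 1), ""),
            sprintf("pool_%04d", seq_len(poolN)))
    })
    pwms <- c(list(plantedMotifPWM()),
              decoyMotifPWMs(n = 10, seed = scfg$seed))
    bg <- suppressWarnings(
        selectBackground(enhSeqs, pool,
                         seed = childSeed(config$seed, "motif_bg")))
    motifRes <- motifEnrichment(enhSeqs, bg, pwms,
                                thresholdFraction = config$motif_threshold)
    writeTable(motifRes, file.path(outDir, "motif_enrichment.tsv"))
    top <- rankMotifs(motifRes, alpha = config$motif_alpha)
    .log(con, "stage motifs: library=%d significant=%d alpha=%g",
         nrow(motifRes), nrow(top), config$motif_alpha)

    snp <- snpEnrichment(vars$index_snps, enhancerRanges(enh),
                         vars$control_snps, tss = genome$tss,
                         nResamples = config$n_resamples,
                         seed = childSeed(config$seed, "snp"))
    writeTable(data.frame(n_index = snp$n_index,
                          observed_overlap = snp$observed_overlap,
                          null_mean = snp$null_mean,
                          p_one_sided = snp$p_one_sided),
               file.path(vdir, "snp_enrichment.tsv"))
    burden <- dnmBurden(vars$dnms, enhancerRanges(enh), "all_enhancers")
    writeTable(data.frame(region_label = burden$region_label,
                          case_in = burden$table[1, 1],
                          case_out = burden$table[1, 2],
                          sib_in = burden$table[2, 1],
                          sib_out = burden$table[2, 2],
                          odds_ratio = burden$odds_ratio,
                          p_fisher = burden$p_fisher),
               file.path(vdir, "dnm_burden.tsv"))
    cnvTab <- cnvReport(vars$dnms, enh, targets, genome$tss)
    writeTable(cnvTab, file.path(vdir, "cnv_report.tsv"))
    .log(con, "stage variants: snp_p=%.4g dnm_or=%.3f dnm_p=%.4g cnv_rows=%d",
         snp$p_one_sided, burden$odds_ratio, burden$p_fisher, nrow(cnvTab))

    atlas <- lapply(seq_along(called), function(i) {
        id <- called$enhancer_id[i]
        simId <- if (id %in% names(idMap)) idMap[[id]] else NA_character_
        tg <- if (!is.na(simId))
            targets[targets$enhancer_id == simId, c("gene_id", "pearson_r",
                                                    "rank")]
        else targets[0, c("gene_id", "pearson_r", "rank")]
        cls <- if (!is.na(simId) && simId %in% classes$interval_id)
            classes$class[classes$interval_id == simId] else "untested"
        list(enhancer_id = id,
             chrom = as.character(seqnames(called))[i],
             start = start(called)[i] - 1, end = end(called)[i],
             discovery_age = called$discovery_age[i],
             ages_active = agesActive(enh)[[id]],
             class = cls,
             targets = tg)
    })
    jsonlite::write_json(atlas, file.path(outDir, "atlas.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
    .log(con, "stage atlas: records=%d", length(atlas))
    for (f in c("enhancers.bed", "classes.tsv", "contrasts.tsv",
                "targets.tsv", "clusters.tsv", "motif_enrichment.tsv",
                "atlas.json"))
        .log(con, "md5 %s %s", f,
             unname(tools::md5sum(file.path(outDir, f))))
    invisible(outDir)
}
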