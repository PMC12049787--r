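make_ce <- function(counts, species, group, gene_id = NULL) {
    CocultureExperiment(counts, species, group, gene_id)
}

test_that("species partitioning is lossless and computes composition
           ratios", {
    cnt <- rbind(h1 = c(10, 20), h2 = c(30, 40), h3 = c(10, 0),
                 m1 = c(25, 30), m2 = c(25, 30))
    ce <- make_ce(cnt, c("human", "human", "human", "mouse", "mouse"),
                  c("TT", "CC"))
    sp <- splitBySpecies(ce)
    expect_identical(nrow(sp$human), 3L)
    expect_identical(nrow(sp$mouse), 2L)
    expect_equal(unname(colSums(SummarizedExperiment::assay(sp$human)) +
                        colSums(SummarizedExperiment::assay(sp$mouse))),
                 unname(colSums(cnt)))
    expect_equal(sp$factors$ratio, c(50 / 50, 60 / 60))

    # zero species total: error naming the sample
    cnt0 <- rbind(h1 = c(10, 20), m1 = c(5, 0))
    ce0 <- make_ce(cnt0, c("human", "mouse"), c("TT", "CC"))
    expect_error(splitBySpecies(ce0), "sample02")

    # simulated composition is recovered by the stored factors
    sim <- simulateCocultureCounts(cocultureSimConfig(
        n_transcripts_h = 2000, n_transcripts_m = 2000,
        n_samples_per_group = 3, ratio_mean = 2, ratio_sd = 0,
        dropout_prob = 0, seed = 6))
    expect_true(all(abs(correctionFactors(sim$experiment)$ratio - 2) < 0.2))
})

test_that("the expression prevalence filter keeps transcripts expressed in
           at least the required sample fraction", {
    cnt <- matrix(1, nrow = 3, ncol = 9,
                  dimnames = list(c("six", "seven", "zero"), NULL))
    cnt["six", 7:9] <- 0      # 6/9 = 66.7% expressed
    cnt["seven", 8:9] <- 0    # 7/9 = 77.8%
    cnt["zero", ] <- 0
    kept <- expressionFilter(cnt, 0.75)
    expect_identical(rownames(kept), "seven")
    # boundary: exactly 75% qualifies (>= on the exact fraction)
    cnt12 <- matrix(c(rep(1, 9), rep(0, 3)), nrow = 1)
    expect_identical(nrow(expressionFilter(cnt12, 0.75)), 1L)
    # works on the container too
    ce <- make_ce(rbind(h = rep(1, 4), m = c(1, 1, 0, 0)),
                  c("human", "mouse"), c("A", "A", "B", "B"))
    expect_identical(nrow(expressionFilter(ce, 0.75)), 1L)
})

test_that("CPM normalisation identities hold, including species-specific
           effective library sizes", {
    expect_equal(computeCpm(matrix(10), library_sizes = 10)[1, 1], 1e6)
    m <- matrix(rpois(50, 40), nrow = 10)
    expect_equal(unname(colSums(computeCpm(m))), rep(1e6, 5))
    m2 <- m; m2[, 3] <- m2[, 3] * 2
    expect_equal(computeCpm(m)[, 3], computeCpm(m2)[, 3])
    # per-species: each species block sums to 1e6 in every sample
    ce <- make_ce(rbind(h1 = c(10, 100), h2 = c(30, 100),
                        m1 = c(600, 50)),
                  c("human", "human", "mouse"), c("TT", "CC"))
    cpm <- computeCpm(ce)
    expect_equal(unname(colSums(cpm[1:2, ])), rep(1e6, 2))
    expect_equal(unname(cpm[3, ]), rep(1e6, 2))
    expect_error(computeCpm(m, library_sizes = c(1, 1, 0, 1, 1)), "> 0")
})

test_that("PCA embedding separates planted groups and degrades gracefully", {
    prof <- rnorm(10, mean = 8)
    m <- cbind(prof, prof, prof + 2, prof + 2)  # duplicated samples per group
    pc <- pcaEmbed(m, log_transform = FALSE)
    expect_true(pc$explained_variance[1] > 0.99)
    expect_true(all(pc$coordinates[1:2, 1] * pc$coordinates[3:4, 1] < 0))
    expect_true(!is.unsorted(rev(pc$explained_variance)))
    # identical samples: zero variance everywhere
    flat <- matrix(5, nrow = 10, ncol = 4)
    expect_true(all(pcaEmbed(flat)$explained_variance == 0))
    expect_error(pcaEmbed(m, n_components = 20), "components")
    # planted group effect yields well-separated silhouettes on PC1-2
    sim <- simulateCocultureCounts(cocultureSimConfig(
        n_transcripts_h = 800, n_transcripts_m = 600,
        n_samples_per_group = 5, frac_de_h = 0.3, frac_de_m = 0.3,
        log2fc = 2, seed = 8))
    ce <- expressionFilter(sim$experiment)
    pc2 <- pcaEmbed(computeCpm(ce))
    lab <- as.integer(factor(sampleGroups(ce)))
    sil <- cluster::silhouette(lab, dist(pc2$coordinates))
    expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("the NB fit returns null results on constant data and matches the
           exact conditional test in the Poisson limit", {
    cnt <- matrix(7, nrow = 5, ncol = 6,
                  dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
    de <- fitNbDe(cnt, group = rep(c("A", "B"), each = 3),
                  offsets = rep(0, 6))
    expect_equal(de$log2fc, rep(0, 5))
    expect_equal(de$p_value, rep(1, 5))

    # Poisson limit on a 2-groups x 2-samples design: LRT p against the
    # exact conditional binomial split of each transcript's total
    set.seed(5)
    mu <- exp(runif(60, log(200), log(2000)))
    cnt2 <- matrix(rpois(240, rep(mu, 4)), nrow = 60)
    rownames(cnt2) <- sprintf("t%02d", 1:60)
    grp <- rep(c("A", "B"), each = 2)
    de2 <- fitNbDe(cnt2, group = grp, offsets = rep(0, 4),
                   dispersion = 1e-8)
    p_oracle <- vapply(seq_len(nrow(cnt2)), function(i) {
        tot <- sum(cnt2[i, ])
        stats::binom.test(sum(cnt2[i, grp == "A"]), tot, 0.5)$p.value
    }, numeric(1))
    comparable <- p_oracle > 1e-8   # avoid denormal tails
    expect_true(all(abs(log(de2$p_value[comparable]) -
                        log(p_oracle[comparable])) < log(1.10)))
})

test_that("planted fold changes are recovered without excess false
           discoveries", {
    sim <- simulateCocultureCounts(cocultureSimConfig(
        n_transcripts_h = 800, n_transcripts_m = 600, seed = 17))
    de <- fitNbDe(expressionFilter(sim$experiment))
    m <- merge(de, sim$truth$transcripts, by = "transcript_id")
    est <- m$log2fc.x[m$is_de] * sign(m$log2fc.y[m$is_de])
    expect_lt(abs(mean(est) - 1), 0.15)
    called <- sum(m$significant)
    expect_lte(sum(m$significant & !m$is_de) / max(1, called), 0.10)
    expect_gt(called, 0)
})

test_that("log fold changes and p-value ranks agree with an independent
           NB GLM implementation", {
    sim <- simulateCocultureCounts(cocultureSimConfig(
        n_transcripts_h = 250, n_transcripts_m = 200,
        n_samples_per_group = 5, dropout_prob = 0, seed = 23))
    ce <- expressionFilter(sim$experiment)
    cnt <- SummarizedExperiment::assay(ce, "counts")
    grp <- factor(sampleGroups(ce), levels = unique(sampleGroups(ce)))
    tot <- speciesTotals(ce)
    off <- matrix(rep(log(tot[, "mouse"]), each = nrow(cnt)), nrow(cnt))
    off[speciesLabels(ce) == "human", ] <-
        matrix(rep(log(tot[, "human"]),
                   each = sum(speciesLabels(ce) == "human")),
               sum(speciesLabels(ce) == "human"))
    de <- fitNbDe(ce)

    y <- edgeR::DGEList(cnt)
    y <- edgeR::scaleOffset(y, off)
    design <- stats::model.matrix(~grp)
    y <- edgeR::estimateDisp(y, design)
    fit <- edgeR::glmFit(y, design)
    lrt <- edgeR::glmLRT(fit, coef = 2)
    expect_gt(cor(de$log2fc, lrt$table$logFC), 0.98)
    expect_gt(cor(rank(de$p_value), rank(lrt$table$PValue)), 0.9)
})

test_that("gene representatives are the top-ranked transcripts with
           documented tie-breaks", {
    de <- data.frame(
        transcript_id = c("t1", "t2", "t3", "t4", "t5"),
        gene_id = c("g1", "g1", "g2", NA, "g3"),
        p_value = c(0.01, 0.5, 0.2, 0.9, 0.9),
        mean_count = c(5, 50, 10, 1, 1),
        stringsAsFactors = FALSE)
    out <- representGenes(de)
    expect_identical(out$gene_representative,
                     c(TRUE, FALSE, TRUE, TRUE, TRUE))
    expect_identical(out$gene_id[4], "t4")   # unmapped: own gene
    # tie on p: larger mean expression wins
    tie <- data.frame(transcript_id = c("a", "b"), gene_id = "g",
                      p_value = 0.2, mean_count = c(1, 9),
                      stringsAsFactors = FALSE)
    expect_identical(representGenes(tie)$gene_representative[2], TRUE)
    # an external map overrides missing gene ids
    mapped <- representGenes(de[, -2],
                             transcript_to_gene = c(t1 = "gX", t2 = "gX",
                                                    t3 = "gY", t4 = "gY",
                                                    t5 = "gZ"))
    expect_identical(sum(mapped$gene_representative), 3L)
})

test_that("null p-values stay calibrated after label permutation", {
    sim <- simulateCocultureCounts(cocultureSimConfig(
        n_transcripts_h = 1200, n_transcripts_m = 800, frac_de_h = 0,
        frac_de_m = 0, dropout_prob = 0, seed = 31))
    ce <- expressionFilter(sim$experiment)
    grp <- sampleGroups(ce)
    perm <- withr::with_seed(1, sample(grp))
    de <- fitNbDe(ce, group = perm)
    expect_gt(stats::ks.test(de$p_value, "punif")$p.value, 0.01)
    expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.02)
})
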