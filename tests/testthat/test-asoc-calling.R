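test_that("per-record het filters enforce depth, minor-allele and tranche
           rules at their boundaries", {
    cases <- list(
        # ref, alt, gt, retained?
        list(10, 9,  "0/1", FALSE),   # depth 19 < 20
        list(18, 2,  "0/1", TRUE),    # depth 20, both alleles >= 2
        list(19, 1,  "0/1", FALSE),   # minor allele 1 < 2
        list(2,  18, "1|0", TRUE),    # phased het accepted
        list(50, 50, "0/0", FALSE),   # homozygous
        list(50, 50, "1/1", FALSE),
        list(50, 50, "./.", FALSE))   # missing genotype
    for (cs in cases) {
        out <- filterHetRecords(make_record(cs[[1]], cs[[2]], gt = cs[[3]]))
        expect_identical(nrow(out) == 1L, cs[[4]],
                         info = paste(unlist(cs), collapse = "/"))
    }

    # malformed genotype: warning, record dropped, run continues
    recs <- rbind(make_record(30, 30), make_record(30, 30, gt = "A/B"))
    expect_warning(out <- filterHetRecords(recs), "malformed")
    expect_identical(nrow(out), 1L)

    # tranche is a strict pass-through filter; absent values pass
    expect_identical(nrow(filterHetRecords(
        make_record(30, 30, tranche = 99.4))), 0L)
    expect_identical(nrow(filterHetRecords(
        make_record(30, 30, tranche = 99.6))), 1L)
    expect_identical(nrow(filterHetRecords(
        make_record(30, 30, tranche = NA))), 1L)

    # depth is recomputed; disagreeing DP fields are reported
    expect_warning(filterHetRecords(make_record(30, 30, dp = 55)),
                   "DP field disagreeing")
})

test_that("allelic counts pool per SNP across retained samples", {
    recs <- rbind(
        make_record(10, 5, sample_id = "d1"),
        make_record(7, 8, sample_id = "d2"),
        make_record(12, 8, snp_id = "rs2", sample_id = "d1"))
    agg <- aggregateAllelicCounts(recs)
    agg <- agg[order(agg$snp_id), ]
    expect_equal(agg$total_ref, c(17, 12))
    expect_equal(agg$total_alt, c(13, 8))
    expect_equal(agg$n_samples, c(2L, 1L))
    # totals conserve the record counts
    expect_equal(sum(agg$total_ref + agg$total_alt),
                 sum(recs$ref_count + recs$alt_count))
    # conflicting allele orientation is an error
    bad <- rbind(make_record(10, 5), make_record(5, 10))
    bad$ref[2] <- "G"; bad$alt[2] <- "A"
    expect_error(aggregateAllelicCounts(bad), "orientation")
})

test_that("two-sided exact binomial p-values match enumeration, closed forms
           and binom.test", {
    expect_equal(binomTwoSided(5, 10), 1)
    expect_equal(binomTwoSided(2, 20), 422 / 2^20)
    expect_equal(binomTwoSided(0, 20), 2 / 2^20)
    expect_equal(binomTwoSided(c(5, 2, 0), c(10, 20, 20)),
                 c(1, 422 / 2^20, 2 / 2^20))
    expect_error(binomTwoSided(5, 0), "n >= 1")
    expect_error(binomTwoSided(11, 10), "x <= n")

    set.seed(42)
    for (i in 1:50) {
        n <- sample(1:500, 1)
        x <- sample(0:n, 1)
        expect_equal(binomTwoSided(x, n),
                     stats::binom.test(x, n, p = 0.5)$p.value,
                     tolerance = 1e-12)
    }
    # general null probability takes the enumeration path
    for (i in 1:20) {
        n <- sample(1:100, 1)
        x <- sample(0:n, 1)
        expect_equal(binomTwoSided(x, n, p0 = 0.3),
                     stats::binom.test(x, n, p = 0.3)$p.value,
                     tolerance = 1e-9)
        expect_equal(binomTwoSided(x, n, p0 = 0.3), brute_binom_p(x, n, 0.3),
                     tolerance = 1e-12)
    }
})

test_that("BH adjustment reproduces the step-up definition", {
    expect_equal(bhAdjust(c(1, 1, 1)), c(1, 1, 1))
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_identical(bhAdjust(numeric(0)), numeric(0))
    expect_error(bhAdjust(c(0.5, 0)), "0, 1")
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    set.seed(11)
    for (i in 1:200) {
        p <- runif(sample(1:50, 1))^sample(1:3, 1)
        p[p == 0] <- 1e-12
        expect_equal(bhAdjust(p), brute_bh(p), tolerance = 1e-12)
    }
})

test_that("the calling pipeline composes filter, pooling, test, BH and
           threshold", {
    # perfectly balanced pooled counts: p = 1 everywhere, no calls
    recs <- do.call(rbind, lapply(1:5, function(i)
        make_record(30, 30, snp_id = paste0("rs", i))))
    calls <- callASoC(recs)
    expect_true(all(calls$p_value == 1))
    expect_identical(sum(calls$is_asoc), 0L)

    # a single fully skewed SNP is called at FDR 0.05 (p = 2 * 0.5^200,
    # m = 1); the minor-allele filter is lifted because a (200, 0) record
    # cannot pass the het-confirmation rule
    one <- callASoC(make_record(200, 0, sample_id = "d1"), min_allele = 0)
    expect_identical(nrow(one), 1L)
    expect_true(one$is_asoc)
    expect_equal(one$p_value, 2 * 0.5^200)
    # under the default filters the same evidence needs both alleles seen
    two <- callASoC(make_record(200, 2, sample_id = "d1"))
    expect_true(two$is_asoc)

    # calls are a subset of SNPs surviving the record filter; totals conserve
    sim <- simulateAllelicCounts(asocSimConfig(n_snps = 400, seed = 13))
    kept <- filterHetRecords(sim$records)
    calls <- callASoC(sim$records)
    expect_true(all(calls$snp_id %in% kept$snp_id))
    expect_equal(sum(calls$total_ref + calls$total_alt),
                 sum(kept$ref_count + kept$alt_count))
    expect_false(is.unsorted(calls$q_value))

    # empty survivors: empty table with a warning, not an error
    expect_warning(none <- callASoC(make_record(5, 5)), "no records")
    expect_identical(nrow(none), 0L)

    # peak annotation riding on the calls
    pk <- simulatePeaks(sim$truth, covered_fraction = 0.5, seed = 3)
    withpk <- callASoC(sim$records, peaks = pk)
    snp_pos <- sim$truth[match(withpk$snp_id, sim$truth$snp_id), ]
    expect_identical(withpk$in_peak,
                     overlapSnpsWithPeaks(snp_pos, pk))
})

test_that("SNP-in-peak overlap honours the BED half-open convention", {
    snp <- data.frame(chrom = "chr8", pos = 101)
    expect_true(overlapSnpsWithPeaks(
        snp, data.frame(chrom = "chr8", start = 100, end = 101)))
    expect_false(overlapSnpsWithPeaks(
        snp, data.frame(chrom = "chr8", start = 101, end = 200)))
    # same interval, wrong chromosome
    expect_false(suppressWarnings(overlapSnpsWithPeaks(
        snp, data.frame(chrom = "chr7", start = 100, end = 101))))
    expect_error(overlapSnpsWithPeaks(
        snp, data.frame(chrom = "chr8", start = 100, end = 100)),
        "end <= start")
})

test_that("Monte-Carlo power is null-calibrated, saturates under strong
           imbalance, and reproduces the frozen regression value", {
    p0 <- estimatePower(depth_per_donor = 100, n_donors = 10,
                        alt_fraction = 0.5, n_null_background = 200,
                        n_reps = 400, seed = 2)
    expect_lte(p0$power, 0.05 + 3 * max(p0$mc_se, sqrt(0.05 * 0.95 / 400)))

    p1 <- estimatePower(depth_per_donor = 100, n_donors = 10,
                        alt_fraction = 0.9, n_null_background = 200,
                        n_reps = 200, seed = 2)
    expect_gte(p1$power, 0.99)

    # Monte-Carlo regression constant (alt 0.65, depth 100 x 10 donors,
    # 1000 null SNPs, 2000 reps, seed 1): pooled depth ~1000 gives a
    # z-score ~9.5, so the pipeline calls the SNP in every replicate.
    pr <- estimatePower(depth_per_donor = 100, n_donors = 10,
                        alt_fraction = 0.65, n_null_background = 1000,
                        n_reps = 2000, seed = 1)
    expect_identical(pr$power, 1)
    expect_identical(pr$mc_se, 0)

    expect_error(estimatePower(100, 10, 1, 100, n_reps = 100), "alt_fraction")
    expect_error(estimatePower(100, 10, 0.6, 100, n_reps = 50), "n_reps")
})

test_that("the vectorised power replicate matches callASoC on the same
           draws", {
    m <- 41L; n_donors <- 6L; depth <- 80; alt <- 0.7
    p_true <- c(alt, rep(0.5, m - 1L))
    dec <- withr::with_seed(99, ASoCkit:::.power_one_rep(
        m, n_donors, depth, Inf, p_true, 20, 2, 0.05))
    # regenerate the identical draws and push them through the full caller
    dec2 <- withr::with_seed(99, {
        d <- matrix(rpois(m * n_donors, depth), m, n_donors)
        a <- matrix(rbinom(m * n_donors, d, p_true), m, n_donors)
        recs <- data.frame(
            snp_id = rep(sprintf("s%03d", seq_len(m)), n_donors),
            chrom = "chr1", pos = rep(seq_len(m), n_donors),
            ref = "A", alt = "G",
            sample_id = rep(sprintf("d%02d", seq_len(n_donors)), each = m),
            gt = "0/1",
            ref_count = as.vector(d - a), alt_count = as.vector(a),
            stringsAsFactors = FALSE)
        calls <- callASoC(recs)
        isTRUE(calls$is_asoc[calls$snp_id == "s001"])
    })
    expect_identical(dec, dec2)
})
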