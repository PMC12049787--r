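#' Configuration for the allelic ATAC-seq count simulator
#'
#' Defines the generative model for per-donor allelic read counts at
#' heterozygous SNPs.  Each donor is heterozygous at a SNP with probability
#' `het_prob`; a heterozygous donor's total depth is negative-binomial with
#' mean `depth_mean` and size `depth_dispersion` (`Inf` gives Poisson); the
#' alt-allele read count is binomial with success probability
#' `p_eff = a / (a + ref_bias * (1 - a))` where `a` is `alt_fraction` for the
#' imbalanced SNPs and 0.5 otherwise.  `ref_bias > 1` therefore emulates
#' reference-mapping bias favouring the reference allele; the caller itself
#' applies no bias correction, the knob exists to probe robustness.
#'
#' @param n_snps number of SNPs.
#' @param n_donors number of donors.
#' @param het_prob per-donor, per-SNP heterozygosity probability.
#' @param depth_mean expected total reads per heterozygous donor per SNP.
#' @param depth_dispersion negative-binomial size; `Inf` means Poisson depth.
#' @param frac_imbalanced proportion of SNPs with true allelic imbalance.
#' @param alt_fraction true alt-read probability at imbalanced SNPs, in (0,1).
#' @param ref_bias multiplicative mapping-bias factor (1 = unbiased).
#' @param seed integer RNG seed; identical configs give identical output.
#' @return An object of class `ASoCSimConfig` (validated list).
#' @seealso [simulateAllelicCounts()]
#' @export
asocSimConfig <- function(n_snps = 1000L, n_donors = 10L, het_prob = 0.5,
                          depth_mean = 60, depth_dispersion = 10,
                          frac_imbalanced = 0.1, alt_fraction = 0.7,
                          ref_bias = 1, seed = 1L) {
    .check_count(n_snps, "n_snps")
    .check_count(n_donors, "n_donors")
    .check_prob(het_prob, "het_prob")
    .check_prob(frac_imbalanced, "frac_imbalanced")
    if (!is.finite(alt_fraction) || alt_fraction <= 0 || alt_fraction >= 1)
        stop("'alt_fraction' must be in (0, 1)")
    if (!is.finite(depth_mean) || depth_mean <= 0)
        stop("'depth_mean' must be > 0")
    if (is.na(depth_dispersion) || depth_dispersion <= 0)
        stop("'depth_dispersion' must be > 0 (Inf for Poisson)")
    if (!is.finite(ref_bias) || ref_bias <= 0)
        stop("'ref_bias' must be > 0")
    structure(list(n_snps = as.integer(n_snps), n_donors = as.integer(n_donors),
                   het_prob = het_prob, depth_mean = depth_mean,
                   depth_dispersion = depth_dispersion,
                   frac_imbalanced = frac_imbalanced,
                   alt_fraction = alt_fraction, ref_bias = ref_bias,
                   seed = as.integer(seed)),
              class = "ASoCSimConfig")
}

.check_count <- function(x, what) {
    if (length(x) != 1L || is.na(x) || !is.finite(x) || x < 1 || x != round(x))
        stop("'", what, "' must be a positive integer")
}

.check_prob <- function(x, what) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
        stop("'", what, "' must be in [0, 1]")
}

#' Simulate per-donor allelic ATAC-seq counts at heterozygous SNPs
#'
#' Generates the long-format allelic count table consumed by [callASoC()],
#' one row per (SNP, heterozygous donor), together with the per-SNP ground
#' truth.  Non-heterozygous donor/SNP pairs emit no record.
#'
#' @param config an [asocSimConfig()].
#' @return A list with elements
#'   * `records`: `data.frame` with columns `snp_id`, `chrom`, `pos`
#'     (1-based), `ref`, `alt`, `sample_id`, `gt`, `ref_count`, `alt_count`;
#'   * `truth`: per-SNP `data.frame` with `snp_id`, `chrom`, `pos`,
#'     `is_imbalanced`, `alt_fraction` (the true binomial parameter before
#'     mapping bias) and `p_eff` (after bias).
#' @examples
#' sim <- simulateAllelicCounts(asocSimConfig(n_snps = 50, seed = 7))
#' head(sim$records)
#' @export
simulateAllelicCounts <- function(config) {
    if (!inherits(config, "ASoCSimConfig"))
        stop("'config' must come from asocSimConfig()")
    withr::with_seed(config$seed, {
        n <- config$n_snps
        d <- config$n_donors
        snp_id <- sprintf("snp%05d", seq_len(n))
        pos <- 1000L * seq_len(n)
        ref <- sample(DNA_BASES4, n, replace = TRUE)
        alt <- vapply(ref, function(b)
            sample(setdiff(DNA_BASES4, b), 1L), character(1), USE.NAMES = FALSE)
        imb <- stats::runif(n) < config$frac_imbalanced
        a <- ifelse(imb, config$alt_fraction, 0.5)
        p_eff <- a / (a + config$ref_bias * (1 - a))

        truth <- data.frame(snp_id = snp_id, chrom = "chr1", pos = pos,
                            is_imbalanced = imb, alt_fraction = a,
                            p_eff = p_eff, stringsAsFactors = FALSE)
        het <- matrix(stats::runif(n * d) < config$het_prob, n, d)
        idx <- which(het, arr.ind = TRUE)
        nh <- nrow(idx)
        if (nh == 0L)
            return(list(records = .empty_records(), truth = truth))
        depth <- if (is.infinite(config$depth_dispersion))
            stats::rpois(nh, config$depth_mean)
        else
            stats::rnbinom(nh, size = config$depth_dispersion,
                           mu = config$depth_mean)
        alt_count <- stats::rbinom(nh, depth, p_eff[idx[, 1L]])
        ord <- order(idx[, 1L], idx[, 2L])
        records <- data.frame(
            snp_id = snp_id[idx[ord, 1L]],
            chrom = "chr1",
            pos = pos[idx[ord, 1L]],
            ref = ref[idx[ord, 1L]],
            alt = alt[idx[ord, 1L]],
            sample_id = sprintf("donor%02d", idx[ord, 2L]),
            gt = "0/1",
            ref_count = (depth - alt_count)[ord],
            alt_count = alt_count[ord],
            stringsAsFactors = FALSE)
        list(records = records, truth = truth)
    })
}

#' Simulate open-chromatin peak intervals around a chosen fraction of SNPs
#'
#' Emits non-overlapping intervals such that a randomly chosen
#' `covered_fraction` of the SNPs fall strictly inside one peak and the
#' remaining SNPs fall inside none.  Peaks are clipped at the midpoints
#' between neighbouring SNPs so that a peak never swallows an uncovered
#' neighbour.
#'
#' @param snps `data.frame` with columns `chrom` and `pos` (1-based), e.g.
#'   the `truth` table of [simulateAllelicCounts()], or a
#'   [GenomicRanges::GRanges] of width-1 positions.
#' @param covered_fraction fraction of SNPs to cover, in \[0, 1\]; the number
#'   of covered SNPs is `round(covered_fraction * n)`.
#' @param peak_halfwidth nominal half-width of each peak in bp.
#' @param seed RNG seed for choosing which SNPs are covered.
#' @return A sorted [GenomicRanges::GRanges] of peaks (1-based, closed), with
#'   a logical per-SNP attribute-free design: use [overlapSnpsWithPeaks()] to
#'   recover coverage.  Write with [writeBed()] for the 0-based half-open
#'   file form.
#' @export
simulatePeaks <- function(snps, covered_fraction, peak_halfwidth = 250L,
                          seed = 1L) {
    .check_prob(covered_fraction, "covered_fraction")
    snps <- .as_snp_frame(snps)
    n <- nrow(snps)
    withr::with_seed(as.integer(seed), {
        covered <- logical(n)
        covered[sample.int(n, round(covered_fraction * n))] <- TRUE
        out <- vector("list", length(unique(snps$chrom)))
        names(out) <- unique(snps$chrom)
        for (ch in unique(snps$chrom)) {
            sel <- snps$chrom == ch
            p0 <- sort(snps$pos[sel]) - 1L           # 0-based SNP coordinates
            cov <- covered[sel][order(snps$pos[sel])]
            mid_lo <- c(-1L, floor((p0[-length(p0)] + p0[-1L]) / 2))
            mid_hi <- c(mid_lo[-1L], p0[length(p0)] + peak_halfwidth + 1L)
            start0 <- pmax(p0 - peak_halfwidth, mid_lo + 1L, 0L)
            end0 <- pmin(p0 + peak_halfwidth + 1L, mid_hi + 1L)
            out[[ch]] <- GenomicRanges::GRanges(
                rep(ch, sum(cov)),
                IRanges::IRanges(start = start0[cov] + 1L,
                                 end = end0[cov]))
        }
        # per-chromosome construction is already position-sorted
        unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
    })
}

.as_snp_frame <- function(snps) {
    if (methods::is(snps, "GRanges"))
        return(data.frame(
            chrom = as.character(GenomicRanges::seqnames(snps)),
            pos = GenomicRanges::start(snps),
            stringsAsFactors = FALSE))
    if (!is.data.frame(snps) || !all(c("chrom", "pos") %in% names(snps)))
        stop("'snps' must be a GRanges or a data.frame with chrom and pos")
    snps
}
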