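REQUIRED_RECORD_COLS <- c("snp_id", "chrom", "pos", "ref", "alt",
                          "sample_id", "gt", "ref_count", "alt_count")
HET_GENOTYPES <- c("0/1", "1/0", "0|1", "1|0")

.check_records <- function(records) {
    miss <- setdiff(REQUIRED_RECORD_COLS, names(records))
    if (length(miss))
        stop("allelic count records are missing column(s): ",
             paste(miss, collapse = ", "))
    if (any(records$ref_count < 0 | records$alt_count < 0, na.rm = TRUE))
        stop("ref_count/alt_count must be non-negative")
    invisible(records)
}

#' Filter per-sample heterozygous allelic count records
#'
#' Applies the per-record retention rules used before pooling: the genotype
#' must be heterozygous biallelic (`0/1`, `1/0` or the phased equivalents),
#' total depth (`ref_count + alt_count`) must reach `min_dp`, both alleles
#' must be supported by at least `min_allele` reads, and when a `tranche`
#' column is present its value must exceed `min_tranche` (records without a
#' tranche value pass that clause).  Records with malformed genotype strings
#' are dropped with a warning rather than aborting the run.
#'
#' Depth is always recomputed as `ref_count + alt_count`; when a `dp` column
#' is present and disagrees, a warning reports how many records mismatched.
#'
#' @param records `data.frame` of allelic count records (columns `snp_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `sample_id`, `gt`, `ref_count`,
#'   `alt_count`, optionally `dp` and `tranche`).
#' @param min_dp minimum total read depth per record (default 20).
#' @param min_allele minimum read count for each allele (default 2) --
#'   a heterozygosity-confirmation filter: both alleles must be observed.
#' @param min_tranche variant-quality tranche cutoff in percent
#'   (strictly greater than; default 99.5).
#' @return The retained records, same columns as the input.
#' @examples
#' recs <- data.frame(snp_id = "rs1", chrom = "chr8", pos = 27608798,
#'                    ref = "T", alt = "C", sample_id = "d1", gt = "0/1",
#'                    ref_count = 18, alt_count = 2)
#' filterHetRecords(recs)   # depth 20, both alleles >= 2: retained
#' @export
filterHetRecords <- function(records, min_dp = 20, min_allele = 2,
                             min_tranche = 99.5) {
    .check_records(records)
    gt <- as.character(records$gt)
    well_formed <- grepl("^[0-9.]+([/|][0-9.]+)?$", gt)
    if (any(!well_formed))
        warning(sum(!well_formed), " record(s) with malformed genotype ",
                "strings were excluded")
    is_het <- well_formed & gt %in% HET_GENOTYPES
    depth <- records$ref_count + records$alt_count
    if ("dp" %in% names(records)) {
        bad_dp <- !is.na(records$dp) & records$dp != depth
        if (any(bad_dp))
            warning(sum(bad_dp), " record(s) had a DP field disagreeing ",
                    "with ref_count + alt_count; depth was recomputed")
    }
    keep <- is_het & depth >= min_dp &
        pmin(records$ref_count, records$alt_count) >= min_allele
    if ("tranche" %in% names(records))
        keep <- keep & (is.na(records$tranche) | records$tranche > min_tranche)
    records[keep, , drop = FALSE]
}

#' Pool allelic counts of each SNP across heterozygous samples
#'
#' Sums reference and alternative read counts per SNP over all retained
#' records, the combination step preceding the binomial test.
#'
#' @param records filtered allelic count records (see [filterHetRecords()]).
#' @return `data.frame` with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `total_ref`, `total_alt`, `n_samples`.
#' @examples
#' recs <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 100, ref = "A",
#'                    alt = "G", sample_id = c("d1", "d2"), gt = "0/1",
#'                    ref_count = c(10, 7), alt_count = c(5, 8))
#' aggregateAllelicCounts(recs)
#' @export
aggregateAllelicCounts <- function(records) {
    .check_records(records)
    dt <- data.table::as.data.table(records)
    conf <- dt[, list(n_ref = data.table::uniqueN(ref),
                      n_alt = data.table::uniqueN(alt)), by = "snp_id"]
    bad <- conf[conf$n_ref > 1L | conf$n_alt > 1L, ]
    if (nrow(bad))
        stop("conflicting ref/alt allele orientation for SNP(s): ",
             paste(utils::head(bad$snp_id, 5L), collapse = ", "))
    agg <- dt[, list(chrom = chrom[1L], pos = pos[1L], ref = ref[1L],
                     alt = alt[1L],
                     total_ref = sum(ref_count), total_alt = sum(alt_count),
                     n_samples = .N), by = "snp_id"]
    data.table::setDF(agg)
    agg
}

#' Exact two-sided binomial p-value (minimum-likelihood rule)
#'
#' Computes the two-sided exact binomial p-value as the sum of
#' `Binomial(n, p0)` probabilities over all outcomes no more likely than the
#' observed one (ties admitted within a relative tolerance of 1e-7), the
#' convention of [stats::binom.test()].  At `p0 = 0.5` this reduces to the
#' closed form `min(1, 2 * P(X <= min(x, n - x)))`, which is used for speed;
#' other null values fall back to explicit enumeration.  Vectorised over
#' `x` and `n`.
#'
#' @param x observed successes (e.g. pooled reference-allele reads).
#' @param n number of trials (pooled total depth); must be >= 1.
#' @param p0 null success probability (default 0.5, allelic balance).
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' binomTwoSided(5, 10)          # most likely outcome: p = 1
#' binomTwoSided(2, 20)          # = 422 / 2^20
#' @export
binomTwoSided <- function(x, n, p0 = 0.5) {
    if (length(x) == 0L) return(numeric(0))
    k <- pmax(length(x), length(n))
    x <- rep_len(x, k); n <- rep_len(n, k)
    if (any(is.na(x)) || any(is.na(n)) || any(n < 1) || any(x < 0) ||
        any(x > n) || any(x != round(x)) || any(n != round(n)))
        stop("'x' and 'n' must satisfy 0 <= x <= n, n >= 1")
    if (length(p0) != 1L || !is.finite(p0) || p0 <= 0 || p0 >= 1)
        stop("'p0' must be a single probability in (0, 1)")
    if (p0 == 0.5) {
        d <- pmin(x, n - x)
        return(pmin(1, 2 * stats::pbinom(d, n, 0.5)))
    }
    vapply(seq_len(k), function(i) {
        pm <- stats::dbinom(0:n[i], n[i], p0)
        sum(pm[pm <= pm[x[i] + 1L] * (1 + 1e-7)])
    }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over all qualified SNPs, delegating to
#' [stats::p.adjust()]; input validation enforces p in (0, 1] and an empty
#' input maps to an empty output.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Flag SNPs falling inside open-chromatin peaks
#'
#' A SNP overlaps a peak when its 0-based coordinate `pos - 1` satisfies
#' `start <= pos - 1 < end` for some peak on the same chromosome (BED
#' half-open convention).  Peaks supplied as a `GRanges` are taken 1-based
#' closed, e.g. from [readBed()] or [simulatePeaks()]; a `data.frame` with
#' `chrom`/`start`/`end` is interpreted as 0-based half-open BED and
#' validated.
#'
#' @param snps `data.frame` with `chrom` and 1-based `pos`, or a `GRanges`.
#' @param peaks `GRanges` (1-based) or BED-like `data.frame` (0-based
#'   half-open).
#' @return logical vector, one flag per SNP.
#' @examples
#' snps <- data.frame(chrom = "chr8", pos = 101)
#' peaks <- data.frame(chrom = "chr8", start = 100, end = 101)
#' overlapSnpsWithPeaks(snps, peaks)   # TRUE: 0-based 100 is inside [100,101)
#' @export
overlapSnpsWithPeaks <- function(snps, peaks) {
    snps <- .as_snp_frame(snps)
    if (!methods::is(peaks, "GRanges")) {
        if (!is.data.frame(peaks) ||
            !all(c("chrom", "start", "end") %in% names(peaks)))
            stop("'peaks' must be a GRanges or a BED-like data.frame")
        if (any(peaks$end <= peaks$start))
            stop("malformed peak interval(s): end <= start")
        peaks <- GenomicRanges::GRanges(
            peaks$chrom,
            IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
    }
    if (any(GenomicRanges::width(peaks) < 1L))
        stop("malformed peak interval(s): end <= start")
    gr <- GenomicRanges::GRanges(snps$chrom,
                                 IRanges::IRanges(snps$pos, snps$pos))
    IRanges::overlapsAny(gr, peaks)
}

#' Call allele-specific open chromatin SNPs
#'
#' The full ASoC calling pipeline: per-record filtering
#' ([filterHetRecords()]), pooling across heterozygous samples
#' ([aggregateAllelicCounts()]), exact two-sided binomial test of the pooled
#' reference fraction against 0.5 ([binomTwoSided()]), Benjamini-Hochberg
#' correction ([bhAdjust()]), and thresholding at `q < fdr`.  When peaks are
#' supplied each SNP is annotated with open-chromatin overlap.
#'
#' @param records allelic count records (see [filterHetRecords()] for the
#'   schema); technical replicates are pooled like distinct samples unless
#'   `collapse_donors = TRUE` and a `donor_id` column is present, in which
#'   case counts are first summed within donor.
#' @param fdr FDR cutoff; calls satisfy `q_value < fdr` (strict).
#' @param peaks optional peak set for [overlapSnpsWithPeaks()].
#' @param min_dp,min_allele,min_tranche per-record filters, see
#'   [filterHetRecords()].
#' @param collapse_donors sum technical replicates within donor before
#'   filtering (default `FALSE`).
#' @return `data.frame` sorted by `q_value` then `p_value`: `snp_id`,
#'   `chrom`, `pos`, `total_ref`, `total_alt`, `n_samples`, `ref_fraction`,
#'   `p_value`, `q_value`, `is_asoc`, `in_peak` (`NA` when no peaks given).
#' @examples
#' sim <- simulateAllelicCounts(asocSimConfig(n_snps = 200, seed = 11))
#' calls <- callASoC(sim$records)
#' head(calls)
#' @export
callASoC <- function(records, fdr = 0.05, peaks = NULL, min_dp = 20,
                     min_allele = 2, min_tranche = 99.5,
                     collapse_donors = FALSE) {
    if (collapse_donors && "donor_id" %in% names(records)) {
        dt <- data.table::as.data.table(records)
        dt <- dt[, list(ref_count = sum(ref_count),
                        alt_count = sum(alt_count)),
                 by = c("snp_id", "chrom", "pos", "ref", "alt", "gt",
                        "donor_id")]
        data.table::setnames(dt, "donor_id", "sample_id")
        records <- data.table::setDF(dt)
    }
    kept <- filterHetRecords(records, min_dp = min_dp,
                             min_allele = min_allele,
                             min_tranche = min_tranche)
    empty <- data.frame(snp_id = character(), chrom = character(),
                        pos = integer(), total_ref = integer(),
                        total_alt = integer(), n_samples = integer(),
                        ref_fraction = numeric(), p_value = numeric(),
                        q_value = numeric(), is_asoc = logical(),
                        in_peak = logical(), stringsAsFactors = FALSE)
    if (nrow(kept) == 0L) {
        warning("no records survived filtering; returning an empty call table")
        return(empty)
    }
    agg <- aggregateAllelicCounts(kept)
    total <- agg$total_ref + agg$total_alt
    p <- binomTwoSided(agg$total_ref, total)
    q <- bhAdjust(p)
    out <- data.frame(snp_id = agg$snp_id, chrom = agg$chrom, pos = agg$pos,
                      total_ref = agg$total_ref, total_alt = agg$total_alt,
                      n_samples = agg$n_samples,
                      ref_fraction = agg$total_ref / total,
                      p_value = p, q_value = q, is_asoc = q < fdr,
                      in_peak = NA, stringsAsFactors = FALSE)
    if (!is.null(peaks))
        out$in_peak <- overlapSnpsWithPeaks(out, peaks)
    out[order(out$q_value, out$p_value), , drop = FALSE]
}
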