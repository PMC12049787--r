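# Independent brute-force oracles and small fixture builders shared across
# the test files.  These deliberately avoid the package's own code paths.

# Minimum-likelihood two-sided binomial p by exhaustive pmf enumeration.
brute_binom_p <- function(x, n, p0 = 0.5) {
    pm <- dbinom(0:n, n, p0)
    sum(pm[pm <= pm[x + 1L] * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by its textbook definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1, mapped back.
brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q_sorted <- numeric(m)
    run_min <- Inf
    for (i in m:1) {
        run_min <- min(run_min, m * ps[i] / i)
        q_sorted[i] <- min(1, run_min)
    }
    q <- numeric(m)
    q[o] <- q_sorted
    q
}

rc_string <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
          collapse = "")
}

# Exhaustive best log2-odds over all SNP-covering placements and strands,
# written independently of the package scanner.
brute_motif_best <- function(probs, background, window, snp_index) {
    L <- nrow(probs)
    score_at <- function(w, idx) {
        b <- strsplit(w, "")[[1]]
        wlen <- length(b)
        best <- -Inf
        for (o in seq_len(max(wlen - L + 1L, 0L))) {
            if (!(o <= idx && idx <= o + L - 1L)) next
            s <- 0
            for (i in seq_len(L)) {
                base <- b[o + i - 1L]
                if (base == "N") next
                j <- match(base, c("A", "C", "G", "T"))
                s <- s + log2(probs[i, j] / background[j])
            }
            best <- max(best, s)
        }
        best
    }
    wlen <- nchar(window)
    max(score_at(toupper(window), snp_index),
        score_at(rc_string(window), wlen - snp_index + 1L))
}

random_pwm <- function(L, seed, concentration = 0.5) {
    set.seed(seed)
    m <- matrix(rgamma(4L * L, shape = concentration) + 1e-3, ncol = 4)
    m <- m / rowSums(m)
    colnames(m) <- c("A", "C", "G", "T")
    PositionWeightMatrix(m, name = sprintf("rand%02d", L))
}

# A sharply informative 8-position motif used for disruption fixtures.
informative_pwm <- function() {
    counts <- matrix(c(
        90,  4,  3,  3,
         2, 92,  3,  3,
         3,  3, 90,  4,
        90,  3,  4,  3,
         3, 90,  3,  4,
         4,  3,  3, 90,
        90,  4,  3,  3,
         3,  3, 92,  2), byrow = TRUE, ncol = 4,
        dimnames = list(NULL, c("A", "C", "G", "T")))
    pfmToPwm(counts, name = "synthTF")
}

.read_asockit_tsv <- function(path) ASoCkit:::.read_tsv(path)

make_record <- function(ref_count, alt_count, gt = "0/1", snp_id = "rs1",
                        sample_id = "d1", tranche = NULL, dp = NULL) {
    df <- data.frame(snp_id = snp_id, chrom = "chr1", pos = 1000L,
                     ref = "A", alt = "G", sample_id = sample_id, gt = gt,
                     ref_count = ref_count, alt_count = alt_count,
                     stringsAsFactors = FALSE)
    if (!is.null(tranche)) df$tranche <- tranche
    if (!is.null(dp)) df$dp <- dp
    df
}
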