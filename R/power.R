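#' Monte-Carlo power of the ASoC calling pipeline
#'
#' Estimates the probability that a truly imbalanced SNP is called by the
#' full pipeline (per-record depth and minor-allele filters, pooling across
#' heterozygous donors, exact two-sided binomial test, Benjamini-Hochberg
#' step-up over the SNP and `n_null_background` balanced background SNPs,
#' strict `q < fdr` threshold).  Each replicate simulates one imbalanced SNP
#' with per-donor alt-read probability `alt_fraction` alongside the balanced
#' background and records whether it is called.
#'
#' Per-donor depths are Poisson around `depth_per_donor` by default; a finite
#' `depth_dispersion` draws negative-binomial depths instead.  All donors are
#' taken heterozygous -- `n_donors` counts the heterozygous donor lines
#' contributing reads.
#'
#' @param depth_per_donor expected reads per heterozygous donor at the SNP.
#' @param n_donors number of heterozygous donors.
#' @param alt_fraction true alt-read probability of the imbalanced SNP,
#'   in (0, 1).
#' @param n_null_background number of balanced background SNPs competing in
#'   the BH correction.
#' @param fdr FDR threshold (strict `<`).
#' @param n_reps Monte-Carlo replicates (at least 100).
#' @param seed integer RNG seed.
#' @param min_dp,min_allele per-record filters as in [filterHetRecords()].
#' @param depth_dispersion NB size for per-donor depth (`Inf` = Poisson).
#' @return A list of class `PowerEstimate`: `power`, `mc_se`
#'   (`sqrt(power * (1 - power) / n_reps)`), `n_reps`, and an echo of the
#'   design parameters.
#' @examples
#' estimatePower(depth_per_donor = 100, n_donors = 10, alt_fraction = 0.8,
#'               n_null_background = 100, n_reps = 100, seed = 1)
#' @export
estimatePower <- function(depth_per_donor, n_donors, alt_fraction,
                          n_null_background, fdr = 0.05, n_reps = 1000L,
                          seed = 1L, min_dp = 20, min_allele = 2,
                          depth_dispersion = Inf) {
    if (!is.finite(alt_fraction) || alt_fraction <= 0 || alt_fraction >= 1)
        stop("'alt_fraction' must be in (0, 1)")
    .check_count(n_donors, "n_donors")
    .check_count(n_reps, "n_reps")
    if (n_reps < 100L)
        stop("'n_reps' must be at least 100 for a usable Monte-Carlo ",
             "standard error")
    if (!is.finite(depth_per_donor) || depth_per_donor <= 0)
        stop("'depth_per_donor' must be > 0")
    m <- as.integer(n_null_background) + 1L
    p_true <- c(alt_fraction, rep(0.5, m - 1L))
    called <- withr::with_seed(as.integer(seed), {
        vapply(seq_len(n_reps), function(rep) {
            .power_one_rep(m, n_donors, depth_per_donor, depth_dispersion,
                           p_true, min_dp, min_allele, fdr)
        }, logical(1))
    })
    power <- mean(called)
    structure(list(power = power,
                   mc_se = sqrt(power * (1 - power) / n_reps),
                   n_reps = as.integer(n_reps),
                   depth_per_donor = depth_per_donor,
                   n_donors = as.integer(n_donors),
                   alt_fraction = alt_fraction,
                   n_null_background = as.integer(n_null_background),
                   fdr = fdr, seed = as.integer(seed)),
              class = "PowerEstimate")
}

# One replicate: row 1 is the imbalanced SNP, the rest the null background.
# Vectorised over SNPs x donors; mirrors filterHetRecords/aggregate/
# binomTwoSided/bhAdjust on implicit all-het records (equivalence is pinned
# by a test against callASoC on the materialised records).
.power_one_rep <- function(m, n_donors, depth_per_donor, depth_dispersion,
                           p_true, min_dp, min_allele, fdr) {
    depth <- if (is.infinite(depth_dispersion))
        stats::rpois(m * n_donors, depth_per_donor)
    else
        stats::rnbinom(m * n_donors, size = depth_dispersion,
                       mu = depth_per_donor)
    depth <- matrix(depth, m, n_donors)
    altc <- matrix(stats::rbinom(m * n_donors, depth, p_true), m, n_donors)
    refc <- depth - altc
    keep <- depth >= min_dp & pmin(refc, altc) >= min_allele
    tot_ref <- rowSums(refc * keep)
    tot_alt <- rowSums(altc * keep)
    surv <- rowSums(keep) >= 1L
    if (!surv[1L]) return(FALSE)
    p <- binomTwoSided(tot_ref[surv], (tot_ref + tot_alt)[surv])
    q <- bhAdjust(p)
    q[1L] < fdr    # row 1 survives, and survivors keep input order
}

#' @export
print.PowerEstimate <- function(x, ...) {
    cat(sprintf(
        "ASoC calling power: %.3f (MC se %.4f, %d reps)\n", x$power,
        x$mc_se, x$n_reps))
    cat(sprintf(
        "  design: %g reads/donor, %d donors, alt fraction %.2f, %d null SNPs, FDR %.3g\n",
        x$depth_per_donor, x$n_donors, x$alt_fraction, x$n_null_background,
        x$fdr))
    invisible(x)
}
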